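#' Bundled reference core-microbiome tables
#'
#' The four published reference tables shipped with the package as plain
#' data, exactly as printed: per-group membership cores (`table1` wheat
#' forecrop, `table2` legume forecrop; 10 OTUs each with mean relative
#' abundance in percent) and per-group composition cores (`table3` wheat,
#' `table4` legume; 10 OTUs each with mean and SD of relative abundance in
#' percent). Taxonomy labels are kept verbatim per table, including
#' duplicated labels across distinct OTU ids — identity is always the OTU
#' id, never the label.
#'
#' @return named list of data.frames. `table1`/`table2` have columns
#'   `otu_id`, `taxonomy`, `mean_ra`; `table3`/`table4` add `sd_ra`.
#' @export
core_table_fixtures <- function() {
  list(
    table1 = data.frame(
      otu_id = c("OTU1", "OTU2", "OTU14", "OTU5", "OTU3", "OTU7", "OTU26",
                 "OTU4", "OTU9", "OTU12"),
      taxonomy = c("Hyphomicrobiaceae", "Sphingomonas sp.", "Bradyrhizobiaceae",
                   "Burkholderiales", "Nitrospira sp.", "Rhizobiales",
                   "Baekduia sp.", "Pseudarthrobacter sp.",
                   "Bradyrhizobium sp.", "Bradyrhizobium sp."),
      mean_ra = c(0.0334, 0.0328, 0.0213, 0.0207, 0.0199, 0.0153, 0.0145,
                  0.0144, 0.0135, 0.0118),
      stringsAsFactors = FALSE),
    table2 = data.frame(
      otu_id = c("OTU1", "OTU3", "OTU11", "OTU4", "OTU10", "OTU6", "OTU13",
                 "OTU16", "OTU8", "OTU7"),
      taxonomy = c("Hyphomicrobiaceae", "Nitrospira sp.", "Bradyrhizobiaceae",
                   "Pseudarthrobacter sp.", "Gp16", "Rhizobiales", "Gp3",
                   "Bradyrhizobiaceae", "Pseudarthrobacter sp.", "Rhizobiales"),
      mean_ra = c(0.0325, 0.0248, 0.0206, 0.0197, 0.0195, 0.0182, 0.0173,
                  0.0169, 0.0165, 0.0149),
      stringsAsFactors = FALSE),
    table3 = data.frame(
      otu_id = c("OTU1", "OTU3", "OTU7", "OTU4", "OTU9", "OTU8", "OTU17",
                 "OTU36", "OTU13", "OTU69"),
      taxonomy = c("Hyphomicrobiaceae", "Nitrospira sp.", "Bradyrhizobiaceae",
                   "Pseudarthrobacter sp.", "Bradyrhizobium sp.",
                   "Pseudarthrobacter sp.", "Nitrospira sp.",
                   "Streptosporangium sp.", "Acidobacteria_Gp3", "Devosia sp."),
      mean_ra = c(1.232, 0.913, 0.3840, 0.6180, 0.3380, 0.2950, 0.1350,
                  0.3041, 0.2954, 0.2575),
      sd_ra = c(0.1780, 0.2790, 0.0033, 0.0021, 0.0016, 0.0003, 0.0005,
                0.0023, 0.0001, 0.0001),
      stringsAsFactors = FALSE),
    table4 = data.frame(
      otu_id = c("OTU1", "OTU3", "OTU11", "OTU4", "OTU10", "OTU13", "OTU16",
                 "OTU8", "OTU9", "OTU7"),
      taxonomy = c("Hyphomicrobiaceae", "Nitrospira sp.", "Rhodoplanes sp.",
                   "Pseudarthrobacter sp.", "Acidobacteria_Gp16",
                   "Acidobacteria_Gp3", "Rhizobiales", "Pseudarthrobacter sp.",
                   "Nitrospira sp.", "Bradyrhizobiaceae"),
      mean_ra = c(1.0240, 0.7360, 0.6750, 0.5760, 0.5599, 0.6360, 0.4457,
                  0.3634, 0.3072, 0.3451),
      sd_ra = c(0.1810, 0.0930, 0.1420, 0.2663, 0.1328, 0.1460, 0.0129,
                0.0500, 0.0663, 0.1095),
      stringsAsFactors = FALSE)
  )
}

# One lineage per fixture OTU id. Where the reference tables disagree on an
# OTU's label across tables, the deepest lineage consistent with all its
# labels is used; the tables themselves keep their printed labels verbatim.
fixture_lineage_strings <- function() {
  c(OTU1  = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae",
    OTU2  = "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingomonas",
    OTU3  = "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
    OTU4  = "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Micrococcaceae;Pseudarthrobacter",
    OTU5  = "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales",
    OTU6  = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales",
    OTU7  = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae",
    OTU8  = "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Micrococcaceae;Pseudarthrobacter",
    OTU9  = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae;Bradyrhizobium",
    OTU10 = "Bacteria;Acidobacteria;Acidobacteria_Gp16;Gp16",
    OTU11 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Rhodoplanes",
    OTU12 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae;Bradyrhizobium",
    OTU13 = "Bacteria;Acidobacteria;Acidobacteria_Gp3;Gp3",
    OTU14 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae",
    OTU16 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae",
    OTU17 = "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
    OTU26 = "Bacteria;Actinobacteria;Thermoleophilia;Solirubrobacterales;Baekduiaceae;Baekduia",
    OTU36 = "Bacteria;Actinobacteria;Actinobacteria;Streptosporangiales;Streptosporangiaceae;Streptosporangium",
    OTU69 = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Devosia")
}

#' Lineages for the fixture OTUs
#'
#' @return named list of `lineage` objects covering every OTU id appearing
#'   in [core_table_fixtures()].
#' @export
fixture_taxonomy <- function() {
  strings <- fixture_lineage_strings()
  mapply(parse_lineage, names(strings), strings, SIMPLIFY = FALSE)
}

#' A core set built directly from one reference table
#'
#' Wraps the printed rows of a fixture table as a `core_set` (members
#' re-sorted by descending abundance), useful for overlap comparisons of the
#' printed cores.
#'
#' @param name one of `"table1"`..`"table4"`.
#' @return a `core_set` (`membership` method for tables 1-2, `composition`
#'   for tables 3-4; group `W` for tables 1 and 3, `L` for tables 2 and 4).
#' @export
fixture_core_set <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  tab <- core_table_fixtures()[[name]]
  if (is.null(tab$sd_ra)) tab$sd_ra <- NA_real_
  new_core_set(method = if (name %in% c("table1", "table2")) "membership"
                        else "composition",
               group = if (name %in% c("table1", "table3")) "W" else "L",
               members = tab[, c("otu_id", "taxonomy", "mean_ra", "sd_ra")],
               params = list(source = name))
}

#' A per-sample community realizing one reference table
#'
#' The reference tables print per-group summaries (mean, and for the
#' composition tables SD, of relative abundance over 4 samples); the
#' underlying per-sample table was never published. This helper constructs a
#' 4-sample proportion-mode community whose group summaries reproduce a
#' table exactly: each listed OTU gets per-sample proportions with the
#' printed mean (and, for tables 3-4, the printed sample SD, via the pattern
#' mean ± d with d = sd * sqrt(3)/2), and each sample carries one
#' filler OTU (present in that sample only, hence never a core candidate)
#' absorbing the remaining mass so columns sum to 1.
#'
#' @param name one of `"table1"`..`"table4"`.
#' @return an `abund_table` in proportion mode with 14 OTUs and 4 samples
#'   (group `W` for tables 1 and 3, `L` for tables 2 and 4).
#' @export
fixture_community <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  tab <- core_table_fixtures()[[name]]
  group <- if (name %in% c("table1", "table3")) "W" else "L"
  n_samp <- 4
  means <- tab$mean_ra / 100
  d <- if (is.null(tab$sd_ra)) rep(0, nrow(tab)) else (tab$sd_ra / 100) * sqrt(3) / 2
  core <- means %o% rep(1, n_samp) + d %o% c(1, -1, 1, -1)
  if (any(core <= 0)) stop("fixture construction produced non-positive proportions")
  filler <- diag(1 - colSums(core))
  values <- rbind(core, filler)
  rownames(values) <- c(tab$otu_id, sprintf("FILL%d", seq_len(n_samp)))
  colnames(values) <- sprintf("%s%d", group, seq_len(n_samp))
  abundance_table(values, mode = "proportion",
                  groups = setNames(rep(group, n_samp), colnames(values)))
}
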