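# Pool of full lineage strings the generator samples taxonomy from. It
# includes the lineages recurrent in rhizosphere core-microbiome surveys
# (Hyphomicrobiaceae, Bradyrhizobiaceae, Nitrospira, Sphingomonas,
# Pseudarthrobacter, Bradyrhizobium, Rhodoplanes, Burkholderiales).
synth_taxonomy_pool <- function() {
  c("Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Bradyrhizobiaceae;Bradyrhizobium",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Rhodoplanes",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Devosia",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingomonas",
    "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales",
    "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae",
    "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
    "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Micrococcaceae;Pseudarthrobacter",
    "Bacteria;Actinobacteria;Thermoleophilia;Solirubrobacterales;Baekduiaceae;Baekduia",
    "Bacteria;Actinobacteria;Actinobacteria;Streptosporangiales;Streptosporangiaceae;Streptosporangium",
    "Bacteria;Acidobacteria;Acidobacteria_Gp3;Gp3",
    "Bacteria;Acidobacteria;Acidobacteria_Gp16;Gp16",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales",
    "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Micrococcaceae")
}

#' Specification of a synthetic rhizosphere community
#'
#' Parameters of the community generator. The defaults emulate the study
#' design the package's methods target: two forecrop groups (`W`, `L`) of 4
#' rhizosphere samples each, sequenced to ~5,000 reads per sample, with a
#' small ubiquitous low-variance planted core, a few abundant high-variance
#' "decoy" taxa (the kind the SDRA filter is meant to reject), and a tail of
#' patchy low-abundance peripheral taxa.
#'
#' Abundance law: each taxon gets a community-level base weight drawn from a
#' lognormal, jittered per sample by an independent lognormal factor with
#' the stated coefficient of variation; expected proportions are
#' renormalized per sample and counts drawn from a multinomial at `depth`.
#'
#' @param group_labels labels of the groups (default `c("W", "L")`).
#' @param samples_per_group samples per group (default 4).
#' @param n_core planted ubiquitous low-variance core taxa (default 10).
#' @param n_decoy abundant high-variance taxa (default 2).
#' @param n_peripheral patchy peripheral taxa (default 40).
#' @param depth reads per sample (default 5000).
#' @param core_mean_ra expected pre-normalization relative weight of a core
#'   taxon (default 0.005).
#' @param core_cv per-sample coefficient of variation of core taxa
#'   (default 0.05; also the spread of base weights across taxa).
#' @param decoy_mean_mult decoy base weight as a multiple of `core_mean_ra`
#'   (default 0.8).
#' @param decoy_cv per-sample coefficient of variation of decoy taxa
#'   (default 1.0).
#' @param peripheral_prevalence probability a peripheral taxon occurs in a
#'   given sample (default 0.5). Peripheral weights are one order of
#'   magnitude below the core.
#' @param group_effect optional multiplicative abundance shift applied to a
#'   subset of taxa in the second group, as
#'   `list(otu_idx = integer vector, factor = number)`; default `NULL` (no
#'   group contrast, the two groups are exchangeable draws).
#' @param seed integer random seed; identical spec + seed reproduce the
#'   output exactly (R's Mersenne-Twister generator).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(group_labels = c("W", "L"), samples_per_group = 4,
                       n_core = 10, n_decoy = 2, n_peripheral = 40,
                       depth = 5000, core_mean_ra = 0.005, core_cv = 0.05,
                       decoy_mean_mult = 0.8, decoy_cv = 1.0,
                       peripheral_prevalence = 0.5, group_effect = NULL,
                       seed = 1) {
  stopifnot(length(group_labels) >= 1, !anyDuplicated(group_labels),
            samples_per_group >= 1, n_core >= 0, n_decoy >= 0,
            n_peripheral >= 0, depth >= 1, core_mean_ra > 0, core_cv >= 0,
            decoy_mean_mult >= 0, decoy_cv >= 0,
            peripheral_prevalence >= 0, peripheral_prevalence <= 1)
  structure(as.list(environment()), class = "synth_spec")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic community
#'
#' Draws an OTU-by-sample count table, a taxonomy map and a truth record
#' from a [synth_spec()]. The truth record identifies the planted core,
#' decoy and peripheral taxa and reports each core taxon's design
#' ("planted") SDRA — its per-sample coefficient of variation times its
#' expected share, on the percent scale — which is the natural reference
#' point for tuning a composition-method threshold on known ground truth.
#'
#' @param spec a `synth_spec`.
#' @return list with `table` (an `abund_table` of counts over all groups'
#'   samples), `taxonomy` (named list of `lineage` objects) and `truth`
#'   (list: `core_ids`, `decoy_ids`, `peripheral_ids`, per-group copies in
#'   `core_ids_by_group`, `planted_core_sd`, `expected_share`, `rng`,
#'   `warnings`).
#' @export
synth_community <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  n_otu <- spec$n_core + spec$n_decoy + spec$n_peripheral
  otu_ids <- sprintf("OTU%d", seq_len(n_otu))
  core_idx <- seq_len(spec$n_core)
  decoy_idx <- spec$n_core + seq_len(spec$n_decoy)
  peri_idx <- spec$n_core + spec$n_decoy + seq_len(spec$n_peripheral)

  base <- numeric(n_otu)
  base[core_idx] <- rlnorm_mean_cv(spec$n_core, spec$core_mean_ra, spec$core_cv)
  base[decoy_idx] <- rlnorm_mean_cv(spec$n_decoy,
                                    spec$core_mean_ra * spec$decoy_mean_mult,
                                    spec$core_cv)
  base[peri_idx] <- rlnorm_mean_cv(spec$n_peripheral,
                                   spec$core_mean_ra / 10, spec$core_cv)

  n_groups <- length(spec$group_labels)
  sample_ids <- as.vector(vapply(spec$group_labels, function(g)
    sprintf("%s%d", g, seq_len(spec$samples_per_group)),
    character(spec$samples_per_group)))
  groups <- setNames(rep(spec$group_labels, each = spec$samples_per_group),
                     sample_ids)

  counts <- matrix(0, n_otu, length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  expected_share <- matrix(0, n_otu, n_groups,
                           dimnames = list(otu_ids, spec$group_labels))
  for (gi in seq_len(n_groups)) {
    gbase <- base
    if (gi == 2 && !is.null(spec$group_effect))
      gbase[spec$group_effect$otu_idx] <-
        gbase[spec$group_effect$otu_idx] * spec$group_effect$factor
    # expected per-sample total weight (peripherals discounted by prevalence)
    tot <- sum(gbase[c(core_idx, decoy_idx)]) +
      sum(gbase[peri_idx]) * spec$peripheral_prevalence
    expected_share[, gi] <- gbase / tot
    expected_share[peri_idx, gi] <- expected_share[peri_idx, gi] *
      spec$peripheral_prevalence
    for (si in seq_len(spec$samples_per_group)) {
      e <- numeric(n_otu)
      e[core_idx] <- gbase[core_idx] *
        rlnorm_mean_cv(spec$n_core, 1, spec$core_cv)
      e[decoy_idx] <- gbase[decoy_idx] *
        rlnorm_mean_cv(spec$n_decoy, 1, spec$decoy_cv)
      e[peri_idx] <- gbase[peri_idx] *
        rlnorm_mean_cv(spec$n_peripheral, 1, spec$core_cv) *
        rbinom(spec$n_peripheral, 1, spec$peripheral_prevalence)
      col <- (gi - 1) * spec$samples_per_group + si
      counts[, col] <- rmultinom(1, spec$depth, e / sum(e))
    }
  }

  pool <- synth_taxonomy_pool()
  tax_strings <- sample(pool, n_otu, replace = TRUE)
  taxonomy <- mapply(parse_lineage, otu_ids, tax_strings, SIMPLIFY = FALSE)

  warnings <- character(0)
  core_share <- expected_share[core_idx, 1]
  if (spec$n_core > 0 && any(core_share * spec$depth < 1))
    warnings <- c(warnings,
                  "depth too small: expected core counts below 1 read/sample")

  truth <- list(
    core_ids = otu_ids[core_idx],
    decoy_ids = otu_ids[decoy_idx],
    peripheral_ids = otu_ids[peri_idx],
    core_ids_by_group = setNames(rep(list(otu_ids[core_idx]), n_groups),
                                 spec$group_labels),
    planted_core_sd = setNames(100 * spec$core_cv * core_share,
                               otu_ids[core_idx]),
    expected_share = expected_share,
    rng = "Mersenne-Twister",
    warnings = warnings)

  list(table = abundance_table(counts, mode = "counts", groups = groups),
       taxonomy = taxonomy, truth = truth)
}
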