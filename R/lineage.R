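#' Taxonomic lineage of one OTU
#'
#' Parses a semicolon-delimited lineage string into an ordered set of named
#' ranks (domain down to species). Two dialects are supported:
#' `rank_prefixed` strips SILVA/Greengenes-style prefixes (`d__`, `p__`,
#' `c__`, `o__`, `f__`, `g__`, `s__`; `k__` is treated as domain) and places
#' each segment in the rank its prefix names; `plain_semicolon` assigns
#' segments positionally from domain downward.
#'
#' @param otu_id identifier of the OTU the lineage belongs to.
#' @param string the lineage string, e.g.
#'   `"Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira"`.
#' @param dialect `"plain_semicolon"` (default) or `"rank_prefixed"`.
#' @return an object of class `lineage`: a list with `otu_id`, `ranks` (a
#'   named character vector over domain, phylum, class, order, family, genus,
#'   species; unclassified ranks are empty strings) and `raw` (the input).
#' @export
parse_lineage <- function(otu_id, string,
                          dialect = c("plain_semicolon", "rank_prefixed")) {
  dialect <- match.arg(dialect)
  rank_names <- c("domain", "phylum", "class", "order", "family", "genus",
                  "species")
  ranks <- setNames(rep("", 7L), rank_names)
  string <- if (is.null(string) || is.na(string)) "" else trimws(string)
  if (nzchar(string)) {
    parts <- trimws(strsplit(string, ";", fixed = TRUE)[[1]])
    if (dialect == "rank_prefixed") {
      prefix_map <- c(d = "domain", k = "domain", p = "phylum", c = "class",
                      o = "order", f = "family", g = "genus", s = "species")
      for (p in parts) {
        if (grepl("^[dkpcofgs]__", p)) {
          ranks[[prefix_map[[substr(p, 1, 1)]]]] <- sub("^[dkpcofgs]__", "", p)
        }
      }
    } else {
      n <- min(length(parts), 7L)
      ranks[seq_len(n)] <- parts[seq_len(n)]
    }
  }
  structure(list(otu_id = otu_id, ranks = ranks, raw = string),
            class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$otu_id, lineage_label(x)))
  invisible(x)
}

#' Is a lineage wholly unclassified?
#'
#' @param lin a `lineage`.
#' @return `TRUE` when no rank carries a name (or every rank is an
#'   "unclassified"/"uncultured" placeholder).
#' @export
is_unclassified <- function(lin) {
  stopifnot(inherits(lin, "lineage"))
  r <- lin$ranks
  named <- nzchar(r) & !grepl("^(unclassified|uncultured|unknown)$", r,
                              ignore.case = TRUE)
  !any(named)
}

#' Display label of a lineage: the deepest named rank
#'
#' @param lin a `lineage`.
#' @return character scalar; `"Unclassified"` for an empty lineage.
#' @export
lineage_label <- function(lin) {
  stopifnot(inherits(lin, "lineage"))
  named <- lin$ranks[nzchar(lin$ranks)]
  if (length(named) == 0) "Unclassified" else unname(named[length(named)])
}
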