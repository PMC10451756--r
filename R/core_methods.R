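# Numeric-aware OTU id ordering: "OTU2" sorts before "OTU10". Ids are split
# into a leading alphabetic prefix and a numeric suffix; ties and ids without
# a numeric suffix fall back to plain lexicographic order.
otu_id_order <- function(ids) {
  prefix <- sub("([0-9]+)$", "", ids)
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", ids)))
  num[!grepl("[0-9]+$", ids)] <- Inf
  order(prefix, num, ids)
}

otu_id_rank <- function(ids) {
  r <- integer(length(ids))
  r[otu_id_order(ids)] <- seq_along(ids)
  r
}

resolve_taxonomy_labels <- function(otu_ids, taxonomy) {
  if (is.null(taxonomy)) return(otu_ids)
  lab <- vapply(otu_ids, function(id) {
    entry <- taxonomy[[id]]
    if (is.null(entry)) id
    else if (inherits(entry, "lineage")) lineage_label(entry)
    else as.character(entry)
  }, character(1))
  unname(lab)
}

#' Construct a core set
#'
#' Low-level constructor shared by the core-definition methods. Members are
#' sorted by descending mean relative abundance with ties broken by
#' numeric-aware OTU id, and the total core abundance is the sum of member
#' means (percent scale).
#'
#' @param method `"membership"`, `"composition"` or `"functional"`.
#' @param group group label the set was computed for.
#' @param members data.frame with columns `otu_id`, `taxonomy`, `mean_ra`,
#'   `sd_ra` (use `NA` where the method reports no SD).
#' @param params named list of the method's parameters.
#' @param sort_members sort on construction (default `TRUE`; reports read
#'   back from disk keep their stored order).
#' @return an object of class `core_set`.
#' @export
new_core_set <- function(method, group, members, params = list(),
                         sort_members = TRUE) {
  stopifnot(is.data.frame(members),
            all(c("otu_id", "taxonomy", "mean_ra", "sd_ra") %in% names(members)))
  if (sort_members && nrow(members) > 0) {
    members <- members[order(-members$mean_ra, otu_id_rank(members$otu_id)), ,
                       drop = FALSE]
  }
  rownames(members) <- NULL
  structure(list(method = method, group = group, members = members,
                 params = params,
                 total_core_abundance = sum(members$mean_ra)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set (%s method), group %s: %d member(s), total %.4f%%\n",
              x$method, x$group, nrow(x$members), x$total_core_abundance))
  if (nrow(x$members) > 0) print(utils::head(x$members, 10))
  invisible(x)
}

#' Member OTU ids of a core set
#' @param core a `core_set`.
#' @return character vector of OTU ids in the set's stored order.
#' @export
core_members <- function(core) {
  stopifnot(inherits(core, "core_set"))
  core$members$otu_id
}

#' Membership-based core microbiome (shared taxa, top N)
#'
#' The membership definition: an OTU is a core candidate when it is detected
#' in every sample of the group (prevalence 1). Candidates are ranked by mean
#' relative abundance (descending, ties broken by OTU id) and the `top_n`
#' most abundant are retained.
#'
#' @param x an `abund_table` in proportion mode.
#' @param group group label to analyze.
#' @param top_n number of top-ranked shared OTUs to keep (default 10).
#' @param taxonomy optional named list of `lineage` objects (or named
#'   character vector of labels) used for the report's taxonomy column.
#' @param presence_epsilon detection floor, see [summarize_group()].
#' @return a `core_set` with `method = "membership"`. `sd_ra` is `NA` for
#'   every member: this definition does not use the SD.
#' @export
membership_core <- function(x, group, top_n = 10, taxonomy = NULL,
                            presence_epsilon = 0) {
  if (!is.numeric(top_n) || length(top_n) != 1 || top_n < 1)
    stop("top_n must be a single integer >= 1")
  s <- summarize_group(x, group, presence_epsilon = presence_epsilon)
  cand <- s[s$prevalence == 1, , drop = FALSE]
  cand <- cand[order(-cand$mean_ra, otu_id_rank(cand$otu_id)), , drop = FALSE]
  keep <- utils::head(cand, min(as.integer(top_n), nrow(cand)))
  members <- data.frame(otu_id = keep$otu_id,
                        taxonomy = resolve_taxonomy_labels(keep$otu_id, taxonomy),
                        mean_ra = keep$mean_ra,
                        sd_ra = rep(NA_real_, nrow(keep)),
                        stringsAsFactors = FALSE)
  new_core_set("membership", group, members,
               params = list(top_n = as.integer(top_n),
                             presence_rule = "all samples",
                             presence_epsilon = presence_epsilon))
}

#' Composition-based core microbiome (SDRA threshold)
#'
#' The composition definition builds on the membership candidate set: among
#' OTUs detected in every sample of the group, those whose standard deviation
#' of relative abundance (SDRA) is strictly below `sd_threshold` form the
#' core — shared taxa held at similar proportions across samples.
#'
#' @inheritParams membership_core
#' @param sd_threshold the SDRA cut-off (strict `<`), default 0.01.
#' @param threshold_scale scale the threshold is stated on: `"percent"`
#'   (default; compared against `sd_ra`, which is a percentage) or
#'   `"proportion"` (threshold multiplied by 100 before the comparison).
#' @param sd_ddof SD convention, see [summarize_group()].
#' @return a `core_set` with `method = "composition"`; members keep their
#'   per-OTU SDRA in `sd_ra`.
#' @export
composition_core <- function(x, group, sd_threshold = 0.01,
                             threshold_scale = c("percent", "proportion"),
                             taxonomy = NULL, sd_ddof = 1,
                             presence_epsilon = 0) {
  threshold_scale <- match.arg(threshold_scale)
  if (!is.numeric(sd_threshold) || sd_threshold <= 0)
    stop("sd_threshold must be > 0")
  sams <- group_samples(x, group)
  if (length(sams) < 2)
    stop("group '", group, "' has a single sample: the standard deviation ",
         "of relative abundance is undefined")
  s <- summarize_group(x, group, presence_epsilon = presence_epsilon,
                       sd_ddof = sd_ddof)
  thr_pct <- if (threshold_scale == "percent") sd_threshold else 100 * sd_threshold
  cand <- s[s$prevalence == 1, , drop = FALSE]
  keep <- cand[cand$sd_ra < thr_pct, , drop = FALSE]
  members <- data.frame(otu_id = keep$otu_id,
                        taxonomy = resolve_taxonomy_labels(keep$otu_id, taxonomy),
                        mean_ra = keep$mean_ra, sd_ra = keep$sd_ra,
                        stringsAsFactors = FALSE)
  new_core_set("composition", group, members,
               params = list(sd_threshold = sd_threshold,
                             threshold_scale = threshold_scale,
                             sd_ddof = sd_ddof,
                             presence_epsilon = presence_epsilon))
}

#' Overlap between two core sets
#'
#' Partitions the union of two core sets' members into the OTUs shared by
#' both and those unique to each — the set algebra behind Venn-diagram
#' comparisons of core definitions (membership vs composition, or one group
#' vs another). Shared OTUs are ordered by descending mean abundance in the
#' first set (ties by OTU id); unique OTUs follow their own set's order.
#'
#' @param a,b `core_set` objects.
#' @return an object of class `core_overlap`: list with `shared`,
#'   `unique_a`, `unique_b` (character vectors of OTU ids), `labels` (OTU id
#'   to taxonomy label map over the union) and the two input identities.
#' @export
core_overlap <- function(a, b) {
  stopifnot(inherits(a, "core_set"), inherits(b, "core_set"))
  ids_a <- a$members$otu_id
  ids_b <- b$members$otu_id
  shared <- ids_a[ids_a %in% ids_b]
  labels <- c(setNames(a$members$taxonomy, ids_a),
              setNames(b$members$taxonomy, ids_b))
  labels <- labels[!duplicated(names(labels))]
  structure(list(shared = shared,
                 unique_a = ids_a[!ids_a %in% ids_b],
                 unique_b = ids_b[!ids_b %in% ids_a],
                 labels = labels,
                 set_a = sprintf("%s/%s", a$method, a$group),
                 set_b = sprintf("%s/%s", b$method, b$group)),
            class = "core_overlap")
}

#' @export
print.core_overlap <- function(x, ...) {
  cat(sprintf("core overlap %s vs %s\n", x$set_a, x$set_b))
  fmt <- function(ids) if (length(ids) == 0) "(none)"
                       else paste(sprintf("%s [%s]", ids, x$labels[ids]),
                                  collapse = ", ")
  cat(" shared:  ", fmt(x$shared), "\n")
  cat(" only a:  ", fmt(x$unique_a), "\n")
  cat(" only b:  ", fmt(x$unique_b), "\n")
  invisible(x)
}

#' Write a core overlap report
#'
#' Three-column tab-separated file: partition (`shared` / `unique_a` /
#' `unique_b`), OTU id, taxonomy label.
#'
#' @param overlap a `core_overlap`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(overlap, path) {
  stopifnot(inherits(overlap, "core_overlap"))
  rows <- do.call(rbind, lapply(c("shared", "unique_a", "unique_b"),
                                function(part) {
    ids <- overlap[[part]]
    if (length(ids) == 0) return(NULL)
    data.frame(partition = part, otu_id = ids,
               taxonomy = unname(overlap$labels[ids]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(partition = character(), otu_id = character(),
                       taxonomy = character(), stringsAsFactors = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
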