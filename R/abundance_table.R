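#' OTU-by-sample abundance table
#'
#' The central container of the package: a non-negative numeric matrix with
#' OTUs (or ASVs) as rows and samples as columns, a `mode` saying whether the
#' cells are read counts, proportions (columns sum to 1) or percentages
#' (columns sum to 100), and a sample-to-group map (e.g. forecrop `"W"` vs
#' `"L"`).
#'
#' @param values numeric matrix, rows = OTUs, columns = samples. Row and
#'   column names are used as OTU and sample identifiers and must be unique.
#' @param mode one of `"counts"`, `"proportion"`, `"percent"`.
#' @param groups named character vector mapping every sample id to a group
#'   label. If `NULL`, all samples are placed in a single group `"all"`.
#' @param validate check the invariants (non-negativity, unique ids, column
#'   sums consistent with `mode`, complete group map).
#'
#' @return an object of class `abund_table`.
#' @export
abundance_table <- function(values,
                            mode = c("counts", "proportion", "percent"),
                            groups = NULL,
                            validate = TRUE) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have OTU row names and sample column names")
  if (is.null(groups)) {
    groups <- setNames(rep("all", ncol(values)), colnames(values))
  }
  groups <- setNames(as.character(groups[colnames(values)]), colnames(values))
  x <- structure(list(values = values, mode = mode, groups = groups),
                 class = "abund_table")
  if (validate) validate_abundance_table(x)
  x
}

validate_abundance_table <- function(x) {
  v <- x$values
  if (anyNA(v)) stop("abundance table contains missing values")
  if (any(v < 0)) stop("abundance table contains negative values")
  if (anyDuplicated(rownames(v)))
    stop("duplicate OTU ids: ", paste(unique(rownames(v)[duplicated(rownames(v))]),
                                      collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample ids: ", paste(unique(colnames(v)[duplicated(colnames(v))]),
                                         collapse = ", "))
  if (anyNA(x$groups) || any(x$groups == ""))
    stop("every sample must have a group label")
  cs <- colSums(v)
  if (x$mode == "proportion") {
    if (any(cs == 0)) stop("all-zero sample column(s): ",
                           paste(colnames(v)[cs == 0], collapse = ", "))
    if (any(abs(cs - 1) > 1e-9))
      stop("proportion-mode columns must sum to 1 (off: ",
           paste(colnames(v)[abs(cs - 1) > 1e-9], collapse = ", "), ")")
  } else if (x$mode == "percent") {
    if (any(abs(cs - 100) > 1e-6))
      stop("percent-mode columns must sum to 100 (off: ",
           paste(colnames(v)[abs(cs - 100) > 1e-6], collapse = ", "), ")")
  }
  invisible(x)
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("abundance table: %d OTUs x %d samples (mode: %s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abund_table <- function(x) dim(x$values)

#' Sample ids belonging to one group
#'
#' @param x an `abund_table`.
#' @param group a group label present in `x`.
#' @return character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  stopifnot(inherits(x, "abund_table"))
  if (!group %in% x$groups)
    stop("unknown group label: ", group,
         " (known: ", paste(unique(x$groups), collapse = ", "), ")")
  names(x$groups)[x$groups == group]
}

#' Group labels present in an abundance table
#' @param x an `abund_table`.
#' @return character vector of unique group labels, in order of appearance.
#' @export
table_groups <- function(x) unique(x$groups)

#' Convert counts (or percentages) to relative abundances
#'
#' Divides every sample column by its column sum so that columns sum to 1.
#' A table already in proportion mode is returned unchanged.
#'
#' @param x an `abund_table`.
#' @return an `abund_table` in `proportion` mode, same OTU and sample order.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abund_table"))
  if (x$mode == "proportion") return(x)
  cs <- colSums(x$values)
  if (any(cs == 0))
    stop("cannot normalize all-zero sample column(s): ",
         paste(colnames(x$values)[cs == 0], collapse = ", "))
  abundance_table(sweep(x$values, 2, cs, "/"), mode = "proportion",
                  groups = x$groups)
}

#' Per-group per-OTU summary statistics
#'
#' For each OTU, computes over the group's samples the mean relative abundance
#' (`mean_ra`), the standard deviation of relative abundance (`sd_ra`, the
#' SDRA statistic of the composition-based core definition), and the
#' prevalence (fraction of samples where the OTU is detected). `mean_ra` and
#' `sd_ra` are reported on the percent scale, matching how core-microbiome
#' tables are conventionally printed.
#'
#' @param x an `abund_table` in proportion mode (see [to_relative()]).
#' @param group a group label in `x`.
#' @param presence_epsilon an OTU counts as present in a sample when its
#'   proportion is strictly greater than this (default 0: any read counts).
#' @param sd_ddof degrees-of-freedom convention for the SD: 1 (sample SD,
#'   the default) or 0 (population SD). With a single sample `sd_ra` is 0.
#' @return data.frame with columns `otu_id`, `group`, `mean_ra`, `sd_ra`,
#'   `prevalence`, one row per OTU in table order.
#' @export
summarize_group <- function(x, group, presence_epsilon = 0, sd_ddof = 1) {
  stopifnot(inherits(x, "abund_table"))
  if (x$mode != "proportion")
    stop("summaries require proportion mode; call to_relative() first")
  if (!sd_ddof %in% c(0, 1)) stop("sd_ddof must be 0 or 1")
  sams <- group_samples(x, group)
  m <- x$values[, sams, drop = FALSE]
  n <- ncol(m)
  means <- rowMeans(m)
  if (n == 1) {
    sds <- rep(0, nrow(m))
  } else {
    sds <- apply(m, 1, sd)            # n - 1 denominator
    if (sd_ddof == 0) sds <- sds * sqrt((n - 1) / n)
  }
  prev <- rowMeans(m > presence_epsilon)
  data.frame(otu_id = rownames(m), group = group,
             mean_ra = 100 * means, sd_ra = 100 * sds, prevalence = prev,
             row.names = NULL, stringsAsFactors = FALSE)
}
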