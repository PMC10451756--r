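#' Read an OTU-by-sample abundance table from a tab-separated file
#'
#' The file layout is one row per OTU: the first column holds OTU ids, the
#' header row holds sample ids, every other cell is a number. The mode is
#' inferred when not given: an all-integer body is read as counts, columns
#' summing to ~1 as proportions, to ~100 as percentages. Inference is
#' best-effort; pass `mode` explicitly for anything ambiguous (e.g. summary
#' tables covering only part of a community, together with
#' `check_sums = FALSE`).
#'
#' @param path file path.
#' @param mode `NULL` (infer) or one of `"counts"`, `"proportion"`,
#'   `"percent"`.
#' @param groups sample-to-group map: a named character vector, or the path
#'   of a two-column tab-separated file (sample id, group label), or `NULL`
#'   (all samples in one group `"all"`).
#' @param check_sums validate column sums against the mode (default `TRUE`).
#'   Only honoured as `FALSE` when `mode` is given explicitly.
#' @return an `abund_table`.
#' @export
read_abundance_table <- function(path, mode = NULL, groups = NULL,
                                 check_sums = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs an OTU id column plus >= 1 sample column")
  otu_ids <- df[[1]]
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id(s): ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(otu_ids, colnames(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at OTU '%s', sample '%s'",
                 body[bad[1], bad[2]], otu_ids[bad[1]], colnames(num)[bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at OTU '%s', sample '%s'",
                 otu_ids[bad[1]], colnames(num)[bad[2]]))
  }
  if (is.character(groups) && length(groups) == 1 && is.null(names(groups)) &&
      file.exists(groups)) {
    groups <- read_group_map(groups)
  }
  if (is.null(mode)) {
    cs <- colSums(num)
    mode <- if (all(abs(num - round(num)) < 1e-9)) "counts"
            else if (all(abs(cs - 1) < 1e-6)) "proportion"
            else if (all(abs(cs - 100) < 1e-4)) "percent"
            else stop("cannot infer mode (columns sum to neither ~1 nor ~100 ",
                      "and values are not integer counts); pass `mode`")
    check_sums <- TRUE
  }
  abundance_table(num, mode = mode, groups = groups, validate = check_sums)
}

#' Write an abundance table to a tab-separated file
#'
#' Inverse of [read_abundance_table()]: first column `otu_id`, one column per
#' sample. The group map is not embedded; persist it with
#' [write_group_map()].
#'
#' @param x an `abund_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abund_table"))
  df <- data.frame(otu_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-group map
#'
#' Two tab-separated columns: sample id, group label. No header.
#'
#' @param path file path.
#' @return `read_group_map`: a named character vector (names are sample ids).
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group map needs two columns: sample id, group")
  setNames(df[[2]], df[[1]])
}

#' @rdname read_group_map
#' @param groups named character vector mapping sample ids to group labels.
#' @export
write_group_map <- function(groups, path) {
  write.table(data.frame(names(groups), unname(groups)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: OTU id, lineage string (no header). Lineages
#' are parsed with [parse_lineage()] in the requested dialect.
#'
#' @param path file path.
#' @param dialect lineage dialect, see [parse_lineage()].
#' @param otu_ids optional character vector of OTU ids that must be covered
#'   (typically the rows of an abundance table). Ids missing from the file
#'   get an all-unclassified lineage with a warning, or an error when
#'   `missing = "error"`.
#' @param missing `"warn"` (default) or `"error"`.
#' @return named list of `lineage` objects.
#' @export
read_taxonomy <- function(path, dialect = c("plain_semicolon", "rank_prefixed"),
                          otu_ids = NULL, missing = c("warn", "error")) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) df$V2 <- ""
  lin <- mapply(parse_lineage, df[[1]], df[[2]],
                MoreArgs = list(dialect = dialect), SIMPLIFY = FALSE)
  names(lin) <- df[[1]]
  if (!is.null(otu_ids)) {
    lost <- setdiff(otu_ids, names(lin))
    if (length(lost) > 0) {
      msg <- paste0(length(lost), " OTU(s) missing from taxonomy: ",
                    paste(head(lost, 5), collapse = ", "),
                    if (length(lost) > 5) ", ...")
      if (missing == "error") stop(msg)
      warning(msg, "; assigning unclassified lineages")
      for (id in lost) lin[[id]] <- parse_lineage(id, "")
    }
  }
  lin
}

#' Write a taxonomy map
#'
#' @param lineages named list of `lineage` objects (or a named character
#'   vector of lineage strings).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(lineages, path) {
  raw <- vapply(lineages,
                function(l) if (inherits(l, "lineage")) l$raw else as.character(l),
                character(1))
  write.table(data.frame(names(lineages), unname(raw)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a core-set report
#'
#' Tab-separated report mirroring the layout of published core-microbiome
#' tables: columns `otu_id`, `taxonomy`, `mean_ra`, `sd_ra` (percent scale, 4
#' decimal places; the SD column is blank for the membership method), a
#' `TOTAL` footer row carrying the summed core abundance, and `#`-prefixed
#' header lines recording the method, group and parameters so the report can
#' be re-read with [read_core_report()].
#'
#' @param core a `core_set` (see [membership_core()], [composition_core()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_core_report <- function(core, path) {
  stopifnot(inherits(core, "core_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", core$method),
               sprintf("# group: %s", core$group),
               sprintf("# params: %s",
                       jsonlite::toJSON(core$params, auto_unbox = TRUE)),
               "otu_id\ttaxonomy\tmean_ra\tsd_ra"), con)
  m <- core$members
  if (nrow(m) > 0) {
    sd_col <- if (core$method == "membership" || all(is.na(m$sd_ra))) ""
              else sprintf("%.4f", m$sd_ra)
    writeLines(sprintf("%s\t%s\t%.4f\t%s", m$otu_id, m$taxonomy, m$mean_ra,
                       sd_col), con)
  }
  writeLines(sprintf("TOTAL\t\t%.4f\t", core$total_core_abundance), con)
  invisible(path)
}

#' Re-read a core-set report written by [write_core_report()]
#'
#' @param path file path.
#' @return a `core_set`. Abundances are recovered to the 4 decimal places
#'   the report prints.
#' @export
read_core_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  pick <- function(key) sub(paste0("^# ", key, ": "), "",
                            grep(paste0("^# ", key, ":"), hdr, value = TRUE)[1])
  method <- pick("method")
  group <- pick("group")
  params <- jsonlite::fromJSON(pick("params"))
  body <- lines[!grepl("^#", lines)]
  body <- body[-1]                                  # column header
  total_line <- grep("^TOTAL\t", body, value = TRUE)
  rows <- body[!grepl("^TOTAL\t", body) & nzchar(body)]
  if (length(rows) > 0) {
    parts <- do.call(rbind, strsplit(rows, "\t"))
    if (ncol(parts) < 4) parts <- cbind(parts, "")
    members <- data.frame(otu_id = parts[, 1], taxonomy = parts[, 2],
                          mean_ra = as.numeric(parts[, 3]),
                          sd_ra = suppressWarnings(as.numeric(parts[, 4])),
                          stringsAsFactors = FALSE)
    members$sd_ra[parts[, 4] == ""] <- NA_real_
  } else {
    members <- data.frame(otu_id = character(), taxonomy = character(),
                          mean_ra = numeric(), sd_ra = numeric(),
                          stringsAsFactors = FALSE)
  }
  core <- new_core_set(method = method, group = group, members = members,
                       params = as.list(params), sort_members = FALSE)
  reported_total <- as.numeric(strsplit(total_line[1], "\t")[[1]][3])
  if (abs(reported_total - core$total_core_abundance) > 5e-4)
    warning("report footer total differs from the sum of its rows")
  core
}
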