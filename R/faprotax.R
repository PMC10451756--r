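#' Parse a FAPROTAX-style taxonomy-to-function rule file
#'
#' The flat-file dialect: a function starts with a header line at column 0
#' (function name, then free-text metadata separated by whitespace); every
#' following indented line carries one taxon pattern; lines whose first
#' non-blank character is `#` are comments. An indented `add_group:NAME`
#' directive imports the (already resolved) clauses of a previously defined
#' function, so includes are acyclic by construction; referencing an
#' undefined function is an error. A function that ends up with no clauses
#' is dropped with a warning.
#'
#' @param path path of the rule file. The bundled miniature rule set
#'   covering common rhizosphere taxa is at [faprotax_mini_rules()].
#' @return an object of class `function_rules`: a named list of rules, each
#'   a list with `name`, `clauses` (character vector of patterns) and
#'   `metadata`.
#' @export
read_function_rules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rules <- list()
  current <- NULL
  flush_rule <- function(rules, current) {
    if (is.null(current)) return(rules)
    if (length(current$clauses) == 0) {
      warning("rule '", current$name, "' has no clauses; dropped")
      return(rules)
    }
    rules[[current$name]] <- current
    rules
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || grepl("^\\s*#", ln)) next
    if (grepl("^\\s", ln)) {                       # clause line
      if (is.null(current))
        stop("clause line before any function header: ", trimws(ln))
      clause <- trimws(ln)
      if (grepl("^add_group:", clause)) {
        ref <- trimws(sub("^add_group:", "", clause))
        if (ref == current$name)
          stop("rule '", current$name, "' includes itself")
        if (is.null(rules[[ref]]))
          stop("rule '", current$name, "' includes undefined function '",
               ref, "' (includes may only reference earlier rules)")
        current$clauses <- unique(c(current$clauses, rules[[ref]]$clauses))
      } else {
        current$clauses <- unique(c(current$clauses, clause))
      }
    } else {                                       # header line
      rules <- flush_rule(rules, current)
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      name <- toks[1]
      if (!is.null(rules[[name]]))
        stop("duplicate function name: ", name)
      current <- list(name = name,
                      clauses = character(0),
                      metadata = paste(toks[-1], collapse = " "))
    }
  }
  rules <- flush_rule(rules, current)
  structure(rules, class = "function_rules")
}

#' @export
print.function_rules <- function(x, ...) {
  cat(sprintf("%d function rule(s):\n", length(x)))
  for (r in x)
    cat(sprintf("  %-32s %d clause(s)\n", r$name, length(r$clauses)))
  invisible(x)
}

#' Path of the bundled miniature rule set
#'
#' A small, self-contained taxonomy-to-function rule file covering functions
#' common in rhizosphere soil surveys (chemoheterotrophy, fermentation,
#' nitrification, nitrogen fixation, denitrification, ureolysis, lytic
#' activities, methylotrophy, aromatic compound degradation, ...). It lets
#' every functional operation run without downloading the full FAPROTAX
#' database; the full database file is accepted by [read_function_rules()]
#' through the same parser.
#'
#' @return file path within the installed package.
#' @export
faprotax_mini_rules <- function() {
  system.file("extdata", "faprotax_mini.txt", package = "rhizocore",
              mustWork = TRUE)
}

# A clause matches a lineage when its wildcard pattern ("*" = any substring,
# allowed at either end or standing alone inside the pattern) matches the
# full semicolon path or any single rank name. Case-sensitive.
clause_matches <- function(clause, lin) {
  targets <- c(lin$raw, unname(lin$ranks[nzchar(lin$ranks)]))
  esc <- gsub("([^A-Za-z0-9_; -])", "\\\\\\1", clause)  # escape, incl. "*"
  rx <- paste0("^", gsub("\\\\\\*", ".*", esc), "$")    # restore wildcard
  any(grepl(rx, targets, perl = TRUE))
}

#' Assign OTUs to ecological functions by lineage matching
#'
#' An OTU is assigned to every function with at least one clause matching
#' its lineage. Functions are not mutually exclusive. OTUs whose lineage is
#' wholly unclassified receive no assignment: function prediction rests on
#' taxonomic identity, so unidentified organisms are excluded.
#'
#' @param lineages named list of `lineage` objects (see [read_taxonomy()]).
#' @param rules a `function_rules` object.
#' @return named list mapping each OTU id to a character vector of function
#'   names (possibly empty). The full set of rule names is attached as
#'   attribute `"functions"`.
#' @export
assign_functions <- function(lineages, rules) {
  stopifnot(inherits(rules, "function_rules") || length(rules) == 0)
  out <- lapply(lineages, function(lin) {
    if (is_unclassified(lin)) return(character(0))
    hit <- vapply(rules, function(r)
      any(vapply(r$clauses, clause_matches, logical(1), lin = lin)),
      logical(1))
    names(rules)[hit]
  })
  attr(out, "functions") <- if (length(rules)) unname(names(rules)) else character(0)
  out
}

#' Per-group functional profile
#'
#' For one group, the percentage of detected OTUs assigned to each function:
#' `pct_assigned = 100 * n_assigned / total_otus`, where `total_otus` counts
#' OTUs present in at least one of the group's samples. The statistic is
#' presence-based — abundance values play no role beyond detection.
#'
#' @param x an `abund_table`.
#' @param group group label.
#' @param assignments output of [assign_functions()].
#' @return object of class `functional_profile`: list with `group`,
#'   `total_otus` and `table` (data.frame `function_name`, `n_assigned`,
#'   `pct_assigned`, in rule order).
#' @export
functional_profile <- function(x, group, assignments) {
  stopifnot(inherits(x, "abund_table"))
  sams <- group_samples(x, group)
  detected <- rownames(x$values)[rowSums(x$values[, sams, drop = FALSE] > 0) > 0]
  if (length(detected) == 0)
    stop("no OTUs detected in group '", group, "'")
  fns <- attr(assignments, "functions")
  if (is.null(fns)) fns <- sort(unique(unlist(assignments)))
  sets <- assignments[detected]
  n_assigned <- vapply(fns, function(fn)
    sum(vapply(sets, function(s) !is.null(s) && fn %in% s, logical(1))),
    integer(1))
  structure(list(group = group, total_otus = length(detected),
                 table = data.frame(function_name = fns,
                                    n_assigned = unname(n_assigned),
                                    pct_assigned = 100 * unname(n_assigned) /
                                      length(detected),
                                    stringsAsFactors = FALSE, row.names = NULL)),
            class = "functional_profile")
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("functional profile, group %s (%d detected OTUs):\n",
              x$group, x$total_otus))
  print(x$table)
  invisible(x)
}

#' Compare a function's assignment percentage between two groups
#'
#' Tests the null hypothesis of equal assignment proportions for one
#' function in two groups. The default is Fisher's exact test on the 2x2
#' table (assigned / not assigned per group), exact at the small OTU counts
#' typical of desk-scale surveys; a two-proportion z-test (chi-square form,
#' no continuity correction) is available as an alternative.
#'
#' @param profile_a,profile_b `functional_profile` objects for the two
#'   groups. A function absent from a profile counts as 0 assigned.
#' @param function_name the function to compare.
#' @param method `"fisher"` (default) or `"prop_z"`.
#' @return one-row data.frame: `function_name`, per-group counts, totals and
#'   percentages, `p_value` (two-sided) and `method`.
#' @export
compare_function_groups <- function(profile_a, profile_b, function_name,
                                    method = c("fisher", "prop_z")) {
  method <- match.arg(method)
  stopifnot(inherits(profile_a, "functional_profile"),
            inherits(profile_b, "functional_profile"))
  n_of <- function(p) {
    i <- match(function_name, p$table$function_name)
    if (is.na(i)) 0L else p$table$n_assigned[i]
  }
  na <- n_of(profile_a); nb <- n_of(profile_b)
  ta <- profile_a$total_otus; tb <- profile_b$total_otus
  if (ta == 0 || tb == 0) stop("zero detected OTUs in one of the groups")
  p <- if (method == "fisher") {
    fisher.test(matrix(c(na, ta - na, nb, tb - nb), nrow = 2))$p.value
  } else {
    suppressWarnings(prop.test(c(na, nb), c(ta, tb), correct = FALSE)$p.value)
  }
  data.frame(function_name = function_name,
             group_a = profile_a$group, n_a = na, total_a = ta,
             pct_a = 100 * na / ta,
             group_b = profile_b$group, n_b = nb, total_b = tb,
             pct_b = 100 * nb / tb,
             p_value = p, method = method,
             stringsAsFactors = FALSE)
}

#' Write functional profiles to a tab-separated file
#'
#' @param profiles list of `functional_profile` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_functional_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(group = p$group, total_otus = p$total_otus, p$table)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
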