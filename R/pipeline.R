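#' Run the full core-microbiome pipeline from a single configuration
#'
#' Orchestrates the end-to-end analysis: read the abundance table, group map
#' and taxonomy; normalize counts to relative abundances; compute the
#' membership-based and composition-based core per group; compute
#' per-group functional profiles from a rule file and compare every function
#' between each pair of groups; compute overlap reports (membership core
#' between group pairs, and membership vs composition within each group).
#' All reports are written to `out_dir` as tab-separated files plus a
#' machine-readable `summary.json`.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   \describe{
#'     \item{abundance}{path of the abundance table (required).}
#'     \item{groups}{path of the sample-to-group map (required unless the
#'       table should be treated as one group).}
#'     \item{taxonomy}{path of the taxonomy map (optional).}
#'     \item{taxonomy_dialect}{`"plain_semicolon"` (default) or
#'       `"rank_prefixed"`.}
#'     \item{rules}{path of a function rule file (default: the bundled
#'       miniature rule set).}
#'     \item{out_dir}{output directory (required; created if absent).}
#'     \item{mode}{abundance mode override (optional).}
#'     \item{top_n}{membership top-N, default 10.}
#'     \item{sd_threshold}{SDRA threshold, default 0.01.}
#'     \item{threshold_scale}{`"percent"` (default) or `"proportion"`.}
#'     \item{sd_ddof}{SD convention, default 1.}
#'     \item{presence_epsilon}{detection floor, default 0.}
#'   }
#' @param quiet suppress progress messages (default `FALSE`).
#' @return the run summary, invisibly: a list with per-group core results
#'   (`n_members`, `total_core_abundance`, member ids), functional
#'   percentages per group, per-function between-group p-values, and overlap
#'   sizes. Any stage failure aborts with an error naming the stage.
#' @export
run_core_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(top_n = 10, sd_threshold = 0.01,
                   threshold_scale = "percent", sd_ddof = 1,
                   presence_epsilon = 0, taxonomy_dialect = "plain_semicolon",
                   rules = faprotax_mini_rules(), mode = NULL,
                   taxonomy = NULL, groups = NULL)
  config <- utils::modifyList(defaults, config)
  for (key in c("abundance", "out_dir"))
    if (is.null(config[[key]])) stop("config entry '", key, "' is required")
  for (key in c("abundance", "groups", "taxonomy", "rules"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config entry '", key, "' points to a missing file: ", config[[key]])
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[rhizocore] stage=%s %s", stage, sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tab <- stage("read_inputs", {
    x <- read_abundance_table(config$abundance, mode = config$mode,
                              groups = config$groups)
    if (nrow(x$values) == 0) stop("abundance table has no OTUs")
    x
  })
  taxonomy <- stage("read_inputs", {
    if (is.null(config$taxonomy)) NULL
    else read_taxonomy(config$taxonomy, dialect = config$taxonomy_dialect,
                       otu_ids = rownames(tab$values))
  })
  say("read_inputs", "otus=%d samples=%d", nrow(tab$values), ncol(tab$values))

  rel <- stage("normalize", to_relative(tab))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- table_groups(rel)

  cores <- list(membership = list(), composition = list())
  for (g in groups) {
    cores$membership[[g]] <- stage("membership_core", {
      core <- membership_core(rel, g, top_n = config$top_n,
                              taxonomy = taxonomy,
                              presence_epsilon = config$presence_epsilon)
      write_core_report(core, file.path(config$out_dir,
                                        sprintf("membership_%s.tsv", g)))
      core
    })
    say("membership_core", "group=%s n=%d", g,
        nrow(cores$membership[[g]]$members))
    if (length(group_samples(rel, g)) >= 2) {
      cores$composition[[g]] <- stage("composition_core", {
        core <- composition_core(rel, g, sd_threshold = config$sd_threshold,
                                 threshold_scale = config$threshold_scale,
                                 taxonomy = taxonomy,
                                 sd_ddof = config$sd_ddof,
                                 presence_epsilon = config$presence_epsilon)
        write_core_report(core, file.path(config$out_dir,
                                          sprintf("composition_%s.tsv", g)))
        core
      })
      say("composition_core", "group=%s n=%d", g,
          nrow(cores$composition[[g]]$members))
    }
  }

  profiles <- NULL
  comparisons <- NULL
  if (!is.null(taxonomy)) {
    rules <- stage("functional_profile", read_function_rules(config$rules))
    assignments <- stage("functional_profile",
                         assign_functions(taxonomy, rules))
    profiles <- stage("functional_profile",
                      setNames(lapply(groups, function(g)
                        functional_profile(rel, g, assignments)), groups))
    write_functional_profiles(profiles,
                              file.path(config$out_dir, "functional_profiles.tsv"))
    say("functional_profile", "groups=%d functions=%d", length(profiles),
        length(rules))
    if (length(groups) >= 2) {
      pairs <- utils::combn(groups, 2, simplify = FALSE)
      comparisons <- stage("compare_groups", do.call(rbind, lapply(pairs,
        function(pr) do.call(rbind, lapply(attr(assignments, "functions"),
          function(fn) compare_function_groups(profiles[[pr[1]]],
                                               profiles[[pr[2]]], fn))))))
      write.table(comparisons,
                  file.path(config$out_dir, "functional_comparisons.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  overlaps <- list()
  if (length(groups) >= 2) {
    for (pr in utils::combn(groups, 2, simplify = FALSE)) {
      key <- sprintf("membership_%s_vs_%s", pr[1], pr[2])
      overlaps[[key]] <- stage("overlap",
        core_overlap(cores$membership[[pr[1]]], cores$membership[[pr[2]]]))
      write_overlap_report(overlaps[[key]],
                           file.path(config$out_dir, paste0(key, ".tsv")))
    }
  }
  for (g in groups) {
    if (is.null(cores$composition[[g]])) next
    key <- sprintf("membership_vs_composition_%s", g)
    overlaps[[key]] <- stage("overlap",
      core_overlap(cores$membership[[g]], cores$composition[[g]]))
    write_overlap_report(overlaps[[key]],
                         file.path(config$out_dir, paste0(key, ".tsv")))
  }

  core_summary <- function(core) list(
    n_members = nrow(core$members),
    total_core_abundance = core$total_core_abundance,
    members = core$members$otu_id)
  summary <- list(
    n_otus = nrow(rel$values), n_samples = ncol(rel$values),
    groups = as.list(table(rel$groups)),
    membership = lapply(cores$membership, core_summary),
    composition = lapply(cores$composition, core_summary),
    functional = if (!is.null(profiles)) lapply(profiles, function(p)
      list(total_otus = p$total_otus,
           pct = setNames(as.list(p$table$pct_assigned),
                          p$table$function_name))),
    comparisons = if (!is.null(comparisons))
      lapply(seq_len(nrow(comparisons)), function(i) as.list(comparisons[i, ])),
    overlaps = lapply(overlaps, function(o)
      list(shared = o$shared, unique_a = o$unique_a, unique_b = o$unique_b)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done", "out_dir=%s", config$out_dir)
  invisible(summary)
}
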