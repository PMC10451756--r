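write_rules <- function(lines) {
  p <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("rule files parse: headers, clauses, comments, includes", {
  p <- write_rules(c("nitrification\telements:N", "\t*Nitrospira*"))
  rules <- read_function_rules(p)
  expect_length(rules, 1)
  expect_equal(rules[[1]]$name, "nitrification")
  expect_equal(rules[[1]]$clauses, "*Nitrospira*")

  expect_length(read_function_rules(write_rules(character(0))), 0)
  expect_length(read_function_rules(write_rules(c("# only a comment"))), 0)

  p2 <- write_rules(c("a\tmeta", "\t*X*", "b", "\tadd_group:a", "\t*Y*"))
  r2 <- read_function_rules(p2)
  expect_setequal(r2[["b"]]$clauses, c("*X*", "*Y*"))

  expect_error(read_function_rules(
    write_rules(c("a", "\tadd_group:zzz"))), "undefined function")
  expect_error(read_function_rules(
    write_rules(c("a", "\tadd_group:a"))), "includes itself")
  expect_warning(r3 <- read_function_rules(
    write_rules(c("empty_one", "real", "\t*Z*"))), "no clauses")
  expect_length(r3, 1)
  expect_error(read_function_rules(
    write_rules(c("a", "\t*X*", "a", "\t*Y*"))), "duplicate")
})

test_that("the bundled mini rule set parses and encodes known biology", {
  rules <- read_function_rules(faprotax_mini_rules())
  expect_gte(length(rules), 8)

  tax <- fixture_taxonomy()
  asg <- assign_functions(tax, rules)
  expect_true("nitrification" %in% asg[["OTU3"]])       # Nitrospira
  expect_setequal(asg[["OTU9"]],                        # Bradyrhizobium
                  c("nitrogen_fixation", "denitrification",
                    "aromatic_compound_degradation"))
  expect_true(all(c("aerobic_chemoheterotrophy", "chemoheterotrophy",
                    "aromatic_compound_degradation") %in% asg[["OTU2"]]))
  expect_true("photoheterotrophy" %in% asg[["OTU11"]])  # Rhodoplanes
})

test_that("clause matching is wildcard-aware, case-sensitive, rank-or-path", {
  rules <- structure(list(fn = list(name = "fn", clauses = "*Nitrospira*",
                                    metadata = "")),
                     class = "function_rules")
  hit <- parse_lineage("a", "Bacteria;Nitrospirae;Nitrospira")
  miss_case <- parse_lineage("b", "Bacteria;nitrospira")
  expect_equal(assign_functions(list(a = hit), rules)$a, "fn")
  expect_length(assign_functions(list(b = miss_case), rules)$b, 0)

  # full-path match without wildcard
  exact <- structure(list(fn = list(name = "fn",
                                    clauses = "Bacteria;Nitrospirae",
                                    metadata = "")),
                     class = "function_rules")
  lin <- parse_lineage("c", "Bacteria;Nitrospirae")
  expect_equal(assign_functions(list(c = lin), exact)$c, "fn")

  # unclassified lineages are never assigned
  uncl <- parse_lineage("d", "")
  wild <- structure(list(fn = list(name = "fn", clauses = "*", metadata = "")),
                    class = "function_rules")
  expect_length(assign_functions(list(d = uncl), wild)$d, 0)

  # empty rule list leaves everything unassigned
  none <- structure(list(), class = "function_rules")
  expect_length(assign_functions(list(a = hit), none)$a, 0)
})

test_that("adding rules only grows assignments; dropping wildcards only shrinks matches", {
  rules <- read_function_rules(faprotax_mini_rules())
  tax <- fixture_taxonomy()
  asg_all <- assign_functions(tax, rules)
  for (k in c(3, 7, 10)) {
    sub <- structure(rules[seq_len(k)], class = "function_rules")
    asg_sub <- assign_functions(tax, sub)
    for (id in names(tax))
      expect_true(all(asg_sub[[id]] %in% asg_all[[id]]))
  }

  with_wild <- structure(list(fn = list(name = "fn", clauses = "*Nitrospira*",
                                        metadata = "")),
                         class = "function_rules")
  without <- structure(list(fn = list(name = "fn", clauses = "Nitrospira",
                                      metadata = "")),
                       class = "function_rules")
  for (lin in tax) {
    m_wild <- length(assign_functions(list(x = lin), with_wild)$x) > 0
    m_plain <- length(assign_functions(list(x = lin), without)$x) > 0
    if (m_plain) expect_true(m_wild)
  }
})

test_that("functional profiles count detected OTUs, not abundance", {
  v <- rbind(c(10, 0, 0, 0), c(0, 5, 1, 0), c(2, 2, 2, 2), c(0, 0, 0, 90))
  dimnames(v) <- list(c("OTU1", "OTU2", "OTU3", "OTU4"),
                      sprintf("W%d", 1:4))
  x <- abundance_table(v, "counts", setNames(rep("W", 4), colnames(v)))
  rules <- structure(list(fermentation = list(name = "fermentation",
                                              clauses = "*Ferm*",
                                              metadata = "")),
                     class = "function_rules")
  tax <- list(OTU1 = parse_lineage("OTU1", "Bacteria;Fermenters"),
              OTU2 = parse_lineage("OTU2", "Bacteria;Other"),
              OTU3 = parse_lineage("OTU3", "Bacteria;Other"),
              OTU4 = parse_lineage("OTU4", "Bacteria;Other"))
  prof <- functional_profile(x, "W", assign_functions(tax, rules))
  expect_equal(prof$total_otus, 4)
  expect_equal(prof$table$pct_assigned, 25.0)           # 1 of 4 detected

  # abundance-invariance: scaling counts changes nothing
  x10 <- abundance_table(v * 13, "counts", x$groups)
  expect_equal(functional_profile(x10, "W", assign_functions(tax, rules))$table,
               prof$table)

  # multi-function OTUs count once per function
  rules2 <- structure(list(f1 = list(name = "f1", clauses = "*Ferm*",
                                     metadata = ""),
                           f2 = list(name = "f2", clauses = "*Ferm*",
                                     metadata = "")),
                      class = "function_rules")
  prof2 <- functional_profile(x, "W", assign_functions(tax, rules2))
  expect_equal(prof2$table$n_assigned, c(1L, 1L))
  expect_true(all(prof2$table$n_assigned <= prof2$total_otus))

  # no assignment at all -> all-zero percentages
  none <- assign_functions(tax, structure(list(), class = "function_rules"))
  expect_error(functional_profile(x, "nope", none), "unknown group")
})

test_that("group comparisons use an exact test matching enumeration", {
  mkprof <- function(group, n, total, fn = "fermentation") {
    structure(list(group = group, total_otus = total,
                   table = data.frame(function_name = fn, n_assigned = n,
                                      pct_assigned = 100 * n / total,
                                      stringsAsFactors = FALSE)),
              class = "functional_profile")
  }
  # identical proportions -> p = 1
  cmp <- compare_function_groups(mkprof("W", 5, 10), mkprof("L", 5, 10),
                                 "fermentation")
  expect_equal(cmp$p_value, 1.0)

  # 9/10 vs 1/10: p ~ 0.0011, matches the enumeration oracle
  cmp2 <- compare_function_groups(mkprof("W", 9, 10), mkprof("L", 1, 10),
                                  "fermentation")
  expect_equal(cmp2$p_value, oracle_fisher_p(9, 10, 1, 10), tolerance = 1e-10)
  expect_lt(cmp2$p_value, 0.005)

  # extreme split: smallest attainable p for the margins
  cmp3 <- compare_function_groups(mkprof("W", 0, 10), mkprof("L", 10, 10),
                                  "fermentation")
  expect_equal(cmp3$p_value, oracle_fisher_p(0, 10, 10, 10), tolerance = 1e-10)

  # a function absent from one profile counts as zero assigned
  cmp4 <- compare_function_groups(mkprof("W", 3, 10), mkprof("L", 2, 8, fn = "other"),
                                  "fermentation")
  expect_equal(cmp4$n_b, 0)

  # z-test alternative stays in [0, 1]
  cmp5 <- compare_function_groups(mkprof("W", 9, 10), mkprof("L", 1, 10),
                                  "fermentation", method = "prop_z")
  expect_true(cmp5$p_value >= 0 && cmp5$p_value <= 1)
})

test_that("Fisher p-values equal the enumeration oracle across small totals", {
  mkprof <- function(group, n, total) {
    structure(list(group = group, total_otus = total,
                   table = data.frame(function_name = "fn", n_assigned = n,
                                      pct_assigned = 100 * n / total,
                                      stringsAsFactors = FALSE)),
              class = "functional_profile")
  }
  set.seed(81)
  for (i in 1:120) {
    ta <- sample(2:50, 1); tb <- sample(2:50, 1)
    a <- sample(0:ta, 1); b <- sample(0:tb, 1)
    p_pkg <- compare_function_groups(mkprof("W", a, ta), mkprof("L", b, tb),
                                     "fn")$p_value
    expect_equal(p_pkg, oracle_fisher_p(a, ta, b, tb), tolerance = 1e-10,
                 info = sprintf("a=%d/%d b=%d/%d", a, ta, b, tb))
  }
})
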