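shared_table <- function(props_by_otu, group = "G") {
  # props_by_otu: named list otu_id -> vector of 4 proportions; a filler OTU
  # per sample absorbs the remainder so columns sum to 1
  m <- do.call(rbind, props_by_otu)
  fill <- diag(1 - colSums(m))
  v <- rbind(m, fill)
  rownames(v) <- c(names(props_by_otu), sprintf("FILL%d", seq_len(ncol(m))))
  colnames(v) <- sprintf("%s%d", group, seq_len(ncol(m)))
  abundance_table(v, mode = "proportion",
                  groups = setNames(rep(group, ncol(v)), colnames(v)))
}

test_that("membership core ranks shared OTUs by mean abundance", {
  x <- shared_table(list(A = rep(0.05, 4), B = rep(0.03, 4), C = rep(0.02, 4)))
  top2 <- membership_core(x, "G", top_n = 2)
  expect_equal(core_members(top2), c("A", "B"))
  expect_equal(top2$total_core_abundance, 8)   # percent scale: 5 + 3

  # nothing shared by all samples -> empty core
  v <- rbind(c(1, 0, 0.5, 0.5), c(0, 1, 0.5, 0.5))
  dimnames(v) <- list(c("A", "B"), sprintf("G%d", 1:4))
  none <- abundance_table(v, mode = "proportion",
                          groups = setNames(rep("G", 4), colnames(v)))
  empty <- membership_core(none, "G", top_n = 10)
  expect_equal(nrow(empty$members), 0)
  expect_equal(empty$total_core_abundance, 0)

  expect_error(membership_core(x, "G", top_n = 0), "top_n")
  expect_error(membership_core(x, "nope", 5), "unknown group")
})

test_that("ties in mean abundance break by numeric-aware OTU id", {
  x <- shared_table(list(OTU10 = rep(0.02, 4), OTU2 = rep(0.02, 4),
                         OTU1 = rep(0.05, 4)))
  expect_equal(core_members(membership_core(x, "G", 3)),
               c("OTU1", "OTU2", "OTU10"))
})

test_that("composition core keeps shared OTUs under the strict SDRA cut", {
  # sd 0 candidate is retained at any positive threshold
  x <- shared_table(list(A = rep(0.05, 4),
                         B = c(0.030, 0.010, 0.030, 0.010)))
  cc <- composition_core(x, "G", sd_threshold = 1e-6)
  expect_equal(core_members(cc), "A")

  # B's SDRA on percent scale: sd(c(3,1,3,1)) = 1.1547
  cc2 <- composition_core(x, "G", sd_threshold = 1.2)
  expect_equal(core_members(cc2), c("A", "B"))
  expect_equal(cc2$members$sd_ra[2], sd(c(3, 1, 3, 1)), tolerance = 1e-9)
  # strictness: threshold exactly at the SDRA excludes
  cc3 <- composition_core(x, "G", sd_threshold = sd(c(3, 1, 3, 1)))
  expect_equal(core_members(cc3), "A")

  # proportion-scale threshold statement
  cc4 <- composition_core(x, "G", sd_threshold = 0.012,
                          threshold_scale = "proportion")
  expect_equal(core_members(cc4), c("A", "B"))

  one <- abundance_table(matrix(1, 1, 1, dimnames = list("A", "S1")),
                         mode = "proportion",
                         groups = c(S1 = "G"))
  expect_error(composition_core(one, "G"), "single sample")
  expect_error(composition_core(x, "G", sd_threshold = 0), "sd_threshold")
})

test_that("raising top_n or the SDRA threshold never removes members", {
  set.seed(51)
  for (i in 1:20) {
    x <- random_proportion_table()
    prev_m <- character(0)
    for (k in c(1, 3, 5, 10)) {
      cur <- core_members(membership_core(x, "G", k))
      expect_true(all(prev_m %in% cur))
      prev_m <- cur
    }
    prev_c <- character(0)
    for (thr in c(0.5, 2, 5, 20)) {
      cur <- core_members(composition_core(x, "G", thr))
      expect_true(all(prev_c %in% cur))
      prev_c <- cur
    }
  }
})

test_that("cores are subsets of the shared-OTU set", {
  set.seed(61)
  for (i in 1:20) {
    x <- random_proportion_table()
    shared <- summarize_group(x, "G")
    shared <- shared$otu_id[shared$prevalence == 1]
    expect_true(all(core_members(membership_core(x, "G", 7)) %in% shared))
    expect_true(all(core_members(composition_core(x, "G", 3)) %in% shared))
  }
})

test_that("both core methods agree exactly with a brute-force oracle", {
  set.seed(71)
  for (i in 1:200) {
    x <- random_proportion_table(n_otu = 20, n_samp = 4)
    top_n <- sample(1:12, 1)
    thr <- runif(1, 0.1, 8)
    expect_identical(core_members(membership_core(x, "G", top_n)),
                     oracle_membership(x$values, colnames(x$values), top_n))
    expect_identical(core_members(composition_core(x, "G", thr)),
                     oracle_composition(x$values, colnames(x$values), thr))
  }
})

test_that("overlap partitions two core sets deterministically", {
  a <- fixture_core_set("table1")
  b <- fixture_core_set("table2")
  ov <- core_overlap(a, b)
  expect_setequal(ov$shared, c("OTU1", "OTU3", "OTU4", "OTU7"))
  # ordering: by descending abundance in the first set
  expect_equal(ov$shared, c("OTU1", "OTU3", "OTU7", "OTU4"))
  expect_setequal(c(ov$shared, ov$unique_a), core_members(a))
  expect_setequal(c(ov$shared, ov$unique_b), core_members(b))
  expect_length(intersect(ov$unique_a, ov$unique_b), 0)
  expect_equal(unname(ov$labels["OTU1"]), "Hyphomicrobiaceae")

  # identity: a vs a shares everything
  self <- core_overlap(a, a)
  expect_equal(self$shared, core_members(a))
  expect_length(self$unique_a, 0)
  expect_length(self$unique_b, 0)

  # the printed legume composition and membership cores share OTU11
  ov2 <- core_overlap(fixture_core_set("table4"), fixture_core_set("table2"))
  expect_true("OTU11" %in% ov2$shared)
  expect_equal(unname(ov2$labels["OTU11"]), "Rhodoplanes sp.")

  # empty inputs yield empty partitions
  empty <- new_core_set("membership", "W",
                        data.frame(otu_id = character(), taxonomy = character(),
                                   mean_ra = numeric(), sd_ra = numeric()))
  ov3 <- core_overlap(empty, empty)
  expect_length(ov3$shared, 0)
})
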