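# Independent brute-force oracles, deliberately written with explicit loops
# and first-principles formulas so they share no code path with the package.

oracle_group_summary <- function(values, sample_ids) {
  out <- data.frame(otu_id = rownames(values), mean_ra = NA_real_,
                    sd_ra = NA_real_, prevalence = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(values))) {
    xs <- as.numeric(values[i, sample_ids])
    n <- length(xs)
    m <- sum(xs) / n
    s <- if (n > 1) sqrt(sum((xs - m)^2) / (n - 1)) else 0
    out$mean_ra[i] <- 100 * m
    out$sd_ra[i] <- 100 * s
    out$prevalence[i] <- sum(xs > 0) / n
  }
  out
}

# numeric-aware id comparison, re-derived independently
oracle_id_sort <- function(ids) {
  key <- vapply(ids, function(id) {
    m <- regmatches(id, regexpr("[0-9]+$", id))
    num <- if (length(m)) as.numeric(m) else Inf
    sprintf("%s|%020.0f|%s", sub("[0-9]+$", "", id), num, id)
  }, character(1))
  ids[order(key)]
}

oracle_membership <- function(values, sample_ids, top_n) {
  s <- oracle_group_summary(values, sample_ids)
  cand <- s[s$prevalence == 1, , drop = FALSE]
  picked <- character(0)
  while (nrow(cand) > 0 && length(picked) < top_n) {
    best <- cand[cand$mean_ra == max(cand$mean_ra), "otu_id"]
    best <- oracle_id_sort(best)[1]
    picked <- c(picked, best)
    cand <- cand[cand$otu_id != best, , drop = FALSE]
  }
  picked
}

oracle_composition <- function(values, sample_ids, sd_threshold_pct) {
  s <- oracle_group_summary(values, sample_ids)
  keep <- s[s$prevalence == 1 & s$sd_ra < sd_threshold_pct, , drop = FALSE]
  keep <- keep[order(-keep$mean_ra,
                     match(keep$otu_id, oracle_id_sort(keep$otu_id))), ,
               drop = FALSE]
  keep$otu_id
}

# two-sided Fisher exact p by full hypergeometric enumeration over all 2x2
# tables with the observed margins, using binomial coefficients directly
oracle_fisher_p <- function(a, total_a, b, total_b) {
  m <- a + b
  denom <- choose(total_a + total_b, m)
  ks <- max(0, m - total_b):min(total_a, m)
  probs <- choose(total_a, ks) * choose(total_b, m - ks) / denom
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random proportion-mode table over a single 4-sample group, with a mix of
# ubiquitous and patchy OTUs (zeros included)
random_proportion_table <- function(n_otu = 20, n_samp = 4, group = "G") {
  v <- matrix(rexp(n_otu * n_samp), n_otu, n_samp)
  zero_mask <- matrix(runif(n_otu * n_samp) < 0.25, n_otu, n_samp)
  v[zero_mask] <- 0
  for (j in seq_len(n_samp)) if (sum(v[, j]) == 0) v[1, j] <- 1
  v <- sweep(v, 2, colSums(v), "/")
  ids <- sample(sprintf("OTU%d", seq_len(n_otu * 3)), n_otu)
  dimnames(v) <- list(ids, sprintf("%s%d", group, seq_len(n_samp)))
  abundance_table(v, mode = "proportion",
                  groups = setNames(rep(group, n_samp), colnames(v)))
}

random_counts_table <- function(n_otu = 15, n_samp = 4, group = "G",
                                lambda = 8) {
  v <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp)
  for (j in seq_len(n_samp)) if (sum(v[, j]) == 0) v[1, j] <- 1
  dimnames(v) <- list(sprintf("OTU%d", seq_len(n_otu)),
                      sprintf("%s%d", group, seq_len(n_samp)))
  abundance_table(v, mode = "counts",
                  groups = setNames(rep(group, n_samp), colnames(v)))
}
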