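# brute-force oracle: enumerate all 2^n Bernoulli sequences and sum the
# probability of sequences whose success count is no more probable than k's
enum_binomial_p <- function(k, n, p0 = 0.5) {
  counts <- rowSums(expand.grid(rep(list(0:1), n)))
  prob_seq <- p0^counts * (1 - p0)^(n - counts)
  count_prob <- vapply(0:n, function(j) sum(prob_seq[counts == j]), numeric(1))
  sum(count_prob[count_prob <= count_prob[k + 1] * (1 + 1e-7)])
}

# oracle: enumerate every 2x2 table with the observed margins
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_vals <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(a_vals, function(a) {
    b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
    exp(lchoose(r1, a) + lchoose(r2, c_) - lchoose(r1 + r2, c1))
  }, numeric(1))
  obs <- probs[a_vals == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("exact binomial agrees with full sequence enumeration", {
  expect_equal(exact_binomial(5, 10)$p_value, 1)
  expect_equal(exact_binomial(0, 10)$p_value, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(exact_binomial(10, 10)$p_value, exact_binomial(0, 10)$p_value)
  for (case in list(c(3, 12, 0.5), c(0, 9, 0.5), c(7, 11, 0.3), c(5, 12, 0.7),
                    c(2, 8, 0.5), c(6, 10, 0.25))) {
    expect_equal(exact_binomial(case[1], case[2], case[3])$p_value,
                 enum_binomial_p(case[1], case[2], case[3]),
                 tolerance = 1e-10,
                 label = paste("k", case[1], "n", case[2], "p", case[3]))
  }
})

test_that("Fisher exact agrees with table enumeration", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  sep <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(sep)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 6), 2))$p_value, 1) # zero margin
  set.seed(31)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab[1, ]) > 15 || sum(tab[2, ]) > 15) next
    expect_equal(fisher_exact_2x2(tab)$p_value, enum_fisher_p(tab),
                 tolerance = 1e-10, label = paste(tab, collapse = ","))
  }
  # odds ratio reported
  expect_equal(fisher_exact_2x2(matrix(c(8, 2, 4, 6), 2))$statistic,
               (8 * 6) / (2 * 4))
})

test_that("t tests match the reference implementation", {
  set.seed(7)
  x <- rnorm(12, 0.4); y <- rnorm(9, -0.1, 1.4)
  r1 <- one_sample_t(x, mu0 = 0.1)
  ref1 <- stats::t.test(x, mu = 0.1)
  expect_equal(r1$statistic, unname(ref1$statistic), tolerance = 1e-12)
  expect_equal(r1$p_value, ref1$p.value, tolerance = 1e-12)
  r2 <- two_sample_t(x, y)
  ref2 <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r2$p_value, ref2$p.value, tolerance = 1e-12)
  r3 <- two_sample_t(x, y, var_equal = FALSE)
  ref3 <- stats::t.test(x, y)
  expect_equal(r3$df, unname(ref3$parameter), tolerance = 1e-9)
  expect_error(one_sample_t(rep(2, 5), 2), "degenerate")
  # symmetric values about mu0 give t = 0, p = 1
  expect_equal(one_sample_t(c(-2, -1, 1, 2), 0)$p_value, 1)
})

test_that("ANOVA + Dunnett: F, single-contrast equivalence, ordering", {
  set.seed(11)
  g <- rep(c("ctrl", "a", "b"), each = 8)
  v <- rnorm(24) + rep(c(0, 1.2, -0.4), each = 8)
  res <- anova_dunnett(v, g, "ctrl", n_mc = 2e4, seed = 99)
  ref <- summary(stats::aov(v ~ g))[[1]]
  expect_equal(res$anova$statistic, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(res$anova$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  # adjusted p between raw p and Bonferroni
  for (cmp in res$comparisons) {
    expect_gte(cmp$adjusted_p, cmp$p_value - 1e-12)
    expect_lte(cmp$adjusted_p, min(1, 2 * cmp$p_value) + 0.02)
  }
  # with two groups only, Dunnett equals the two-sample t
  g2 <- rep(c("ctrl", "a"), each = 10)
  v2 <- rnorm(20) + rep(c(0, 0.8), each = 10)
  res2 <- anova_dunnett(v2, g2, "ctrl", n_mc = 1e5, seed = 12)
  tt <- two_sample_t(v2[g2 == "a"], v2[g2 == "ctrl"])
  expect_equal(res2$comparisons[["a"]]$adjusted_p, tt$p_value, tolerance = 0.01)
  # identical groups: F ~ 0, adjusted p ~ 1
  vid <- rep(c(1, 2, 3, 4), 3)
  gid <- rep(c("ctrl", "a", "b"), each = 4)
  resid_ <- anova_dunnett(vid, gid, "ctrl", n_mc = 1e4, seed = 5)
  expect_lt(resid_$anova$statistic, 1e-20)
  expect_gt(min(vapply(resid_$comparisons, `[[`, 1, "adjusted_p")), 0.99)
})

test_that("BH step-up matches hand-computed vectors and is idempotent", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.2)), c(0.015, 0.06, 0.2))
  set.seed(3)
  p <- runif(40)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  # idempotent at the decision level: thresholding the adjusted values
  # reproduces the step-up rejection set at any level
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    k_star <- max(c(0, which(sort(p) <= alpha * seq_along(p) / length(p))))
    reject <- p <= (if (k_star > 0) sort(p)[k_star] else -1)
    expect_equal(bh_adjust(p) <= alpha, reject)
  }
  # order preserved
  expect_equal(order(bh_adjust(p)[order(p)]), seq_along(p))
})

test_that("stats_table assembles a BH-adjusted family", {
  res <- list(a = exact_binomial(2, 20), b = exact_binomial(9, 20),
              c = fisher_exact_2x2(matrix(c(9, 1, 3, 7), 2)))
  tab <- stats_table(res)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_bh, bh_adjust(tab$p))
  expect_true(all(tab$p_bh >= tab$p - 1e-12))
})
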