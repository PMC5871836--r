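# Statistical battery: exact binomial and Fisher tests by small-probability
# summation, t tests, one-way ANOVA with Dunnett many-to-one comparisons
# (seeded Monte-Carlo critical values), and Benjamini-Hochberg adjustment.

#' Test result container
#'
#' @param test_name name of the test.
#' @param statistic test statistic (NA where none applies).
#' @param p_value two-tailed p-value.
#' @param df degrees of freedom, if any.
#' @param n sample size, if any.
#' @param ... further named fields (e.g. `estimate`, `comparison`, `seed`).
#' @return list of class `"test_result"`.
#' @export
test_result <- function(test_name, statistic, p_value, df = NA_real_,
                        n = NA_real_, ...) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, df = df, n = n), list(...)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test_name,
              x$statistic, x$p_value,
              if (!is.null(x$adjusted_p)) sprintf(" (adj %.4g)", x$adjusted_p)
              else ""))
  invisible(x)
}

#' Two-tailed exact binomial test
#'
#' Small-probability summation: the p-value is the total probability of
#' all outcomes whose point probability does not exceed that of the
#' observed count (the convention of standard exact-test implementations).
#'
#' @param k observed count of successes.
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @return a [test_result()].
#' @export
exact_binomial <- function(k, n, p0 = 0.5) {
  stopifnot(k >= 0, n >= k, p0 > 0, p0 < 1)
  d <- stats::dbinom(0:n, n, p0)
  rel <- 1 + 1e-7
  p <- min(1, sum(d[d <= d[k + 1] * rel]))
  test_result("exact binomial", statistic = k, p_value = p, n = n,
              estimate = k / n, p0 = p0)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the p-value sums the hypergeometric
#' probabilities of all tables no more probable than the observed one.
#' The sample odds ratio is reported.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return a [test_result()].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) {
    return(test_result("Fisher exact", statistic = unname(or), p_value = 1,
                       n = sum(tab)))
  }
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  x <- lo:hi
  d <- stats::dhyper(x, r1, r2, c1)
  rel <- 1 + 1e-7
  p <- min(1, sum(d[d <= d[x == tab[1, 1]] * rel]))
  test_result("Fisher exact", statistic = unname(or), p_value = p, n = sum(tab))
}

#' Two-tailed one-sample t test
#'
#' @param values numeric vector (length >= 2, nonzero variance).
#' @param mu0 null mean (default 0).
#' @return a [test_result()].
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate variance: all values identical")
  tstat <- (mean(values) - mu0) / (s / sqrt(n))
  test_result("one-sample t", statistic = tstat,
              p_value = 2 * stats::pt(-abs(tstat), n - 1), df = n - 1, n = n,
              estimate = mean(values))
}

#' Two-tailed two-sample t test
#'
#' Pooled-variance by default (`var_equal = TRUE`); Welch optional.
#'
#' @param a,b numeric vectors.
#' @param var_equal pooled-variance test? (default TRUE)
#' @return a [test_result()].
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("degenerate variance in both groups")
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mean(a) - mean(b)) / se
  test_result("two-sample t", statistic = tstat,
              p_value = 2 * stats::pt(-abs(tstat), df), df = df, n = na + nb,
              estimate = mean(a) - mean(b))
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' The omnibus F test plus Dunnett comparisons of every treatment group
#' against the control. Family-wise adjusted p-values use the joint null
#' distribution of the maximum absolute contrast statistic, evaluated by
#' seeded Monte-Carlo (group means drawn from the null, a shared pooled
#' variance draw per replicate).
#'
#' @param values numeric response vector.
#' @param group factor/character of group labels.
#' @param control label of the control group.
#' @param n_mc Monte-Carlo replicates (default 1e5).
#' @param seed RNG seed for the Monte-Carlo draw (recorded in results).
#' @return list with `anova` (a [test_result()]) and `comparisons` (list
#'   of [test_result()]s, one per treatment, with `adjusted_p`).
#' @export
anova_dunnett <- function(values, group, control, n_mc = 1e5, seed = 42L) {
  group <- as.character(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  labs <- unique(group)
  if (!control %in% labs) stop("control label not present")
  k <- length(labs)
  if (k < 2) stop("need at least two groups")
  ns <- vapply(labs, function(g) sum(group == g), numeric(1))
  if (any(ns < 2)) stop("need at least 2 observations per group")
  means <- vapply(labs, function(g) mean(values[group == g]), numeric(1))
  N <- length(values)
  sse <- sum((values - means[group])^2)
  df2 <- N - k
  mse <- sse / df2
  ssb <- sum(ns * (means - mean(values))^2)
  fstat <- (ssb / (k - 1)) / mse
  p_f <- stats::pf(fstat, k - 1, df2, lower.tail = FALSE)
  an <- test_result("one-way ANOVA F", statistic = fstat, p_value = p_f,
                    df = df2, n = N)
  treats <- setdiff(labs, control)
  n0 <- ns[control]
  tstats <- vapply(treats, function(g)
    (means[g] - means[control]) / sqrt(mse * (1 / ns[g] + 1 / n0)),
    numeric(1))
  # joint null of the contrast statistics by Monte-Carlo
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z0 <- stats::rnorm(n_mc, sd = sqrt(1 / n0))
  s2 <- stats::rchisq(n_mc, df2) / df2
  maxT <- rep(0, n_mc)
  for (g in treats) {
    zg <- stats::rnorm(n_mc, sd = sqrt(1 / ns[g]))
    Tg <- abs(zg - z0) / sqrt(s2 * (1 / ns[g] + 1 / n0))
    maxT <- pmax(maxT, Tg)
  }
  comps <- lapply(seq_along(treats), function(i) {
    raw <- 2 * stats::pt(-abs(tstats[i]), df2)
    adj <- mean(maxT >= abs(tstats[i]))
    test_result("Dunnett", statistic = unname(tstats[i]),
                p_value = raw, df = df2, n = ns[treats[i]] + n0,
                adjusted_p = max(adj, raw), seed = seed,
                comparison = paste(treats[i], "vs", control))
  })
  names(comps) <- treats
  list(anova = an, comparisons = comps)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving FDR adjustment with enforced monotonicity; idempotent.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE, na.last = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj[is.na(p)] <- NA
  adj
}

#' Assemble a stats summary table
#'
#' One row per test with BH adjustment applied within the declared family.
#'
#' @param results named list of [test_result()]s forming one comparison
#'   family.
#' @return data.frame with test, comparison, statistic, df, n, p and
#'   BH-adjusted p columns.
#' @export
stats_table <- function(results) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, test = r$test_name,
               statistic = r$statistic, df = r$df, n = r$n,
               p = r$p_value, stringsAsFactors = FALSE)
  }))
  df$p_bh <- bh_adjust(df$p)
  df
}
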