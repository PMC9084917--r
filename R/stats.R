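#' Spearman rank correlation (tie-aware)
#'
#' Pearson correlation of mid-ranks. Returns `NA` with a warning when either
#' vector is constant — e.g. a decoy ensemble sampled so tightly that the
#' criterion cannot distinguish good from bad decoys — rather than erroring.
#'
#' @param a,b equal-length numeric vectors, length >= 3.
#' @return rho in [-1, 1], or `NA`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) abort("inputs must have equal length")
  if (length(a) < 3) abort("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warn("constant input: Spearman correlation undefined (returning NA)")
    return(NA_real_)
  }
  stats::cor(rank(a), rank(b))
}

# exact null distribution of the signed-rank statistic W+ for given
# (possibly tied, mid-) ranks: DP convolution over doubled ranks.
signrank_exact_p <- function(w, ranks, alternative) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  poly <- c(1, numeric(total))          # coefficients over 2*W = 0..total
  for (r in r2) {
    shifted <- c(numeric(r), poly[seq_len(total + 1 - r)])
    poly <- poly + shifted
  }
  prob <- poly / 2^length(r2)
  w2 <- round(2 * w)
  p_ge <- sum(prob[(w2 + 1):(total + 1)])
  p_le <- sum(prob[1:(w2 + 1)])
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are dropped (standard matched-pairs convention); the null
#' distribution is exact — computed by enumeration over sign patterns of the
#' (mid-)ranks, which also covers tied absolute differences — for n <= 25,
#' and a tie-corrected normal approximation with continuity correction is
#' used above that.
#'
#' @param x paired differences, or first sample if `y` given.
#' @param y optional second sample (`x - y` is tested).
#' @param alternative `"greater"` (differences > 0), `"less"`, or
#'   `"two_sided"`.
#' @param exact_max largest n for which the exact null is used.
#' @return list with `statistic` (W+, sum of positive-difference ranks),
#'   `p_value`, `n` (non-zero differences), and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("greater", "less", "two_sided"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) abort("all differences are zero")
  if (n < 5) warn("fewer than 5 non-zero differences: test has little power")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signrank_exact_p(w, r, alternative)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    p <- switch(alternative,
      greater = pnorm((w - mu - cc) / sqrt(sigma2), lower.tail = FALSE),
      less = pnorm((w - mu + cc) / sqrt(sigma2)),
      two_sided = min(1, 2 * pnorm((abs(w - mu) - cc) / sqrt(sigma2),
                                   lower.tail = FALSE))
    )
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p_value = p, n = n, method = method,
       alternative = alternative)
}

#' Paired t-test on per-target differences
#'
#' Standard paired t-test (wraps the base implementation). Errors when the
#' differences have zero variance — identical selections cannot be tested.
#'
#' @param x paired differences, or first sample if `y` given.
#' @param y optional second sample.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"`.
#' @return list with `statistic` (t), `p_value`, `df`, `alternative`.
#' @export
paired_t <- function(x, y = NULL, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  if (length(d) < 2) abort("need at least 2 pairs")
  if (stats::sd(d) == 0) abort("zero-variance differences: paired t undefined")
  ht <- stats::t.test(d, alternative = sub("two_sided", "two.sided", alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), alternative = alternative)
}
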