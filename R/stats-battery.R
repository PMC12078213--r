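# Condition-comparison statistical battery: paired/unpaired t tests with an
# a-priori one-tailed rule and Shapiro-Wilk gating, Wilcoxon signed-rank and
# rank-sum tests, and the exact binomial "coin-flip" sign test.

#' Exact binomial coin-flip (sign) test
#'
#' Probability of observing at least \code{n_concordant} paired differences
#' with the hypothesized sign out of \code{n_total} informative pairs under
#' a fair coin: \code{p = sum_{k=N}^{M} C(M,k) / 2^M}. All intermediate
#' quantities are integers below 2^53, so the double-precision result is
#' exact.
#'
#' @param n_concordant number of "heads" N (effects with the expected sign)
#' @param n_total number of "tosses" M (paired comparisons)
#' @return upper-tail probability
#' @examples
#' binomial_coinflip(17, 17)  # 7.6e-6
#' binomial_coinflip(10, 13)  # 0.0461
#' @export
binomial_coinflip <- function(n_concordant, n_total) {
  stopifnot(length(n_concordant) == 1, length(n_total) == 1)
  if (n_concordant != round(n_concordant) || n_total != round(n_total) ||
      n_total < 1 || n_concordant < 0) {
    stop("n_concordant and n_total must be non-negative integers")
  }
  if (n_concordant > n_total) stop("n_concordant exceeds n_total")
  sum(choose(n_total, n_concordant:n_total)) / 2^n_total
}

#' Paired t test with a-priori one-tailed rule
#'
#' Standard paired t on \code{a - b}. When \code{tails = 1} and the sign of
#' the observed mean difference matches \code{a_priori_sign}, the one-tailed
#' p is reported; otherwise the two-tailed p is used (a one-tailed test is
#' only licensed by an a-priori directional hypothesis that the data agree
#' with).
#'
#' @param a,b paired samples; pairs with any NA are dropped
#' @param tails 1 or 2
#' @param a_priori_sign expected sign of mean(a - b) (+1 or -1); required
#'   when \code{tails = 1}
#' @return list(t, df, p, p_one_tailed, p_two_tailed, tails_used, mean_diff)
#' @export
paired_t <- function(a, b, tails = 2, a_priori_sign = NULL) {
  stopifnot(length(a) == length(b), tails %in% c(1, 2))
  keep <- is.finite(a) & is.finite(b)
  d <- a[keep] - b[keep]
  n <- length(d)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(d) == 0) stop("zero variance of paired differences")
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  df <- n - 1
  p2 <- 2 * stats::pt(-abs(tstat), df)
  p1 <- stats::pt(-abs(tstat), df)
  use_one <- tails == 1 && !is.null(a_priori_sign) &&
    sign(mean(d)) == sign(a_priori_sign)
  list(t = tstat, df = df, p = if (use_one) p1 else p2,
       p_one_tailed = p1, p_two_tailed = p2,
       tails_used = if (use_one) 1L else 2L, mean_diff = mean(d), n = n)
}

#' Unpaired (Welch) t test with the same one-tailed rule
#' @inheritParams paired_t
#' @return list(t, df, p, tails_used, mean_diff)
#' @export
unpaired_t <- function(a, b, tails = 2, a_priori_sign = NULL) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tstat <- unname(tt$statistic); df <- unname(tt$parameter)
  p2 <- tt$p.value; p1 <- p2 / 2
  use_one <- tails == 1 && !is.null(a_priori_sign) &&
    sign(mean(a) - mean(b)) == sign(a_priori_sign)
  list(t = tstat, df = df, p = if (use_one) p1 else p2,
       p_one_tailed = p1, p_two_tailed = p2,
       tails_used = if (use_one) 1L else 2L, mean_diff = mean(a) - mean(b))
}

#' Shapiro-Wilk normality gate
#'
#' @param x sample (typically paired differences)
#' @param alpha gate level (default 0.05)
#' @return list(p, normal); \code{normal} is TRUE when p > alpha, meaning a
#'   downstream t test needs no asterisk flag
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("need at least 3 values")
  if (stats::sd(x) == 0) stop("constant input")
  p <- stats::shapiro.test(x)$p.value
  list(p = p, normal = p > alpha)
}

#' Wilcoxon signed-rank test (signed-W convention)
#'
#' Reports W = (sum of positive ranks) - (sum of negative ranks) of the
#' paired differences, so |W| <= n(n+1)/2. The two-sided p is exact (via the
#' signed-rank distribution) for n <= 25 without ties, and uses the normal
#' approximation with tie correction otherwise. Zero differences are dropped.
#'
#' @param a,b paired samples
#' @return list(W, n, p, exact)
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need at least 5 non-zero paired differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- w_pos - w_neg
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # psignrank is the exact distribution of the positive-rank sum V
    v <- w_pos
    p_lo <- stats::psignrank(v, n)
    p_hi <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_pos - mu - 0.5 * sign(w_pos - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(W = W, n = n, p = p, exact = exact)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' U is reported for the first sample: the number of pairs (i, j) with
#' a_i > b_j (+ half the ties). Exact p without ties for small samples,
#' otherwise a tie-corrected normal approximation.
#'
#' @param a,b independent samples
#' @return list(U, n1, n2, p, exact)
#' @export
rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 3 || n2 < 3) stop("need n >= 3 per group")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 <= 50 && n2 <= 50) {
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    ntot <- n1 + n2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 *
      (ntot + 1 - sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1)))
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(U = U, n1 = n1, n2 = n2, p = p, exact = exact)
}

# metrics for which "better" is ill-defined: always two-tailed
TWO_TAILED_METRICS <- c("direction_anisotropy", "direction_asymmetry",
                        "saccade_dispersion_deg", "ms_slope_hz",
                        "ms_intercept_deg_s")

# expected sign of (reference - comparison) difference under the a-priori
# hypothesis that the comparison (binocular or dominant) condition performs
# better: +1 means the metric is expected to DECREASE in the better
# condition (e.g. latency), -1 means increase (e.g. gain).
METRIC_BETTER_SIGN <- c(
  latency_ms = +1, accel_deg_s2 = -1, gain = -1, direction_noise_deg = +1,
  speed_noise_pct = +1, direction_anisotropy = NA, direction_asymmetry = NA,
  speed_responsiveness = -1, saccade_rate_hz = +1, saccade_amplitude_deg = +1,
  saccade_dispersion_deg = NA, proportion_smooth = -1,
  contraction_tau_ms = +1, dilation_tau_ms = +1, pupil_diameter_mm = +1,
  ms_slope_hz = NA, ms_intercept_deg_s = NA, fixation_error_deg = +1)

#' Compare one metric between two conditions
#'
#' Runs the full battery on per-subject values of one oculometric under a
#' reference condition A and a comparison condition B: paired t (one-tailed
#' when the a-priori sign agrees with the data and the metric has a defined
#' direction of superiority), Shapiro-Wilk gate on the differences, Wilcoxon
#' signed-rank, and the exact binomial sign test. Metrics with missing
#' values on either side (the pupil time constants when blinks obscured the
#' measurement) switch to unpaired tests (Welch t and rank-sum) on the
#' available values.
#'
#' @param metric metric name (one of the 18 oculometric field names)
#' @param a,b per-subject values under condition A (reference, e.g.
#'   monocular) and B (comparison, e.g. binocular)
#' @param force_unpaired use unpaired tests regardless of missingness
#' @return one-row data.frame (a ComparisonResult)
#' @export
compare_metric <- function(metric, a, b, force_unpaired = FALSE) {
  stopifnot(length(a) == length(b))
  two_tailed <- metric %in% TWO_TAILED_METRICS ||
    is.na(METRIC_BETTER_SIGN[metric])
  # a-priori sign of mean(a - b): reference minus better condition
  sgn <- if (two_tailed) NULL else unname(METRIC_BETTER_SIGN[metric])
  complete <- is.finite(a) & is.finite(b)
  unpaired <- force_unpaired || sum(complete) < length(a[is.finite(a)]) ||
    sum(complete) < length(b[is.finite(b)])
  tails <- if (two_tailed) 2 else 1

  degenerate_t <- list(t = 0, df = sum(complete) - 1, p = 1,
                       p_one_tailed = 0.5, p_two_tailed = 1,
                       tails_used = 2L, mean_diff = 0)
  if (!unpaired) {
    tt <- tryCatch(paired_t(a, b, tails = tails, a_priori_sign = sgn),
                   error = function(e) degenerate_t)
    sw <- tryCatch(shapiro_gate(a[complete] - b[complete]),
                   error = function(e) list(p = NA_real_, normal = TRUE))
    wx <- tryCatch(wilcoxon_signed_rank(a, b),
                   error = function(e) list(W = 0, p = 1))
    wstat <- wx$W; wp <- wx$p; wtype <- "signed_rank"
  } else {
    tt <- tryCatch(unpaired_t(a, b, tails = tails, a_priori_sign = sgn),
                   error = function(e) degenerate_t)
    sw <- tryCatch(shapiro_gate(c(a[is.finite(a)] - mean(a, na.rm = TRUE),
                                  b[is.finite(b)] - mean(b, na.rm = TRUE))),
                   error = function(e) list(p = NA_real_, normal = NA))
    wx <- tryCatch(rank_sum(a, b), error = function(e) list(U = 0, p = 1))
    wstat <- wx$U; wp <- wx$p; wtype <- "rank_sum"
  }

  d <- a[complete] - b[complete]
  n_info <- sum(d != 0)
  if (!two_tailed && n_info > 0) {
    n_conc <- sum(sign(d[d != 0]) == sgn)
  } else {
    # without an a-priori direction, count the majority side
    n_conc <- if (n_info > 0) max(sum(d > 0), sum(d < 0)) else 0L
  }
  p_binom <- if (n_info > 0) binomial_coinflip(n_conc, n_info) else 1

  ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
  data.frame(
    metric = metric, n = sum(complete),
    mean_a = ma, sd_a = stats::sd(a, na.rm = TRUE),
    mean_b = mb, sd_b = stats::sd(b, na.rm = TRUE),
    median_a = stats::median(a, na.rm = TRUE),
    median_b = stats::median(b, na.rm = TRUE),
    t = tt$t, df = tt$df, p_t = tt$p, p_t_two_tailed = tt$p_two_tailed,
    tails = tt$tails_used,
    shapiro_p = sw$p, normal = sw$normal, flagged = !isTRUE(sw$normal),
    wilcoxon_type = wtype, wilcoxon_stat = wstat, p_wilcoxon = wp,
    n_concordant = n_conc, n_informative = n_info, p_binomial = p_binom,
    percent_difference = 100 * (ma - mb) / ma,
    unpaired = unpaired,
    stringsAsFactors = FALSE)
}

#' Compare two viewing conditions across all oculometrics
#'
#' @param tab_a,tab_b data.frames of per-subject oculometric values (one row
#'   per subject, one column per metric; rows aligned by subject) for the
#'   reference and comparison condition
#' @param metrics metric columns to compare (default: the intersection of
#'   both tables with the 18 canonical metric names)
#' @return data.frame of ComparisonResult rows
#' @export
compare_conditions <- function(tab_a, tab_b, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- intersect(names(METRIC_BETTER_SIGN),
                         intersect(names(tab_a), names(tab_b)))
  }
  stopifnot(nrow(tab_a) == nrow(tab_b), length(metrics) > 0)
  if (nrow(tab_a) < 3) stop("need at least 3 subjects")
  out <- lapply(metrics, function(m) {
    force_unp <- m %in% c("contraction_tau_ms", "dilation_tau_ms") &&
      (anyNA(tab_a[[m]]) || anyNA(tab_b[[m]]))
    tryCatch(compare_metric(m, tab_a[[m]], tab_b[[m]],
                            force_unpaired = force_unp),
             error = function(e) NULL)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
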