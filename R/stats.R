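# Rank-based statistics for the per-participant RMSE tables: summaries,
# the exact Wilcoxon signed-rank test (paired sphere vs. cross within
# participants) and the exact Mann-Whitney rank-sum test (two independent
# columns). Exact p-values are computed by enumeration, so they remain valid
# at the study's tiny sample sizes where normal approximations are not.

#' Labelled paired RMSE samples
#'
#' @param a,b numeric vectors of RMSE values [mm], non-negative.
#' @param labels length-2 character, e.g. `c("sphere", "cross")`.
#' @param paired TRUE when values are per-participant pairs (equal lengths).
#' @export
paired_samples <- function(a, b, labels = c("sphere", "cross"), paired = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0) || any(b < 0)) stop("RMSE values must be non-negative")
  if (paired && length(a) != length(b))
    stop("paired samples must have equal lengths")
  structure(list(a = a, b = b, labels = labels, paired = paired),
            class = "paired_samples")
}

#' Summary statistics (mean, sample sd, variance, range)
#'
#' @param values numeric vector, n >= 1.
#' @return object of class `summary_stats` with `mean`, `sd`, `variance`,
#'   `min`, `max`, `n` (sd/variance are NA for n = 1).
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input")
  s <- if (length(values) > 1L) stats::sd(values) else NA_real_
  structure(list(mean = mean(values), sd = s,
                 variance = if (is.na(s)) NA_real_ else s^2,
                 min = min(values), max = max(values), n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.4f (range %.4f-%.4f), sd %.4f, variance %.4f, n = %d\n",
              x$mean, x$min, x$max, x$sd, x$variance, x$n))
  invisible(x)
}

#' Table-style "Mean (range)" string
#'
#' @param values numeric vector.
#' @param digits decimals (tables use 2, rounding half-up).
#' @export
mean_range_label <- function(values, digits = 2L) {
  s <- summarize_values(values)
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  sprintf("%s (%s-%s)", fmt(s$mean), fmt(s$min), fmt(s$max))
}

# signed-rank statistic W+ with average ranks on |d|
signed_rank_stat <- function(d) {
  r <- rank(abs(d))
  sum(r[d > 0])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' `W_plus` is the sum of the ranks of positive differences `a - b`
#' (average ranks for tied magnitudes). Exact p-values enumerate all `2^n`
#' sign assignments of the observed rank magnitudes — valid with ties;
#' otherwise a normal approximation with continuity correction and
#' tie-corrected variance is used. Two-sided p doubles the smaller tail,
#' capped at 1.
#'
#' @param samples a [paired_samples] object, or numeric vector `a`.
#' @param b numeric vector when `samples` is a plain vector.
#' @param zero_policy `"drop"` (classic: discard zero differences) or
#'   `"pratt"` (rank zeros, then discard their ranks from both tails).
#' @param mode `"auto"` (exact iff n_effective <= 20), `"exact"`, or
#'   `"normal_approx"`.
#' @return list with `W_plus`, `p_two_sided`, `n_effective`, `mode`.
#' @export
wilcoxon_signed_rank <- function(samples, b = NULL,
                                 zero_policy = c("drop", "pratt"),
                                 mode = c("auto", "exact", "normal_approx")) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  if (inherits(samples, "paired_samples")) {
    stopifnot(samples$paired)
    d <- samples$a - samples$b
  } else {
    stopifnot(length(samples) == length(b))
    d <- as.numeric(samples) - as.numeric(b)
  }
  if (all(d == 0))
    stop(structure(class = c("fiducialign_undefined_test", "error", "condition"),
                   list(message = "all paired differences are zero; signed-rank test undefined",
                        call = sys.call())))
  if (zero_policy == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    ranks_all <- r
  } else {
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    ranks_all <- r[d != 0]     # zeros contribute to ranking, not to tails
  }
  n_eff <- length(ranks_all)
  use_exact <- switch(mode, exact = TRUE, normal_approx = FALSE,
                      auto = n_eff <= 20L)
  if (use_exact) {
    if (n_eff > 24L) stop("exact enumeration limited to n_effective <= 24")
    # distribution of W+ over all sign assignments of the observed ranks
    probs <- c(1)
    vals <- c(0)
    for (rk in ranks_all) {
      vals2 <- c(vals, vals + rk)
      probs2 <- c(probs, probs) / 2
      o <- order(vals2)
      vals2 <- vals2[o]; probs2 <- probs2[o]
      grp <- cumsum(!duplicated(vals2))
      vals <- vals2[!duplicated(vals2)]
      probs <- as.vector(rowsum(probs2, grp))
    }
    eps <- 1e-9
    p_le <- sum(probs[vals <= w_plus + eps])
    p_ge <- sum(probs[vals >= w_plus - eps])
    p <- min(1, 2 * min(p_le, p_ge))
    used <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    ties <- table(ranks_all)
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    used <- "normal_approx"
  }
  list(W_plus = w_plus, p_two_sided = p, n_effective = n_eff, mode = used)
}

#' Exact Mann-Whitney rank-sum test
#'
#' `U` for group `a` with average ranks on ties; the exact two-sided p-value
#' enumerates all `choose(n_a + n_b, n_a)` assignments of the observed
#' pooled values to the two groups (valid with ties).
#'
#' @param a,b numeric vectors; exact mode requires `n_a + n_b <= 20`.
#' @return list with `U`, `p_two_sided`, `n_a`, `n_b`.
#' @export
mann_whitney_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  if (na + nb > 20L)
    stop("exact enumeration limited to n_a + n_b <= 20; use a normal approximation for larger samples")
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  p <- min(1, 2 * min(p_le, p_ge))
  list(U = u_obs, p_two_sided = p, n_a = na, n_b = nb)
}

#' Repetition (replicate) analysis of workflow RMSE
#'
#' Summary of a vector of replicate RMSE values (the tenfold-repetition
#' design), reporting the variance explicitly alongside mean, sd and range.
#'
#' @param rmse_values numeric vector, n >= 2.
#' @return a `summary_stats` object.
#' @export
repetition_analysis <- function(rmse_values) {
  if (length(rmse_values) < 2L)
    stop("repetition analysis needs at least 2 replicates")
  summarize_values(rmse_values)
}

#' Packaged per-participant RMSE tables
#'
#' The two study tables shipped as CSV fixtures: `"scannability"`
#' (original vs. scanned geometry, n = 5) and `"in_face"` (geometries within
#' the facial scan, n = 10), columns `participant`, `rmse_sphere`,
#' `rmse_cross`.
#'
#' @param which `"scannability"` or `"in_face"`.
#' @return data.frame.
#' @export
load_rmse_table <- function(which = c("scannability", "in_face")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "scannability") "table1_scannability_rmse.csv"
                   else "table2_inface_rmse.csv",
                   package = "fiducialign", mustWork = TRUE)
  utils::read.csv(f)
}
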