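#' Force-rank detectors within each sample
#'
#' Each detector is ranked within its sample on the analog abundance readout
#' (Ct): rank 1 = lowest Ct = most abundant. All ties -- in particular the
#' block of censored detectors sitting at the detection limit -- receive the
#' same rank. The default mid-rank (mean of the occupied positions) keeps
#' the per-sample rank sum at D(D+1)/2; `"max"` assigns the largest occupied
#' position instead.
#'
#' Ranks are invariant to adding any constant to all Cts of a sample, which
#' is what makes the downstream test free of loading/efficiency assumptions.
#'
#' @param ct a [ct_matrix]
#' @param ties `"average"` (mid-rank, default) or `"max"`
#' @return object of class `rank_matrix`: list with `rank` (matrix, same
#'   dimnames as the input) and `censored` (carried through)
#' @export
rank_within_samples <- function(ct, ties = c("average", "max")) {
  ties <- match.arg(ties)
  stopifnot(inherits(ct, "ct_matrix"))
  rk <- apply(ct$ct, 2, rank, ties.method = ties)
  dimnames(rk) <- dimnames(ct$ct)
  structure(list(rank = rk, censored = ct$censored), class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("rank_matrix: %d detectors x %d samples\n", nrow(x$rank), ncol(x$rank)))
  invisible(x)
}

#' Rank-difference test between two groups
#'
#' For each detector, compares per-sample ranks between the two design groups
#' with an unequal-variance (Welch) t-test. The reported effect is
#' `rank_diff = mean rank(reference) - mean rank(case)`; with rank 1 = most
#' abundant, a positive rank difference means the detector is induced in the
#' case group.
#'
#' Degenerate inputs follow the documented conventions of [welch_t()]: both
#' groups constant with equal means gives p = 1.
#'
#' @param ranks a `rank_matrix` from [rank_within_samples()]
#' @param design a two-group [study_design]
#' @param reference_group label of the reference (control) group
#' @return data.frame: detector, mean_rank_ref, mean_rank_case, rank_diff,
#'   t, df, p, censored_frac
#' @export
rank_diff_test <- function(ranks, design, reference_group) {
  stopifnot(inherits(ranks, "rank_matrix"), inherits(design, "study_design"))
  grp <- split_contrast(design, reference_group)
  miss <- setdiff(c(grp$ref, grp$case), colnames(ranks$rank))
  if (length(miss)) stop("samples missing from rank matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  a <- ranks$rank[, grp$ref, drop = FALSE]
  b <- ranks$rank[, grp$case, drop = FALSE]
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    w <- welch_t(a[i, ], b[i, ])
    c(w$t, w$df, w$p)
  }, numeric(3)))
  data.frame(
    detector = rownames(ranks$rank),
    mean_rank_ref = rowMeans(a),
    mean_rank_case = rowMeans(b),
    rank_diff = rowMeans(a) - rowMeans(b),
    t = res[, 1], df = res[, 2], p = res[, 3],
    censored_frac = rowMeans(ranks$censored[, c(grp$ref, grp$case), drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Spearman rank correlation of two mean-rank profiles
#'
#' Pearson correlation of mid-rank re-ranked values; a constant vector has no
#' defined rank correlation and yields `NA`.
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @return Spearman's rho in `[-1, 1]`, or `NA`
#' @export
spearman_concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Rank-rank regression with prediction-interval outlier calls
#'
#' Fits ordinary least squares of case mean ranks on control mean ranks and
#' flags detectors falling strictly outside a band around the fit.
#' `"pointwise_pi"` is the proper prediction interval
#' `yhat(x0) +/- t * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)`;
#' `"parallel"` uses the constant half-width `t * s`, mirroring the familiar
#' parallel-line presentation of rank-rank scatter plots. A perfectly
#' collinear cloud gives a zero-width band in which only points off the line
#' are outliers.
#'
#' @param x control-group mean ranks (named by detector)
#' @param y case-group mean ranks
#' @param level coverage probability (default 0.95)
#' @param band `"pointwise_pi"` (default) or `"parallel"`
#' @return object of class `concordance_result`: list with `slope`,
#'   `intercept`, `residual_sd`, `spearman_rho`, `band` (data.frame detector,
#'   x, y, fit, lower, upper, outlier) and `outliers` (detector ids)
#' @export
prediction_interval_outliers <- function(x, y, level = 0.95,
                                         band = c("pointwise_pi", "parallel")) {
  band <- match.arg(band)
  stopifnot(length(x) == length(y), length(x) >= 4, level > 0, level < 1)
  det <- names(x)
  if (is.null(det)) det <- paste0("d", seq_along(x))
  n <- length(x)
  fit <- stats::lm(y ~ x)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  s <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  tcrit <- stats::qt((1 + level) / 2, df = n - 2)
  yhat <- a + b * x
  half <- if (band == "pointwise_pi") {
    Sxx <- sum((x - mean(x))^2)
    tcrit * s * sqrt(1 + 1 / n + (x - mean(x))^2 / Sxx)
  } else {
    rep(tcrit * s, n)
  }
  lower <- yhat - half
  upper <- yhat + half
  out <- y < lower | y > upper   # strictly outside
  res <- data.frame(detector = det, x = unname(x), y = unname(y),
                    fit = unname(yhat), lower = unname(lower),
                    upper = unname(upper), outlier = unname(out),
                    stringsAsFactors = FALSE)
  structure(
    list(slope = b, intercept = a, residual_sd = s,
         spearman_rho = spearman_concordance(x, y),
         level = level, band_type = band,
         band = res, outliers = det[out]),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result: slope %.3f, rho %.3f, %d/%d outliers (%s %d%%)\n",
              x$slope, x$spearman_rho, length(x$outliers), nrow(x$band),
              x$band_type, round(100 * x$level)))
  invisible(x)
}
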