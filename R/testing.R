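#' Unequal-variance (Welch) two-sample t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite fractional degrees of
#' freedom. Degenerate inputs follow documented conventions: both samples
#' constant with equal means gives `t = 0, p = 1`; both constant with
#' unequal means gives `p = 0` with the `degenerate` flag set.
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return list: `t`, `df`, `p`, `degenerate`
#' @export
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs >= 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Fit empirical-Bayes variance-moderation hyperparameters
#'
#' Moment estimator on log sample variances for the hierarchical model
#' `s_g^2 | sigma_g^2 ~ sigma_g^2 chisq(d_g)/d_g`,
#' `1/sigma_g^2 ~ chisq(d0)/(d0 s0^2)`: with `z_g = log s_g^2` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, solve
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))`
#' for `d0` by Newton iteration on the monotone trigamma, and set
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. A non-positive
#' right-hand side means the variances carry no excess spread and the prior
#' degrees of freedom are infinite, with `s0^2 = exp(mean(e))`.
#'
#' @param variances per-detector sample variances `s_g^2` (cycles^2)
#' @param df per-detector residual degrees of freedom (scalar or vector)
#' @return list of class `moderation_hyper`: `d0` (prior df, possibly
#'   `Inf`), `s0_sq` (prior variance), `n_used`
#' @export
fit_moderation <- function(variances, df) {
  df <- rep_len(df, length(variances))
  ok <- is.finite(variances) & variances > 0 & df >= 1
  if (sum(ok) < 10) stop("need >= 10 detectors with positive variance and df >= 1",
                         call. = FALSE)
  if (any(!ok)) warning(sum(!ok), " detectors with zero/invalid variance dropped from moderation fit")
  s2 <- variances[ok]; d <- df[ok]
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  n <- length(e)
  rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(d / 2))
  if (rhs <= 0) {
    d0 <- Inf
    # no excess spread beyond sampling noise: the variances share one value,
    # estimated by their arithmetic mean (exact when the spread is zero)
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * .trigamma_inverse(rhs)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = n), class = "moderation_hyper")
}

#' @export
print.moderation_hyper <- function(x, ...) {
  cat(sprintf("moderation_hyper: d0 = %s, s0^2 = %.4g (n = %d)\n",
              format(x$d0), x$s0_sq, x$n_used))
  invisible(x)
}

# Newton solve of trigamma(y) = x; monotone decreasing, asymptotic
# initializer y ~ 0.5 + 1/x. tol 1e-8, <= 50 iterations.
.trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated two-sample t-test
#'
#' Pooled-variance two-group t-test with the detector variance shrunk toward
#' the empirical-Bayes prior: `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`,
#' tested on `d0 + d` degrees of freedom. `d0 = 0` reproduces the ordinary
#' pooled t exactly (no shrinkage); `d0 = Inf` tests every detector with the
#' common variance `s0^2` against the normal reference distribution.
#'
#' @param a,b numeric vectors (>= 2 values each)
#' @param hyper a `moderation_hyper` (or list with `d0`, `s0_sq`)
#' @return list: `t`, `df`, `p`, `s2` (pooled sample variance), `s2_post`
#' @export
moderated_t <- function(a, b, hyper) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs >= 2 values", call. = FALSE)
  d <- na + nb - 2
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / d
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  if (is.infinite(d0)) {
    s2_post <- s0
    tt <- (mean(a) - mean(b)) / sqrt(s2_post * (1 / na + 1 / nb))
    return(list(t = tt, df = Inf, p = 2 * stats::pnorm(-abs(tt)),
                s2 = s2, s2_post = s2_post))
  }
  s2_post <- (d0 * s0 + d * s2) / (d0 + d)
  tt <- (mean(a) - mean(b)) / sqrt(s2_post * (1 / na + 1 / nb))
  dft <- d0 + d
  list(t = tt, df = dft, p = 2 * stats::pt(-abs(tt), dft), s2 = s2,
       s2_post = s2_post)
}

#' Matrix-level moderated differential test
#'
#' Fits moderation hyperparameters across all detectors of a normalized Ct
#' matrix, then applies the moderated t-test per detector for
#' case-minus-reference differences. Detectors censored anywhere in the
#' contrast are flagged (their statistics are still computed -- clamped
#' values bias normalized comparisons, so the flag keeps them auditable).
#'
#' @param norm a `norm_ct_matrix` (or [ct_matrix])
#' @param design two-group [study_design]
#' @param reference_group reference group label
#' @return list: `table` (data.frame detector, mean_ref, mean_case, diff,
#'   t, df, p, q, censored_any) and `hyper`
#' @export
moderated_de <- function(norm, design, reference_group) {
  grp <- split_contrast(design, reference_group)
  a <- norm$ct[, grp$case, drop = FALSE]  # case
  b <- norm$ct[, grp$ref, drop = FALSE]   # reference
  na <- ncol(a); nb <- ncol(b)
  d <- na + nb - 2
  s2 <- ((na - 1) * apply(a, 1, stats::var) + (nb - 1) * apply(b, 1, stats::var)) / d
  hyper <- fit_moderation(s2, d)
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    m <- moderated_t(a[i, ], b[i, ], hyper)
    c(m$t, m$df, m$p)
  }, numeric(3)))
  cen <- if (!is.null(norm$censored)) {
    rowSums(norm$censored[, c(grp$ref, grp$case), drop = FALSE]) > 0
  } else rep(FALSE, nrow(a))
  tab <- data.frame(
    detector = rownames(norm$ct),
    mean_ref = rowMeans(b), mean_case = rowMeans(a),
    diff = rowMeans(a) - rowMeans(b),
    t = res[, 1], df = res[, 2], p = res[, 3],
    q = bh_adjust(res[, 3]),
    censored_any = cen,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(table = tab, hyper = hyper)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (q-values); monotone and
#' never below the raw p.
#'
#' @param p vector of p-values in (0, 1]
#' @return q-values, same length
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}
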