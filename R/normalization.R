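#' Median-normalize a Ct matrix
#'
#' Subtracts each sample's median Ct from all of that sample's values,
#' yielding delta-Ct values whose per-sample median is zero. By default the
#' median is computed over uncensored detectors only (a censored block
#' sitting exactly at the detection limit would drag the median), but every
#' cell -- censored or not -- is shifted. Removes per-sample additive
#' offsets (loading, extraction and conversion efficiency) exactly.
#'
#' @param ct a [ct_matrix]
#' @param include_censored include censored cells in the per-sample median
#' @return object of class `norm_ct_matrix`: list with `ct` (delta-Ct,
#'   cycles), `censored`, `method = "median"`, `controls_used` (empty) and
#'   `sample_median` (the subtracted per-sample medians)
#' @export
median_normalize <- function(ct, include_censored = FALSE) {
  stopifnot(inherits(ct, "ct_matrix"))
  med <- vapply(seq_len(ncol(ct$ct)), function(j) {
    v <- ct$ct[, j]
    if (!include_censored) v <- v[!ct$censored[, j]]
    if (length(v) == 0) {
      stop("sample '", colnames(ct$ct)[j], "' has no uncensored detectors",
           call. = FALSE)
    }
    stats::median(v)
  }, numeric(1))
  names(med) <- colnames(ct$ct)
  dct <- sweep(ct$ct, 2, med)
  structure(
    list(ct = dct, censored = ct$censored, method = "median",
         controls_used = character(), sample_median = med),
    class = "norm_ct_matrix"
  )
}

#' @export
print.norm_ct_matrix <- function(x, ...) {
  cat(sprintf("norm_ct_matrix (%s%s): %d detectors x %d samples\n",
              x$method,
              if (length(x$controls_used)) paste0(": ", paste(x$controls_used, collapse = ", ")) else "",
              nrow(x$ct), ncol(x$ct)))
  invisible(x)
}

#' Endogenous-control stability (geNorm M value)
#'
#' For candidate controls j and k, `V_jk` is the sample SD across samples of
#' the Ct difference `Ct_k - Ct_j` -- on the Ct scale this is the SD of the
#' pairwise log2 expression ratio, the classical geNorm pairwise variation.
#' A candidate's stability `M_j` is the mean of `V_jk` over the other
#' candidates; lower M = more stable. Selection keeps the `n_select`
#' lowest-M candidates (default 2, one normalizer pair); `method =
#' "exclusion"` instead runs the stepwise geNorm loop, dropping the
#' worst-M candidate and recomputing until `n_select` remain.
#'
#' The report flags the conventional acceptance thresholds: each selected
#' control's M below 0.15 and the combined (mean) M of the selection below
#' 0.1.
#'
#' @param ct a [ct_matrix]
#' @param candidates at least two candidate detector ids, uncensored in every
#'   sample
#' @param n_select how many controls to keep
#' @param method `"lowest"` (rank all candidates once) or `"exclusion"`
#'   (stepwise elimination)
#' @param m_max,combined_max acceptance thresholds for per-control and
#'   combined M
#' @return object of class `stability_report`: data.frame `m_values`
#'   (candidate, m), `selected`, `combined_m`, logical flags
#'   `per_control_ok`, `combined_ok`
#' @export
stability_m <- function(ct, candidates, n_select = 2,
                        method = c("lowest", "exclusion"),
                        m_max = 0.15, combined_max = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(ct, "ct_matrix"))
  candidates <- as.character(candidates)
  if (length(candidates) < 2) stop("need >= 2 candidate controls", call. = FALSE)
  miss <- setdiff(candidates, detector_ids(ct))
  if (length(miss)) stop("candidates not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ct$censored[candidates, ])) {
    bad <- candidates[rowSums(ct$censored[candidates, , drop = FALSE]) > 0]
    stop("candidate control censored in some sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_select <- min(n_select, length(candidates))

  m_of <- function(cand) {
    x <- ct$ct[cand, , drop = FALSE]
    vapply(seq_along(cand), function(j) {
      mean(vapply(setdiff(seq_along(cand), j), function(k) {
        stats::sd(x[k, ] - x[j, ])
      }, numeric(1)))
    }, numeric(1))
  }

  m_all <- stats::setNames(m_of(candidates), candidates)
  if (method == "lowest" || length(candidates) == n_select) {
    selected <- names(sort(m_all))[seq_len(n_select)]
  } else {
    keep <- candidates
    while (length(keep) > n_select) {
      m_cur <- stats::setNames(m_of(keep), keep)
      keep <- setdiff(keep, names(which.max(m_cur)))
    }
    selected <- keep
  }
  combined <- mean(m_all[selected])
  structure(
    list(m_values = data.frame(candidate = candidates, m = unname(m_all),
                               stringsAsFactors = FALSE),
         selected = selected, combined_m = combined,
         per_control_ok = all(m_all[selected] < m_max),
         combined_ok = combined < combined_max,
         thresholds = c(per_control = m_max, combined = combined_max)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report (geNorm M):\n")
  for (i in seq_len(nrow(x$m_values))) {
    cat(sprintf("  %s: M = %.4f%s\n", x$m_values$candidate[i], x$m_values$m[i],
                if (x$m_values$candidate[i] %in% x$selected) "  [selected]" else ""))
  }
  cat(sprintf("  combined M = %.4f (per-control < %.2f: %s; combined < %.2f: %s)\n",
              x$combined_m, x$thresholds["per_control"], x$per_control_ok,
              x$thresholds["combined"], x$combined_ok))
  invisible(x)
}

#' Normalize to the mean of endogenous controls
#'
#' `deltaCt[g, s] = Ct[g, s] - mean over controls of Ct[control, s]`.
#' The arithmetic mean on the Ct (log) scale is the geometric mean on the
#' quantity scale, the standard multi-control normalizer. Removes per-sample
#' additive offsets exactly.
#'
#' @param ct a [ct_matrix]
#' @param controls one or more control detector ids, uncensored in every
#'   sample
#' @return a `norm_ct_matrix` with `method = "controls"`
#' @export
control_normalize <- function(ct, controls) {
  stopifnot(inherits(ct, "ct_matrix"))
  controls <- as.character(controls)
  if (length(controls) == 0) stop("empty control list", call. = FALSE)
  miss <- setdiff(controls, detector_ids(ct))
  if (length(miss)) stop("controls not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ct$censored[controls, ])) {
    stop("control detector censored in some sample", call. = FALSE)
  }
  ref <- colMeans(ct$ct[controls, , drop = FALSE])
  structure(
    list(ct = sweep(ct$ct, 2, ref), censored = ct$censored,
         method = "controls", controls_used = controls, sample_median = ref),
    class = "norm_ct_matrix"
  )
}

#' Delta-delta-Ct and fold change between two groups
#'
#' `ddct = mean deltaCt(case) - mean deltaCt(reference)`; since Ct falls by
#' one cycle per doubling, `log2 fold change = -ddct` and the linear fold
#' change is `2^-ddct`.
#'
#' @param norm a `norm_ct_matrix`
#' @param design two-group [study_design]
#' @param reference_group reference group label
#' @return data.frame: detector, dct_ref, dct_case, ddct,
#'   log2_fold_change, fold_change
#' @export
ddct_fold_change <- function(norm, design, reference_group) {
  grp <- split_contrast(design, reference_group)
  dref <- rowMeans(norm$ct[, grp$ref, drop = FALSE])
  dcase <- rowMeans(norm$ct[, grp$case, drop = FALSE])
  ddct <- dcase - dref
  data.frame(detector = rownames(norm$ct),
             dct_ref = dref, dct_case = dcase, ddct = ddct,
             log2_fold_change = -ddct, fold_change = 2^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative quantity calibrated to the reference group
#'
#' Per detector and sample, `RQ = 2^-(deltaCt - mean deltaCt over reference
#' samples)`: reference samples average to RQ 1 (their mean log2 RQ is 0),
#' and case samples express fold differences relative to the reference mean.
#'
#' @inheritParams ddct_fold_change
#' @return matrix of relative quantities (same dimnames as the input)
#' @export
calibrated_expression <- function(norm, design, reference_group) {
  grp <- split_contrast(design, reference_group)
  ref_mean <- rowMeans(norm$ct[, grp$ref, drop = FALSE])
  2^(-sweep(norm$ct, 1, ref_mean))
}
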