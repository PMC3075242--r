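#' Differential-expression filter thresholds
#'
#' Thresholds are inclusive: a detector at exactly the rank-difference or
#' fold-change cutoff, or exactly at `p_max`, passes.
#'
#' @param rank_diff_min minimum absolute rank difference (rank units)
#' @param log2fc_min minimum absolute log2 fold change
#' @param p_max maximum p-value
#' @return list of class `filter_spec`
#' @export
filter_spec <- function(rank_diff_min = 10, log2fc_min = 1.0, p_max = 0.01) {
  stopifnot(rank_diff_min > 0, log2fc_min > 0, p_max > 0)
  structure(list(rank_diff_min = rank_diff_min, log2fc_min = log2fc_min,
                 p_max = p_max), class = "filter_spec")
}

#' Amplification-kinetics QC thresholds
#'
#' A conforming reaction amplifies log-linearly at about one Ct per cycle
#' through its exponential phase. The QC fits log2 fluorescence against
#' cycle inside a window bounded by `floor_frac` and `plateau_frac` of the
#' maximum fluorescence (at most `window` cycles from the first crossing)
#' and requires the slope inside `[slope_min, slope_max]` with fit R^2 of at
#' least `r2_min`. The default slope band (0.8, 1.2) passes a
#' perfect-doubling curve and rejects efficiencies below ~1.74 or above
#' ~2.30.
#'
#' @param slope_min,slope_max accepted log2-fluorescence slope per cycle
#' @param r2_min minimum R^2 of the window fit
#' @param window maximum cycles fitted from the first window crossing
#' @param floor_frac,plateau_frac fractions of maximum fluorescence bounding
#'   the fit window
#' @return list of class `kinetics_spec`
#' @export
kinetics_spec <- function(slope_min = 0.8, slope_max = 1.2, r2_min = 0.98,
                          window = 5, floor_frac = 0.05, plateau_frac = 0.60) {
  stopifnot(0 < floor_frac, floor_frac < plateau_frac, plateau_frac < 1,
            slope_min < 1, 1 < slope_max, window >= 3, r2_min > 0)
  structure(list(slope_min = slope_min, slope_max = slope_max,
                 r2_min = r2_min, window = window,
                 floor_frac = floor_frac, plateau_frac = plateau_frac),
            class = "kinetics_spec")
}

#' Amplification-kinetics QC of reaction curves
#'
#' Automates the visual curation of qPCR traces: for each reaction the
#' exponential window is the run of cycles whose fluorescence lies between
#' `floor_frac` and `plateau_frac` of that reaction's maximum, truncated to
#' `window` cycles from the first crossing; an OLS fit of log2 fluorescence
#' on cycle must then show near-doubling kinetics (see [kinetics_spec()]).
#' Windows shorter than 3 usable cycles fail with reason
#' `"insufficient exponential phase"`.
#'
#' @param curves a [curve_set]
#' @param spec a [kinetics_spec]
#' @return data.frame: detector, sample, pass, slope, r2, n_points, reason
#' @export
kinetics_qc <- function(curves, spec = kinetics_spec()) {
  stopifnot(inherits(curves, "curve_set"), inherits(spec, "kinetics_spec"))
  key <- paste(curves$detector, curves$sample, sep = "\r")
  res <- lapply(unique(key), function(k) {
    sub <- curves[key == k, ]
    out <- data.frame(detector = sub$detector[1], sample = sub$sample[1],
                      pass = FALSE, slope = NA_real_, r2 = NA_real_,
                      n_points = 0L, reason = "", stringsAsFactors = FALSE)
    m <- max(sub$fluorescence)
    eligible <- which(sub$fluorescence >= spec$floor_frac * m &
                        sub$fluorescence <= spec$plateau_frac * m &
                        sub$fluorescence > 0)
    if (m <= 0 || length(eligible) == 0) {
      out$reason <- "insufficient exponential phase"
      return(out)
    }
    first <- sub$cycle[eligible[1]]
    win <- eligible[sub$cycle[eligible] < first + spec$window]
    if (length(win) < 3) {
      out$reason <- "insufficient exponential phase"
      return(out)
    }
    x <- sub$cycle[win]
    y <- log2(sub$fluorescence[win])
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
    ok_slope <- slope >= spec$slope_min && slope <= spec$slope_max
    ok_r2 <- r2 >= spec$r2_min
    out$pass <- ok_slope && ok_r2
    out$slope <- slope; out$r2 <- r2; out$n_points <- length(win)
    out$reason <- if (out$pass) "ok" else if (!ok_slope) "slope out of band" else "poor linearity"
    out
  })
  do.call(rbind, res)
}

#' Per-detector curation verdict from reaction-level QC
#'
#' A detector is curated out of a contrast when its reactions fail the
#' kinetics QC: under the default `"any"` rule a single failing reaction
#' suffices; `"majority"` requires more than half.
#'
#' @param qc output of [kinetics_qc()]
#' @param rule `"any"` or `"majority"`
#' @return named logical vector detector -> curation pass
#' @export
curation_from_qc <- function(qc, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  fail_frac <- tapply(!qc$pass, qc$detector, mean)
  pass <- if (rule == "any") fail_frac == 0 else fail_frac <= 0.5
  stats::setNames(as.logical(pass), names(fail_frac))
}

#' Apply the differential-expression filters of one method
#'
#' Rank method: `|rank_diff| >= rank_diff_min` and `p_rank <= p_max`.
#' Median / moderated methods: `|log2FC| >= log2fc_min` and the method's
#' p-value at or below `p_max`. All cutoffs inclusive. Curation-failed
#' detectors are excluded regardless of statistics; detectors lacking a
#' p-value (NA) never pass.
#'
#' @param table a pipeline result table (see [run_pipeline()])
#' @param spec a [filter_spec]
#' @param method `"rank"`, `"median"` or `"moderated"`
#' @return character vector of passing detector ids
#' @export
apply_filters <- function(table, spec = filter_spec(),
                          method = c("rank", "median", "moderated")) {
  method <- match.arg(method)
  keep <- switch(method,
    rank = abs(table$rank_diff) >= spec$rank_diff_min & table$p_rank <= spec$p_max,
    median = abs(table$log2fc_median) >= spec$log2fc_min & table$p_median <= spec$p_max,
    moderated = abs(table$log2_fold_change) >= spec$log2fc_min & table$p_mod <= spec$p_max
  )
  keep[is.na(keep)] <- FALSE
  if (!is.null(table$curation_pass)) keep <- keep & table$curation_pass
  table$detector[keep]
}

#' Venn region counts for 2-3 named detector sets
#'
#' Counts every intersection region; the regions partition the union of the
#' sets, so their counts sum to the union size.
#'
#' @param sets named list of 2 or 3 character vectors
#' @return data.frame: region (set names joined by `&` for intersections,
#'   `only` suffix for exclusive regions), count
#' @export
venn_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2, 3), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 0) member <- matrix(logical(0), 0, length(sets),
                                       dimnames = list(NULL, names(sets)))
  if (length(u) == 1) member <- matrix(member, 1, dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  names(patterns) <- names(sets)
  region <- apply(patterns, 1, function(p) {
    nm <- paste(names(sets)[as.logical(p)], collapse = "&")
    if (sum(p) == 1) paste0(nm, "_only") else nm
  })
  count <- apply(patterns, 1, function(p) {
    if (length(u) == 0) return(0L)
    sum(apply(member, 1, function(mm) all(mm == as.logical(p))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full differential-expression workflow on one contrast
#'
#' Executes, in order: within-sample force ranking and the rank-difference
#' test; median normalization with a Welch t-test per detector; stability
#' selection of endogenous controls (when the design names >= 2 candidates)
#' followed by control normalization and the empirical-Bayes moderated
#' t-test; optional amplification-kinetics curation; the three inclusive
#' filters; Venn overlap of the three hit sets; and the focus list
#' (rank-filter hits that survive curation, annotated with the
#' delta-delta-Ct log2 fold change and moderated p). Also returns the
#' rank-rank concordance with prediction-interval outliers. Deterministic
#' given its inputs.
#'
#' When no control candidates are available the moderated test runs on the
#' median-normalized values and `log2_fold_change` derives from them.
#'
#' @param ct a [ct_matrix]
#' @param design two-group [study_design]
#' @param reference_group reference group label
#' @param curves optional [curve_set] for kinetics curation
#' @param fspec a [filter_spec]
#' @param qspec a [kinetics_spec]
#' @param band,level prediction-band settings for the rank-rank concordance
#' @param curation_rule `"any"` or `"majority"` failing reactions to exclude
#'   a detector
#' @return list of class `ctrank_result`: `table` (per-detector statistics),
#'   `sets` (the three filtered detector sets), `venn`, `focus`,
#'   `concordance`, `stability` (or NULL), `qc` (or NULL), `hyper`, `log`
#'   (per-detector exclusion records)
#' @export
run_pipeline <- function(ct, design, reference_group,
                         curves = NULL,
                         fspec = filter_spec(), qspec = kinetics_spec(),
                         band = "pointwise_pi", level = 0.95,
                         curation_rule = "any") {
  stopifnot(inherits(ct, "ct_matrix"), inherits(design, "study_design"))

  # --- rank branch -------------------------------------------------------
  rk <- rank_within_samples(ct)
  rank_res <- rank_diff_test(rk, design, reference_group)
  conc <- prediction_interval_outliers(
    stats::setNames(rank_res$mean_rank_ref, rank_res$detector),
    stats::setNames(rank_res$mean_rank_case, rank_res$detector),
    level = level, band = band)

  # --- median branch -----------------------------------------------------
  med <- median_normalize(ct)
  grp <- split_contrast(design, reference_group)
  med_t <- t(vapply(seq_len(nrow(med$ct)), function(i) {
    w <- welch_t(med$ct[i, grp$case], med$ct[i, grp$ref])
    c(w$t, w$df, w$p)
  }, numeric(3)))
  med_fc <- ddct_fold_change(med, design, reference_group)

  # --- moderated branch --------------------------------------------------
  stability <- NULL
  if (length(design$control_candidates) >= 2) {
    stability <- stability_m(ct, design$control_candidates)
    norm <- control_normalize(ct, stability$selected)
  } else {
    norm <- med
  }
  mod <- moderated_de(norm, design, reference_group)
  mod_fc <- ddct_fold_change(norm, design, reference_group)

  # --- curation ----------------------------------------------------------
  qc <- NULL
  curation <- stats::setNames(rep(TRUE, nrow(rank_res)), rank_res$detector)
  if (!is.null(curves)) {
    qc <- kinetics_qc(curves, qspec)
    verdict <- curation_from_qc(qc, curation_rule)
    curation[names(verdict)] <- verdict
  }

  table <- data.frame(
    detector = rank_res$detector,
    mean_rank_ref = rank_res$mean_rank_ref,
    mean_rank_case = rank_res$mean_rank_case,
    rank_diff = rank_res$rank_diff,
    t_rank = rank_res$t, df_rank = rank_res$df, p_rank = rank_res$p,
    dct_ref_median = med_fc$dct_ref, dct_case_median = med_fc$dct_case,
    ddct_median = med_fc$ddct, log2fc_median = med_fc$log2_fold_change,
    t_median = med_t[, 1], df_median = med_t[, 2], p_median = med_t[, 3],
    dct_ref = mod_fc$dct_ref, dct_case = mod_fc$dct_case,
    ddct = mod_fc$ddct, log2_fold_change = mod_fc$log2_fold_change,
    fold_change = mod_fc$fold_change,
    t_mod = mod$table$t, df_mod = mod$table$df, p_mod = mod$table$p,
    q_mod = mod$table$q,
    censored_frac = rank_res$censored_frac,
    censored_any = mod$table$censored_any,
    curation_pass = unname(curation[rank_res$detector]),
    pi_outlier = rank_res$detector %in% conc$outliers,
    stringsAsFactors = FALSE, row.names = NULL
  )
  table$pass_rank <- table$detector %in% apply_filters(table, fspec, "rank")
  table$pass_median <- table$detector %in% apply_filters(table, fspec, "median")
  table$pass_moderated <- table$detector %in% apply_filters(table, fspec, "moderated")

  sets <- list(rank = table$detector[table$pass_rank],
               median = table$detector[table$pass_median],
               moderated = table$detector[table$pass_moderated])
  venn <- venn_overlap(sets)

  focus <- table[table$pass_rank & table$curation_pass,
                 c("detector", "rank_diff", "p_rank", "ddct",
                   "log2_fold_change", "fold_change", "p_mod", "q_mod",
                   "censored_frac")]
  focus <- focus[order(-abs(focus$rank_diff)), ]
  rownames(focus) <- NULL

  log <- rbind(
    if (any(!table$curation_pass))
      data.frame(detector = table$detector[!table$curation_pass],
                 stage = "curation", reason = "failed amplification kinetics",
                 stringsAsFactors = FALSE),
    if (any(table$censored_any))
      data.frame(detector = table$detector[table$censored_any],
                 stage = "censoring", reason = "censored in >= 1 contrast sample",
                 stringsAsFactors = FALSE)
  )

  structure(
    list(table = table, sets = sets, venn = venn, focus = focus,
         concordance = conc, stability = stability, qc = qc,
         hyper = mod$hyper, log = log,
         params = list(reference_group = reference_group, fspec = fspec,
                       qspec = qspec, band = band, level = level,
                       curation_rule = curation_rule)),
    class = "ctrank_result"
  )
}

#' @export
print.ctrank_result <- function(x, ...) {
  cat(sprintf("ctrank_result: %d detectors; hits rank/median/moderated = %d/%d/%d; focus = %d\n",
              nrow(x$table), length(x$sets$rank), length(x$sets$median),
              length(x$sets$moderated), nrow(x$focus)))
  invisible(x)
}

#' Filter-count summary of a pipeline run
#'
#' The five headline counts of a three-method comparison: detectors
#' significant (p at or below `p_max`) in at least one method before effect
#' filters; hits of each of the three filtered methods; and the three-way
#' intersection.
#'
#' @param result a `ctrank_result`
#' @return named integer vector: `any_significant`, `rank`, `median`,
#'   `moderated`, `all_three`
#' @export
filter_count_summary <- function(result) {
  t <- result$table
  pm <- result$params$fspec$p_max
  any_sig <- sum(pmin(t$p_rank, t$p_median, t$p_mod, na.rm = TRUE) <= pm)
  c(any_significant = any_sig,
    rank = length(result$sets$rank),
    median = length(result$sets$median),
    moderated = length(result$sets$moderated),
    all_three = length(Reduce(intersect, result$sets)))
}

#' Detectors common to several contrasts' focus lists
#'
#' Intersects focus lists across independently analyzed contrasts (e.g.
#' tumors of inflammatory and of genetic origin) and reports each common
#' detector's per-contrast rank difference and fold change.
#'
#' @param ... named `ctrank_result` objects (>= 2)
#' @return data.frame: detector plus `rank_diff.<name>` and
#'   `log2fc.<name>` columns per contrast
#' @export
intersect_focus <- function(...) {
  results <- list(...)
  stopifnot(length(results) >= 2, !is.null(names(results)))
  common <- Reduce(intersect, lapply(results, function(r) r$focus$detector))
  out <- data.frame(detector = common, stringsAsFactors = FALSE)
  for (nm in names(results)) {
    f <- results[[nm]]$focus
    idx <- match(common, f$detector)
    out[[paste0("rank_diff.", nm)]] <- f$rank_diff[idx]
    out[[paste0("log2fc.", nm)]] <- f$log2_fold_change[idx]
  }
  out
}
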