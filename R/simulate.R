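#' Simulation configuration for synthetic TaqMan array data
#'
#' Encodes the statistical structure the analysis assumes: per-detector
#' baseline abundances, a per-sample loading/efficiency offset (additive on
#' the Ct scale, i.e. multiplicative on template quantity -- exactly the
#' nuisance rank statistics neutralize), designated low-variance endogenous
#' controls, group effects on chosen detectors, and censoring at the
#' detection limit.
#'
#' Baselines are drawn uniformly over `baseline_range`; the default (18, 38)
#' lets a realistic fraction of low-abundance detectors censor at 40.
#' Detectors carrying a planted effect draw their baselines from the interior
#' `de_baseline_range` so the effect is expressible in both groups: an effect
#' planted on the most abundant detector cannot move its rank below 1, and
#' one planted near the detection limit is truncated by censoring --
#' mirroring the fact that reproducibly quantifiable miRNAs sit away from
#' both extremes.
#'
#' @param n_detectors detectors per array (default 384, one TaqMan card).
#' @param n_per_group samples per group (default 4, the study size).
#' @param baseline_range cycles, uniform draw range for detector baselines.
#' @param de_detectors named numeric vector: detector id -> effect beta in
#'   cycles added to the case group (negative beta = more abundant in cases).
#'   Names may be existing detector ids or are assigned to fresh ids.
#' @param loading_sd SD (cycles) of the per-sample offset.
#' @param noise_sd SD (cycles) of per-reaction noise.
#' @param n_controls number of designated stable endogenous controls.
#' @param control_noise_sd per-reaction noise SD for controls (must be <=
#'   `noise_sd`).
#' @param control_baseline_range cycles; controls draw baselines here so they
#'   are always well detected.
#' @param de_baseline_range cycles; baseline draw range for detectors with a
#'   planted effect.
#' @param detection_limit censoring threshold in cycles.
#' @param group_labels labels for (reference, case) groups.
#' @param seed integer; the whole simulation is deterministic given the seed.
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_detectors = 384,
                       n_per_group = 4,
                       baseline_range = c(18, 38),
                       de_detectors = numeric(),
                       loading_sd = 1,
                       noise_sd = 0.5,
                       n_controls = 2,
                       control_noise_sd = 0.05,
                       control_baseline_range = c(20, 28),
                       de_baseline_range = c(22, 34),
                       detection_limit = 40,
                       group_labels = c("control", "case"),
                       seed = 1L) {
  stopifnot(n_per_group >= 2, noise_sd >= 0, control_noise_sd >= 0,
            n_controls >= 0, n_detectors > n_controls + length(de_detectors),
            length(baseline_range) == 2, baseline_range[1] < baseline_range[2],
            length(group_labels) == 2)
  if (control_noise_sd > noise_sd) {
    stop("control_noise_sd must not exceed noise_sd", call. = FALSE)
  }
  if (length(de_detectors) && is.null(names(de_detectors))) {
    names(de_detectors) <- sprintf("de%02d", seq_along(de_detectors))
  }
  ctl_ids <- if (n_controls > 0) sprintf("ctrl_%02d", seq_len(n_controls)) else character()
  if (length(intersect(names(de_detectors), ctl_ids))) {
    stop("an effect was assigned to a control detector", call. = FALSE)
  }
  structure(
    list(n_detectors = n_detectors, n_per_group = n_per_group,
         baseline_range = baseline_range, de_detectors = de_detectors,
         loading_sd = loading_sd, noise_sd = noise_sd,
         n_controls = n_controls, control_noise_sd = control_noise_sd,
         control_baseline_range = control_baseline_range,
         de_baseline_range = de_baseline_range,
         detection_limit = detection_limit,
         group_labels = group_labels, control_ids = ctl_ids,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a censored Ct matrix with known truth
#'
#' Generates `Ct[g, s] = baseline_g + delta_s + beta_g * 1[s in case] + eps`
#' with `delta_s ~ N(0, loading_sd^2)` and `eps ~ N(0, noise_sd^2)`
#' (`control_noise_sd` for controls, which carry no group effect). Values at
#' or above the detection limit are clamped to it and censored. Byte-identical
#' output for a fixed seed.
#'
#' @param config a [sim_config]
#' @return list with elements `ct` (a [ct_matrix]), `design` (a
#'   [study_design] whose `control_candidates` are the designated controls),
#'   and `truth` (data.frame: detector, baseline, beta, is_control).
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_ctl <- config$n_controls
    n_de <- length(config$de_detectors)
    n_bg <- config$n_detectors - n_ctl - n_de
    de_ids <- names(config$de_detectors)
    bg_ids <- sprintf("det%03d", seq_len(n_bg))
    det <- c(config$control_ids, de_ids, bg_ids)
    beta <- c(rep(0, n_ctl), unname(config$de_detectors), rep(0, n_bg))
    is_control <- c(rep(TRUE, n_ctl), rep(FALSE, n_de + n_bg))
    baseline <- c(
      stats::runif(n_ctl, config$control_baseline_range[1], config$control_baseline_range[2]),
      stats::runif(n_de, config$de_baseline_range[1], config$de_baseline_range[2]),
      stats::runif(n_bg, config$baseline_range[1], config$baseline_range[2])
    )
    n <- config$n_per_group
    samples <- c(paste0(config$group_labels[1], "_", seq_len(n)),
                 paste0(config$group_labels[2], "_", seq_len(n)))
    groups <- stats::setNames(rep(config$group_labels, each = n), samples)
    in_case <- as.numeric(groups == config$group_labels[2])
    delta <- stats::rnorm(2 * n, 0, config$loading_sd)
    noise_sd_vec <- ifelse(is_control, config$control_noise_sd, config$noise_sd)
    D <- length(det)
    eps <- matrix(stats::rnorm(D * 2 * n), D, 2 * n) * noise_sd_vec
    ct <- outer(baseline, rep(1, 2 * n)) +
      outer(rep(1, D), delta) +
      outer(beta, in_case) +
      eps
    dimnames(ct) <- list(det, samples)
    mat <- ct_matrix(ct, detection_limit = config$detection_limit)
    list(
      ct = mat,
      design = study_design(groups, control_candidates = config$control_ids),
      truth = data.frame(detector = det, baseline = baseline, beta = beta,
                         is_control = is_control, stringsAsFactors = FALSE)
    )
  })
}

#' Simulate qPCR amplification curves
#'
#' Exponential mode emits a saturating amplification trajectory
#' `f(c) = plateau * min(1, efficiency^(c - c0))`: below the plateau the
#' log2 fluorescence is exactly linear in cycle with slope
#' `log2(efficiency)` per cycle (slope 1 = perfect doubling, "1 Ct/cycle"),
#' the signature the kinetics QC tests for. Linear mode emits straight-line
#' fluorescence drift, a QC-failure case with no log-linear phase.
#'
#' @param efficiency amplification fold change per cycle (> 1 in exponential
#'   mode; 2 = perfect doubling).
#' @param c0 cycle at which fluorescence reaches the plateau.
#' @param plateau saturation fluorescence (arbitrary units).
#' @param n_cycles cycles measured (>= 10).
#' @param drift_mode `"exponential"` or `"linear"`.
#' @param detector,sample identifiers attached to the reaction.
#' @return a single-reaction [curve_set]
#' @export
simulate_curves <- function(efficiency = 2, c0 = 25, plateau = 1,
                            n_cycles = 40,
                            drift_mode = c("exponential", "linear"),
                            detector = "det1", sample = "s1") {
  drift_mode <- match.arg(drift_mode)
  if (n_cycles < 10) stop("n_cycles must be >= 10", call. = FALSE)
  cyc <- seq_len(n_cycles)
  if (drift_mode == "exponential") {
    if (efficiency <= 1) stop("efficiency must exceed 1 in exponential mode", call. = FALSE)
    f <- plateau * pmin(1, efficiency^(cyc - c0))
  } else {
    f <- plateau * cyc / n_cycles
  }
  curve_set(data.frame(detector = detector, sample = sample,
                       cycle = cyc, fluorescence = f,
                       stringsAsFactors = FALSE))
}

#' Combine several curve sets
#' @param ... [curve_set] objects
#' @return a [curve_set]
#' @export
bind_curves <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  curve_set(df)
}

#' Simulate a two-species target-prediction fixture with known truth
#'
#' Builds per-source mouse/human miRNA-to-gene prediction tables with a
#' planted conserved subset, a one-to-one ortholog map, Present/Absent
#' expression calls, and the truth sets the downstream consensus should
#' recover. Mouse genes are `mgene###`, human orthologs `HGENE###`.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_genes size of the mouse gene universe.
#' @param n_sources prediction sources (default 4, as when pooling
#'   TargetScan, MicroCosm, DIANA-microT and PicTar).
#' @param targets_per_mirna predicted targets per miRNA per source.
#' @param conserved_frac fraction of each source's mouse predictions whose
#'   human ortholog is also predicted.
#' @param present_frac fraction of the gene universe scored Present.
#' @param seed integer seed; the fixture is deterministic given it.
#' @return list: `mouse`/`human` (lists of per-source prediction
#'   data.frames with columns mirna, gene), `orthologs` (data.frame
#'   mouse_id, human_id), `present_calls` (named character vector
#'   gene -> "Present"/"Absent"), `truth` (list per miRNA: `conserved`
#'   = union over sources of planted conserved mouse genes,
#'   `conserved_expressed` = that set intersected with Present genes).
#' @export
simulate_target_fixture <- function(n_mirnas = 4, n_genes = 200,
                                    n_sources = 4, targets_per_mirna = 30,
                                    conserved_frac = 0.5,
                                    present_frac = 0.7, seed = 1L) {
  stopifnot(n_mirnas >= 1, n_genes >= targets_per_mirna, n_sources >= 1,
            conserved_frac >= 0, conserved_frac <= 1,
            present_frac >= 0, present_frac <= 1)
  withr::with_seed(as.integer(seed), {
    mirnas <- sprintf("miR-%d", seq_len(n_mirnas))
    mg <- sprintf("mgene%03d", seq_len(n_genes))
    hg <- sprintf("HGENE%03d", seq_len(n_genes))
    ortho <- data.frame(mouse_id = mg, human_id = hg, stringsAsFactors = FALSE)
    map <- stats::setNames(hg, mg)
    present <- stats::setNames(
      ifelse(stats::runif(n_genes) < present_frac, "Present", "Absent"), mg)
    sources <- sprintf("source%d", seq_len(n_sources))
    mouse <- list(); human <- list()
    truth_cons <- stats::setNames(vector("list", n_mirnas), mirnas)
    for (src in sources) {
      mpairs <- NULL; hpairs <- NULL
      for (mi in mirnas) {
        mtar <- sample(mg, targets_per_mirna)
        n_cons <- round(conserved_frac * targets_per_mirna)
        cons <- if (n_cons > 0) mtar[seq_len(n_cons)] else character()
        # human set: orthologs of the conserved subset plus unrelated extras
        extras <- sample(setdiff(hg, map[mtar]), targets_per_mirna - n_cons)
        htar <- c(unname(map[cons]), extras)
        mpairs <- rbind(mpairs, data.frame(mirna = mi, gene = mtar,
                                           stringsAsFactors = FALSE))
        hpairs <- rbind(hpairs, data.frame(mirna = mi, gene = htar,
                                           stringsAsFactors = FALSE))
        truth_cons[[mi]] <- union(truth_cons[[mi]], cons)
      }
      mouse[[src]] <- mpairs
      human[[src]] <- hpairs
    }
    truth <- lapply(truth_cons, function(g) {
      g <- sort(g)
      list(conserved = g,
           conserved_expressed = g[present[g] == "Present"])
    })
    list(mouse = mouse, human = human, orthologs = ortho,
         present_calls = present, truth = truth)
  })
}
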