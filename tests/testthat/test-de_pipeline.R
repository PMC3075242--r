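test_that("kinetics QC passes perfect doubling and rejects slow or linear curves", {
  qc2 <- kinetics_qc(simulate_curves(efficiency = 2))
  expect_true(qc2$pass)
  expect_equal(qc2$slope, 1, tolerance = 0.01)

  qc15 <- kinetics_qc(simulate_curves(efficiency = 1.5))
  expect_false(qc15$pass)
  expect_equal(qc15$slope, log2(1.5), tolerance = 0.01)

  qclin <- kinetics_qc(simulate_curves(drift_mode = "linear"))
  expect_false(qclin$pass)

  # plateau reached immediately: no usable exponential window
  flat <- curve_set(data.frame(detector = "f", sample = "s", cycle = 1:12,
                               fluorescence = rep(1, 12)))
  qcf <- kinetics_qc(flat)
  expect_false(qcf$pass)
  expect_equal(qcf$reason, "insufficient exponential phase")
})

test_that("curation rules aggregate reaction verdicts per detector", {
  cs <- bind_curves(
    simulate_curves(2, detector = "good", sample = "s1"),
    simulate_curves(2, detector = "good", sample = "s2"),
    simulate_curves(2, detector = "mixed", sample = "s1"),
    simulate_curves(1.5, detector = "mixed", sample = "s2"),
    simulate_curves(1.5, detector = "bad", sample = "s1"),
    simulate_curves(1.5, detector = "bad", sample = "s2"))
  qc <- kinetics_qc(cs)
  any_rule <- curation_from_qc(qc, "any")
  expect_equal(any_rule[c("good", "mixed", "bad")],
               c(good = TRUE, mixed = FALSE, bad = FALSE))
  maj_rule <- curation_from_qc(qc, "majority")
  expect_equal(maj_rule[c("good", "mixed", "bad")],
               c(good = TRUE, mixed = TRUE, bad = FALSE))
})

test_that("filters use inclusive thresholds and respect curation", {
  tab <- data.frame(
    detector = c("at_cut", "big_fc_weak_p", "curated_out", "null"),
    rank_diff = c(10, 40, 60, 2),
    p_rank = c(0.01, 0.02, 0.001, 0.9),
    log2fc_median = c(1.0, 2, 3, 0.1),
    p_median = c(0.01, 0.02, 0.001, 0.9),
    log2_fold_change = c(1.0, 2, 3, 0.1),
    p_mod = c(0.01, 0.02, 0.001, 0.9),
    curation_pass = c(TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  spec <- filter_spec()
  expect_equal(apply_filters(tab, spec, "rank"), "at_cut")
  expect_equal(apply_filters(tab, spec, "median"), "at_cut")
  expect_equal(apply_filters(tab, spec, "moderated"), "at_cut")
  # loosening p admits the weak-p detector, never the curated-out one
  loose <- filter_spec(p_max = 0.05)
  expect_setequal(apply_filters(tab, loose, "rank"), c("at_cut", "big_fc_weak_p"))
})

test_that("tightening any threshold never adds a detector", {
  withr::with_seed(55, {
    tab <- data.frame(
      detector = paste0("d", 1:200),
      rank_diff = rnorm(200, 0, 20),
      p_rank = runif(200),
      log2fc_median = rnorm(200), p_median = runif(200),
      log2_fold_change = rnorm(200), p_mod = runif(200),
      curation_pass = TRUE, stringsAsFactors = FALSE)
    base <- filter_spec(rank_diff_min = 10, log2fc_min = 1, p_max = 0.05)
    for (m in c("rank", "median", "moderated")) {
      loosest <- apply_filters(tab, base, m)
      for (tight in list(filter_spec(20, 1, 0.05), filter_spec(10, 2, 0.05),
                         filter_spec(10, 1, 0.01))) {
        expect_true(all(apply_filters(tab, tight, m) %in% loosest))
      }
    }
  })
})

test_that("venn regions partition the union", {
  v <- venn_overlap(list(A = c("x", "y"), B = c("y", "z"), C = "y"))
  get <- function(r) v$count[v$region == r]
  expect_equal(get("A&B&C"), 1L)   # y
  expect_equal(get("A_only"), 1L)  # x
  expect_equal(get("B_only"), 1L)  # z
  expect_equal(sum(v$count), 3L)

  same <- venn_overlap(list(A = letters[1:4], B = letters[1:4], C = letters[1:4]))
  expect_equal(same$count[same$region == "A&B&C"], 4L)
  disj <- venn_overlap(list(A = "a", B = c("b", "q"), C = c("c", "r")))
  expect_true(all(disj$count[grepl("&", disj$region)] == 0))

  withr::with_seed(9, {
    for (i in 1:15) {
      sets <- list(A = sample(letters, 8), B = sample(letters, 12),
                   C = sample(letters, 5))
      v <- venn_overlap(sets)
      expect_equal(sum(v$count), length(unique(unlist(sets))))
    }
  })
})

test_that("the pipeline recovers planted effects end to end", {
  # a 3-cycle shift moves a detector dozens of rank positions, so the
  # rank-displacement component of the filter is essentially deterministic;
  # the Welch p on n = 4 ranks retains a small per-detector miss rate, so
  # focus-list membership is held to a pooled fraction rather than
  # per-seed exhaustive recovery
  beta <- stats::setNames(rep(c(-3, 3), each = 4), paste0("de", 1:8))
  rank_ok <- 0
  recovered <- 0
  for (seed in 1:20) {
    sim <- simulate_ct(sim_config(de_detectors = beta, seed = seed))
    res <- run_pipeline(sim$ct, sim$design, "control")
    tab <- res$table[match(names(beta), res$table$detector), ]
    if (all(abs(tab$rank_diff) >= 10 &
              sign(tab$rank_diff) == sign(-beta))) rank_ok <- rank_ok + 1
    recovered <- recovered + sum(names(beta) %in% res$focus$detector)
  }
  expect_gte(rank_ok, 19)
  expect_gte(recovered / (20 * length(beta)), 0.9)
})

test_that("the pipeline is deterministic and internally consistent", {
  sim <- simulate_ct(sim_config(de_detectors = c(up = -2.5), seed = 4))
  cs <- bind_curves(simulate_curves(2, detector = "up", sample = "control_1"),
                    simulate_curves(1.5, detector = "det001", sample = "case_1"))
  r1 <- run_pipeline(sim$ct, sim$design, "control", curves = cs)
  r2 <- run_pipeline(sim$ct, sim$design, "control", curves = cs)
  expect_identical(r1, r2)

  # log2FC = -ddct everywhere; q >= p; curated detector excluded from focus
  expect_equal(r1$table$log2_fold_change, -r1$table$ddct)
  expect_true(all(r1$table$q_mod >= r1$table$p_mod - 1e-15))
  expect_false("det001" %in% r1$focus$detector)
  expect_true("det001" %in% r1$log$detector[r1$log$stage == "curation"])
  # venn counts sum to the union of hit sets
  expect_equal(sum(r1$venn$count), length(unique(unlist(r1$sets))))
  # stability selection used the designated controls
  expect_setequal(r1$stability$selected, c("ctrl_01", "ctrl_02"))
})

test_that("rank and fold-change signs agree on noiseless data", {
  cfg <- sim_config(n_detectors = 40, loading_sd = 2, noise_sd = 0,
                    control_noise_sd = 0,
                    de_detectors = c(up = -3, dn = 2), seed = 13)
  sim <- simulate_ct(cfg)
  # noiseless wells have zero variance, which the moderation fit drops loudly
  expect_warning(res <- run_pipeline(sim$ct, sim$design, "control"),
                 "zero/invalid variance")
  t <- res$table[!res$table$censored_any, ]
  nz <- abs(t$rank_diff) > 1e-9 & abs(t$log2_fold_change) > 1e-9
  expect_true(all(sign(t$rank_diff[nz]) == sign(t$log2_fold_change[nz])))
})

test_that("focus lists intersect across contrasts", {
  beta <- c(shared1 = -3, shared2 = 3, only_a = -3)
  sim_a <- simulate_ct(sim_config(de_detectors = beta, seed = 70))
  sim_b <- simulate_ct(sim_config(de_detectors = beta[1:2], seed = 71))
  ra <- run_pipeline(sim_a$ct, sim_a$design, "control")
  rb <- run_pipeline(sim_b$ct, sim_b$design, "control")
  common <- intersect_focus(a = ra, b = rb)
  expect_true(all(c("shared1", "shared2") %in% common$detector))
  expect_false("only_a" %in% common$detector)
  expect_true(all(c("rank_diff.a", "log2fc.b") %in% names(common)))
})
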