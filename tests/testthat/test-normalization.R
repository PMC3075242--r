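test_that("median normalization centers samples and excludes censored cells", {
  ct <- make_ct(matrix(c(20, 25, 30), 3, 1))
  expect_equal(unname(median_normalize(ct)$ct[, 1]), c(-5, 0, 5))

  # censored cell excluded from the median but still shifted
  ct2 <- make_ct(matrix(c(20, 25, 30, 41), 4, 1))
  expect_equal(unname(median_normalize(ct2)$ct[, 1]), c(-5, 0, 5, 15))
  expect_equal(unname(median_normalize(ct2, include_censored = TRUE)$ct[, 1]),
               c(-7.5, -2.5, 2.5, 12.5))

  # all-censored sample errors with its name
  ct3 <- make_ct(matrix(c(20, 25, 41, 42), 2, 2))
  expect_error(median_normalize(ct3), "s2")
})

test_that("both normalizations remove per-sample additive offsets exactly", {
  withr::with_seed(5, {
    m <- matrix(runif(40, 20, 35), 10, 4)
    rownames(m) <- c("ctlA", "ctlB", paste0("d", 1:8))
    colnames(m) <- paste0("s", 1:4)
    off <- runif(4, -4, 4)
    a <- ct_matrix(m); b <- ct_matrix(sweep(m, 2, off, `+`))
    expect_equal(median_normalize(a)$ct, median_normalize(b)$ct)
    expect_equal(control_normalize(a, c("ctlA", "ctlB"))$ct,
                 control_normalize(b, c("ctlA", "ctlB"))$ct)
  })
})

test_that("geNorm M values match hand computation and rank jittered candidates last", {
  # constant pairwise difference: perfectly co-stable pair, M = 0
  m <- matrix(c(20, 21, 22, 23, 24, 25), 2, 3, byrow = TRUE)
  rownames(m) <- c("A", "B")
  rep0 <- stability_m(make_ct(m), c("A", "B"))
  expect_equal(rep0$m_values$m, c(0, 0))
  expect_equal(rep0$combined_m, 0)
  expect_true(rep0$combined_ok)

  # hand case: differences B - A = (0, 1, -1), sample SD = 1
  m2 <- rbind(A = c(20, 21, 22), B = c(20, 22, 21))
  colnames(m2) <- paste0("s", 1:3)
  rep2 <- stability_m(ct_matrix(m2), c("A", "B"))
  expect_equal(rep2$m_values$m, c(1, 1))

  # a jittered third candidate gets the largest M and is never selected
  withr::with_seed(88, {
    worst_selected <- 0
    for (i in 1:20) {
      base <- runif(8, 22, 26)
      mm <- rbind(A = base + rnorm(8, 0, 0.05),
                  B = base + rnorm(8, 0, 0.05),
                  C = base + rnorm(8, 0, 2))
      colnames(mm) <- paste0("s", 1:8)
      rep <- stability_m(ct_matrix(mm), c("A", "B", "C"))
      expect_equal(rep$m_values$candidate[which.max(rep$m_values$m)], "C")
      if ("C" %in% rep$selected) worst_selected <- worst_selected + 1
      # stepwise exclusion agrees here
      expect_setequal(stability_m(ct_matrix(mm), c("A", "B", "C"),
                                  method = "exclusion")$selected, rep$selected)
    }
    expect_equal(worst_selected, 0)
  })
})

test_that("stability candidates must be >= 2 and uncensored", {
  ct <- make_ct(matrix(c(20, 41, 21, 41), 2, 2))
  expect_error(stability_m(ct, "d01"), ">= 2")
  expect_error(stability_m(ct, c("d01", "d02")), "censored")
})

test_that("control normalization equals subtracting the control mean", {
  m <- rbind(ctl1 = c(20, 21), ctl2 = c(22, 23), tgt = c(28, 29))
  colnames(m) <- c("s1", "s2")
  norm <- control_normalize(ct_matrix(m), c("ctl1", "ctl2"))
  expect_equal(unname(norm$ct["tgt", ]), c(7, 7))
  # a lone control normalized to itself is zero everywhere
  solo <- control_normalize(ct_matrix(m), "ctl1")
  expect_equal(unname(solo$ct["ctl1", ]), c(0, 0))
  expect_error(control_normalize(ct_matrix(m), character()), "empty")
})

test_that("control normalization divides by the controls' geometric mean on the quantity scale", {
  withr::with_seed(14, {
    m <- matrix(runif(24, 20, 30), 6, 4)
    rownames(m) <- c("c1", "c2", "c3", "t1", "t2", "t3")
    norm <- control_normalize(make_ct(m), c("c1", "c2", "c3"))
    q <- 2^(-m)                                  # relative quantity
    geo <- apply(q[1:3, ], 2, function(v) prod(v)^(1 / 3))
    expect_equal(2^(-norm$ct), sweep(q, 2, geo, `/`), ignore_attr = TRUE)
  })
})

test_that("delta-delta-Ct fold changes follow the sign convention", {
  m <- rbind(t = c(6, 6, 4, 4))  # dct: ref mean 6, case mean 4
  colnames(m) <- paste0("s", 1:4)
  norm <- structure(list(ct = m, censored = m & FALSE, method = "median",
                         controls_used = character()),
                    class = "norm_ct_matrix")
  d <- study_design(stats::setNames(rep(c("control", "case"), each = 2),
                                    colnames(m)))
  fc <- ddct_fold_change(norm, d, "control")
  expect_equal(fc$ddct, -2)
  expect_equal(fc$log2_fold_change, 2)
  expect_equal(fc$fold_change, 4)
  # swap: antisymmetric
  fc2 <- ddct_fold_change(norm, d, "case")
  expect_equal(fc2$log2_fold_change, -2)
  # identical groups: no change
  m0 <- rbind(t = c(5, 5, 5, 5)); colnames(m0) <- paste0("s", 1:4)
  norm0 <- structure(list(ct = m0, censored = m0 & FALSE), class = "norm_ct_matrix")
  expect_equal(ddct_fold_change(norm0, d, "control")$fold_change, 1)
})

test_that("calibrated expression is anchored on the reference group", {
  m <- rbind(t = c(5, 5, 3, 7)); colnames(m) <- paste0("s", 1:4)
  norm <- structure(list(ct = m, censored = m & FALSE), class = "norm_ct_matrix")
  d <- study_design(stats::setNames(rep(c("control", "case"), each = 2),
                                    colnames(m)))
  rq <- calibrated_expression(norm, d, "control")
  expect_equal(unname(rq["t", ]), c(1, 1, 4, 1 / 4))
  expect_true(all(rq > 0))
  # mean log2 RQ over reference samples is zero by construction
  expect_equal(mean(log2(rq["t", 1:2])), 0)
})

test_that("fold-change errors are unbiased with the propagated standard error", {
  # per-detector error variance after control normalization:
  #   noise^2 * (1/n_case + 1/n_ref) plus the shared control-noise term
  beta <- c(-3, -3, 2, 2, 3)
  se <- sqrt(2 * (0.5^2 + 2 * 0.05^2 / 2) / 4)
  errs <- unlist(lapply(1:20, function(s) {
    cfg <- sim_config(de_detectors = stats::setNames(beta, paste0("de", 1:5)),
                      seed = s)
    sim <- simulate_ct(cfg)
    norm <- control_normalize(sim$ct, sim$design$control_candidates)
    fc <- ddct_fold_change(norm, sim$design, "control")
    fc$log2_fold_change[match(paste0("de", 1:5), fc$detector)] - (-beta)
  }))
  # 100 draws: |mean| < 3 * se / 10 (rounded up), sd within 3 sigma of se
  expect_lt(abs(mean(errs)), 0.12)
  expect_gt(sd(errs), 0.75 * se)
  expect_lt(sd(errs), 1.25 * se)
})
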