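make_ct <- function(target_by_tp, ref_ct = 20, n_rep = 1) {
  rows <- lapply(names(target_by_tp), function(tp) {
    rbind(data.frame(sample = "s", timepoint = as.numeric(tp),
                     replicate = seq_len(n_rep), gene = "TGT",
                     ct = target_by_tp[[tp]]),
          data.frame(sample = "s", timepoint = as.numeric(tp),
                     replicate = seq_len(n_rep), gene = "REF",
                     ct = ref_ct))
  })
  do.call(rbind, rows)
}

test_that("2^-ddCt reproduces hand-computed fold changes", {
  # sample dCt = 24 - 20 = 4; calibrator dCt = 26 - 20 = 6; ddCt = -2, RQ = 4
  ct <- make_ct(list(`0` = 26, `3` = 24))
  rq <- delta_delta_ct(ct, "TGT", "REF")
  expect_equal(rq$summary$mean_rq[rq$summary$timepoint == 3], 4)
  # calibrator against itself
  expect_equal(rq$summary$mean_rq[rq$summary$timepoint == 0], 1)
  # one-cycle increase halves the RQ
  ct2 <- make_ct(list(`0` = 26, `3` = 27))
  rq2 <- delta_delta_ct(ct2, "TGT", "REF")
  expect_equal(rq2$summary$mean_rq[rq2$summary$timepoint == 3], 0.5)
})

test_that("adding a constant to every Ct of both genes leaves RQ unchanged", {
  set.seed(31)
  ct <- make_expression_table(default_trajectories()$target, sd = 0.3,
                              seed = 31)
  shifted <- ct
  shifted$ct <- shifted$ct + 3.7
  a <- delta_delta_ct(ct, "RUNX2", "ACTB")
  b <- delta_delta_ct(shifted, "RUNX2", "ACTB")
  expect_equal(a$replicates$rq, b$replicates$rq, tolerance = 1e-12)
})

test_that("per-replicate calibration pins every calibrator RQ at exactly 1", {
  set.seed(32)
  ct <- make_expression_table(default_trajectories()$target, sd = 0.4,
                              seed = 32)
  rq <- delta_delta_ct(ct, "RUNX2", "ACTB", per_replicate_calibration = TRUE)
  cal <- rq$replicates[rq$replicates$timepoint == 0, ]
  expect_equal(cal$rq, rep(1, 5))
  # mean-calibrator convention: day-0 mean RQ 1, replicates scatter
  rq2 <- delta_delta_ct(ct, "RUNX2", "ACTB")
  cal2 <- rq2$replicates[rq2$replicates$timepoint == 0, ]
  expect_gt(sd(cal2$rq), 0)
  expect_equal(prod(cal2$rq)^(1 / 5), 1, tolerance = 1e-12) # geometric mean
})

test_that("records without a reference Ct are dropped with a warning", {
  ct <- make_ct(list(`0` = 26, `3` = 24))
  ct <- ct[!(ct$gene == "REF" & ct$timepoint == 3), ]
  expect_warning(rq <- delta_delta_ct(ct, "TGT", "REF"), "dropped")
  expect_false(3 %in% rq$summary$timepoint)
  no_cal <- make_ct(list(`3` = 24, `6` = 25))
  expect_error(delta_delta_ct(no_cal, "TGT", "REF"), "calibrator")
})

test_that("pooled t test matches the closed-form oracle", {
  got <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, -3.674, tolerance = 1e-3)
  expect_equal(got$df, 4)
  expect_equal(got$p, 0.02131, tolerance = 1e-3)
  set.seed(33)
  for (i in 1:25) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = 0.5)
    want <- oracle_pooled_t(a, b)
    got <- unpaired_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    swapped <- unpaired_t(b, a)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
})

test_that("degenerate t-test inputs are handled explicitly", {
  same <- unpaired_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  diff <- unpaired_t(c(2, 2), c(3, 3))
  expect_true(diff$degenerate)
  expect_equal(diff$p, 0)
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("pearson matches the product-moment oracle to 1e-12", {
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6,
               tolerance = 1e-12)
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(1:5, -(1:5))$r, -1, tolerance = 1e-12)
  set.seed(34)
  for (i in 1:25) {
    x <- rnorm(sample(4:30, 1)); y <- rnorm(length(x))
    want <- oracle_pearson(x, y)
    got <- pearson_cor(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("trajectory correlation pairs series and reports the sign", {
  up <- data.frame(timepoint = c(0, 3, 6, 10), value = c(1, 2, 3, 4))
  down <- data.frame(timepoint = c(0, 3, 6, 10), value = c(4, 3, 2, 1))
  expect_lt(trajectory_correlation(up, down)$r, 0)
  expect_equal(trajectory_correlation(up, up)$r, 1, tolerance = 1e-12)
  short <- data.frame(timepoint = c(0, 3), value = c(1, 2))
  expect_error(trajectory_correlation(short, short), "3 shared")
})

test_that("planted opposite trajectories yield negative correlation", {
  traj <- default_trajectories()
  hits <- vapply(1:40, function(s) {
    tgt <- delta_delta_ct(
      make_expression_table(traj$target, gene = "T", sd = 0.25, seed = s),
      "T", "ACTB")
    mir <- delta_delta_ct(
      make_expression_table(traj$mirna, gene = "M", sd = 0.25,
                            seed = s + 1000L),
      "M", "ACTB")
    trajectory_correlation(tgt, mir)$r < 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("per-timepoint tests support both published contrasts", {
  traj <- default_trajectories()
  rq <- delta_delta_ct(
    make_expression_table(traj$target, sd = 0.1, seed = 35), "RUNX2",
    "ACTB")
  vs_cal <- timepoint_tests(rq, "vs_calibrator")
  expect_setequal(vs_cal$timepoint, c(3, 6, 10, 14, 21))
  # strong fold changes at late timepoints reach significance
  expect_true(all(vs_cal$p[vs_cal$timepoint >= 14] < 0.05))

  flat <- stats::setNames(rep(1, 6), c(0, 3, 6, 10, 14, 21))
  ctrl <- delta_delta_ct(
    make_expression_table(flat, sd = 0.1, seed = 36), "RUNX2", "ACTB")
  vs_ctrl <- timepoint_tests(rq, "vs_control", control = ctrl)
  expect_true(all(vs_ctrl$p[vs_ctrl$timepoint >= 14] < 0.05))
  expect_error(timepoint_tests(rq, "vs_control"), "control")
})

test_that("Ct tables round-trip through CSV", {
  ct <- make_expression_table(default_trajectories()$target, seed = 37)
  tmp <- tempfile(fileext = ".csv")
  write_ct_csv(ct, tmp)
  back <- read_ct_csv(tmp)
  expect_equal(back$ct, ct$ct, tolerance = 1e-12)
  expect_equal(back$gene, ct$gene)
})
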