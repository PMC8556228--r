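test_that("closed-form 1:1 response obeys its limiting identities", {
  # at C = KD the association plateau is Rmax / 2
  sg <- simulate_sensorgram(kon = 1e5, koff = 0.1, Rmax = 80, C = 1e-6,
                            t_assoc = 600, t_dissoc = 100)
  plateau <- sg$response[sg$time == 600]
  expect_equal(plateau, 40, tolerance = 1e-6)

  # Req at 10 uM with KD = 1 uM is Rmax * 10 / 11
  expect_equal(req_1to1(10e-6, 100, 1e-6), 100 * 10 / 11, tolerance = 1e-12)

  # dissociation decays to zero
  sg2 <- simulate_sensorgram(1e4, 1e-2, 100, 5e-6, t_dissoc = 3000)
  expect_lt(tail(sg2$response, 1), 1e-8 * max(sg2$response))

  expect_error(simulate_sensorgram(-1, 1e-2, 100, 1e-6), "positive")
  expect_error(simulate_sensorgram(1e4, 1e-2, 100, 1e-6, noise_sd = -1),
               ">= 0")
})

test_that("noise-free titration is deterministic; noisy is seed-reproducible", {
  a <- simulate_titration(1e4, 1e-2, 100)
  b <- simulate_titration(1e4, 1e-2, 100)
  expect_identical(a, b)
  n1 <- simulate_titration(1e4, 1e-2, 100, noise_sd = 1, seed = 9)
  n2 <- simulate_titration(1e4, 1e-2, 100, noise_sd = 1, seed = 9)
  n3 <- simulate_titration(1e4, 1e-2, 100, noise_sd = 1, seed = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("global fit recovers generating parameters from noise-free data", {
  grid <- data.frame(kon = rep(c(1e3, 1e4, 1e5), each = 3),
                     koff = c(1e-3, 5e-3, 2e-2,
                              5e-3, 2e-2, 1e-1,
                              5e-2, 7e-2, 1e-1))
  for (i in seq_len(nrow(grid))) {
    kon <- grid$kon[i]
    koff <- grid$koff[i]
    sg <- simulate_titration(kon, koff, 100, dt = 2)
    fit <- fit_global_1to1(sg)
    expect_true(fit$converged)
    expect_equal(fit$kon, kon, tolerance = 1e-3)
    expect_equal(fit$koff, koff, tolerance = 1e-3)
    expect_equal(fit$Rmax, 100, tolerance = 1e-3)
    expect_equal(fit$KD, koff / kon, tolerance = 1e-3)
    expect_identical(fit$KD, fit$koff / fit$kon)
  }
})

test_that("flat traces and single concentrations are rejected", {
  sg <- simulate_titration(1e4, 1e-2, 100)
  sg$response <- 0
  expect_error(fit_global_1to1(sg), "flat")
  one <- simulate_sensorgram(1e4, 1e-2, 100, 1e-6)
  one$cycle_id <- 1L
  expect_error(fit_global_1to1(one), ">= 2 concentrations")
})

test_that("Req is monotone increasing and saturating in concentration", {
  C <- 10^seq(-8, -4, length.out = 40)
  r <- req_1to1(C, 100, 1e-6)
  expect_true(all(diff(r) > 0))
  expect_lt(max(r), 100)
  expect_gt(tail(r, 1), 99)
})

test_that("steady-state fit round-trips exact isotherm points", {
  C <- c(0.625, 1.25, 2.5, 5, 10, 20) * 1e-6
  ss <- fit_steady_state(C, req_1to1(C, 75, 2e-6))
  expect_true(ss$converged)
  expect_equal(ss$KD, 2e-6, tolerance = 1e-6)
  expect_equal(ss$Rmax, 75, tolerance = 1e-6)
})

test_that("steady-state flags saturation and the weak-affinity linear regime", {
  C <- c(1, 2, 4, 8) * 1e-6
  flat <- fit_steady_state(C, rep(50, 4))
  expect_true("saturated" %in% flat$flags)
  expect_equal(flat$KD, 0)

  # C far below KD: Req ~ linear in C
  weak <- fit_steady_state(C, req_1to1(C, 100, 5e-4))
  expect_true(weak$converged)
  expect_true("weak_affinity" %in% weak$flags)
})

test_that("steady-state and kinetic KD agree on noise-free titrations", {
  sg <- simulate_titration(2e4, 4e-2, 120, t_assoc = 2000, t_dissoc = 100,
                           dt = 4,
                           concentrations = c(10, 5, 2.5, 1.25, 0.625) * 1e-6)
  fit <- fit_global_1to1(sg, t_assoc = 2000)
  req <- extract_req(sg, t_assoc = 2000)
  ss <- fit_steady_state(req$concentration, req$Req)
  expect_equal(ss$KD, fit$KD, tolerance = 0.02)
})

test_that("interaction triage distinguishes binder, blank and pathological input", {
  # clean simulated binder round-trips through the gates
  sg <- simulate_titration(1e4, 1e-2, 100, noise_sd = 0.5, seed = 4)
  fit <- fit_global_1to1(sg)
  call <- classify_interaction(fit, max_response = max(sg$response),
                               noise_sd = 0.5)
  expect_equal(call$label, "interaction")
  expect_equal(call$KD, 1e-6, tolerance = 0.1)

  # flat noise trace: no interaction
  blank <- classify_interaction(NULL, max_response = 1.2, noise_sd = 1)
  expect_equal(blank$label, "no_interaction")

  # signal present but no fit passed its gates
  nd <- classify_interaction(
    structure(list(converged = FALSE, KD = NA_real_,
                   se = c(KD = NA_real_)), class = "kinetic_fit"),
    max_response = 50, noise_sd = 1)
  expect_equal(nd$label, "not_defined")

  # implausible KD (outside tested decade band) fails the gate
  off <- structure(list(converged = TRUE, KD = 5e-2,
                        se = c(KD = 1e-3)), class = "kinetic_fit")
  expect_equal(classify_interaction(off, 50, 1)$label, "not_defined")
})

test_that("sensorgram CSV round-trips", {
  sg <- simulate_titration(1e4, 1e-2, 100, dt = 10)
  tmp <- tempfile(fileext = ".csv")
  write_sensorgram_csv(sg, tmp)
  back <- read_sensorgram_csv(tmp)
  expect_equal(back$response, sg$response)
  expect_equal(back$concentration, sg$concentration)
})

test_that("noisy KD recovery stays within 10% for the vast majority of runs", {
  ok <- vapply(1:30, function(s) {
    sg <- simulate_titration(1e4, 1e-2, 100, noise_sd = 1, seed = s, dt = 2)
    fit <- fit_global_1to1(sg)
    isTRUE(fit$converged) && abs(fit$KD - 1e-6) / 1e-6 < 0.1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
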