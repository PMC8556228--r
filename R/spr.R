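# 1:1 Langmuir surface plasmon resonance: closed-form sensorgram model,
# global kinetic fitting, steady-state affinity fitting, and interaction
# classification.
#
# For a 1:1 interaction at constant analyte concentration C the response is
# exact in closed form:
#   association  (0 <= t <= t_assoc):  R(t) = Req * (1 - exp(-(kon*C + koff) * t))
#                with Req = Rmax * C / (C + KD), KD = koff / kon
#   dissociation (t > t_assoc):        R(t) = R(t_assoc) * exp(-koff * (t - t_assoc))

#' Equilibrium response of a 1:1 interaction
#' @param C Analyte concentration (M).
#' @param Rmax Maximal response (RU).
#' @param KD Equilibrium dissociation constant (M).
#' @return Req in RU.
#' @export
req_1to1 <- function(C, Rmax, KD) Rmax * C / (C + KD)

# noise-free 1:1 response at times t (s) for one concentration
response_1to1 <- function(t, kon, koff, Rmax, C, t_assoc = 180) {
  KD <- koff / kon
  Req <- req_1to1(C, Rmax, KD)
  kobs <- kon * C + koff
  R_end <- Req * (1 - exp(-kobs * t_assoc))
  ifelse(t <= t_assoc,
         Req * (1 - exp(-kobs * t)),
         R_end * exp(-koff * (t - t_assoc)))
}

#' Simulate a 1:1 sensorgram
#'
#' Closed-form two-phase 1:1 Langmuir response with optional additive
#' Gaussian noise. Default phase durations follow a 180 s association /
#' 300 s dissociation cycle.
#'
#' @param kon Association rate (1/(M*s)), > 0.
#' @param koff Dissociation rate (1/s), > 0.
#' @param Rmax Maximal response (RU), > 0.
#' @param C Analyte concentration (M), > 0.
#' @param t_assoc Association duration (s), default 180.
#' @param t_dissoc Dissociation duration (s), default 300.
#' @param dt Sampling interval (s), default 1.
#' @param noise_sd Gaussian noise SD in RU (default 0, deterministic).
#' @param seed Optional RNG seed used when `noise_sd > 0`.
#' @return data.frame of class `sensorgram`: `time`, `response`,
#'   `concentration`, `phase`.
#' @export
simulate_sensorgram <- function(kon, koff, Rmax, C, t_assoc = 180,
                                t_dissoc = 300, dt = 1, noise_sd = 0,
                                seed = NULL) {
  if (any(c(kon, koff, Rmax, C, t_assoc, t_dissoc, dt) <= 0))
    stop("kon, koff, Rmax, C and durations must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- response_1to1(t, kon, koff, Rmax, C, t_assoc)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, noise_sd)
  }
  out <- data.frame(time = t, response = r, concentration = C,
                    phase = ifelse(t <= t_assoc, "association",
                                   "dissociation"))
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' Simulate a multi-concentration titration series
#'
#' One cycle per concentration, response reset to zero between cycles
#' (regeneration). The default two-fold dilution series spans 10 to
#' 0.625 uM.
#'
#' @param kon,koff,Rmax Kinetic parameters shared across cycles.
#' @param concentrations Analyte concentrations in M; default
#'   `c(10, 5, 2.5, 1.25, 0.625) * 1e-6`.
#' @param noise_sd,seed,... Passed to [simulate_sensorgram()]; per-cycle
#'   seeds are derived from `seed`.
#' @return data.frame with columns of [simulate_sensorgram()] plus
#'   `cycle_id`.
#' @export
simulate_titration <- function(kon, koff, Rmax,
                               concentrations = c(10, 5, 2.5, 1.25, 0.625) * 1e-6,
                               noise_sd = 0, seed = NULL, ...) {
  cycles <- lapply(seq_along(concentrations), function(i) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    sg <- simulate_sensorgram(kon, koff, Rmax, concentrations[i],
                              noise_sd = noise_sd, seed = s, ...)
    sg$cycle_id <- i
    sg
  })
  out <- do.call(rbind, cycles)
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' Read / write sensorgram CSV (`time_s,response_ru,concentration_M,cycle_id`)
#' @param path CSV path.
#' @return data.frame of class `sensorgram`.
#' @export
read_sensorgram_csv <- function(path) {
  tab <- utils::read.csv(path)
  stopifnot(all(c("time_s", "response_ru", "concentration_M") %in% names(tab)))
  out <- data.frame(time = tab$time_s, response = tab$response_ru,
                    concentration = tab$concentration_M,
                    cycle_id = if ("cycle_id" %in% names(tab)) tab$cycle_id
                               else match(tab$concentration_M,
                                          unique(tab$concentration_M)))
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' @rdname read_sensorgram_csv
#' @param sg A sensorgram data.frame.
#' @export
write_sensorgram_csv <- function(sg, path) {
  df <- data.frame(time_s = sg$time, response_ru = sg$response,
                   concentration_M = sg$concentration,
                   cycle_id = if ("cycle_id" %in% names(sg)) sg$cycle_id else 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Global 1:1 kinetic fit across concentrations
#'
#' Nonlinear least squares with kon, koff and Rmax shared across all
#' concentration cycles, parameterized on the log scale to enforce
#' positivity, using Levenberg-Marquardt from a multi-start grid
#' (kon in 10^{3,4,5,6} 1/(M*s), koff in 10^{-3,-2,-1} 1/s, Rmax from the
#' observed maximum). KD is reported as koff/kon; its standard error comes
#' from the delta method on the log-parameter covariance.
#'
#' @param sg A sensorgram data.frame covering at least two concentrations
#'   spanning a >= 4-fold range (columns `time`, `response`,
#'   `concentration`).
#' @param t_assoc Association-phase end (s), default 180.
#' @return A list of class `kinetic_fit`: `kon`, `koff`, `Rmax`, `KD`,
#'   `se` (named, delta-method), `rss`, `n_concentrations`, `converged`,
#'   `n_obs`.
#' @export
fit_global_1to1 <- function(sg, t_assoc = 180) {
  concs <- sort(unique(sg$concentration))
  if (length(concs) < 2L)
    stop("global fit requires sensorgrams at >= 2 concentrations")
  if (max(concs) / min(concs) < 4)
    warning("concentration span below 4-fold; kinetic parameters may be ",
            "poorly constrained")
  if (max(abs(sg$response)) < .Machine$double.eps^0.5)
    stop("flat zero traces carry no binding signal; nothing to fit")
  resid_fun <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2]); Rmax <- exp(p[3])
    sg$response - response_1to1(sg$time, kon, koff, Rmax,
                                sg$concentration, t_assoc)
  }
  rmax0 <- max(sg$response)
  starts <- expand.grid(lkon = log(10^c(3, 4, 5, 6)),
                        lkoff = log(10^c(-3, -2, -1)),
                        lrmax = log(max(rmax0, 1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, KD = NA_real_,
                          rss = NA_real_,
                          n_concentrations = length(concs)),
                     class = "kinetic_fit"))
  p <- best$par
  kon <- exp(p[1]); koff <- exp(p[2]); Rmax <- exp(p[3])
  n <- nrow(sg); dof <- n - 3L
  se <- c(kon = NA_real_, koff = NA_real_, Rmax = NA_real_, KD = NA_real_)
  cov_ok <- FALSE
  covl <- tryCatch({
    s2 <- best$deviance / dof
    s2 * solve(best$hessian / 2) # hessian of SSR approx 2*J'J
  }, error = function(e) NULL)
  if (!is.null(covl) && all(is.finite(diag(covl))) &&
      all(diag(covl) >= 0)) {
    cov_ok <- TRUE
    sd_log <- sqrt(diag(covl))
    se["kon"] <- kon * sd_log[1]
    se["koff"] <- koff * sd_log[2]
    se["Rmax"] <- Rmax * sd_log[3]
    # log KD = log koff - log kon
    var_lkd <- covl[2, 2] + covl[1, 1] - 2 * covl[1, 2]
    se["KD"] <- (koff / kon) * sqrt(max(var_lkd, 0))
  }
  converged <- best$info %in% 1:4 && is.finite(best$deviance)
  structure(list(kon = kon, koff = koff, Rmax = Rmax, KD = koff / kon,
                 se = se, rss = best$deviance,
                 n_concentrations = length(concs), n_obs = n,
                 converged = converged, cov_ok = cov_ok),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("1:1 kinetic fit: NOT converged\n")
  } else {
    cat(sprintf(
      "1:1 kinetic fit over %d concentrations: kon = %.3g 1/(M*s), koff = %.3g 1/s, Rmax = %.1f RU\n  KD = %.3g M (%.3g uM), RSS = %.3g\n",
      x$n_concentrations, x$kon, x$koff, x$Rmax, x$KD, x$KD * 1e6, x$rss))
  }
  invisible(x)
}

#' Steady-state affinity fit
#'
#' Least-squares fit of the binding isotherm `Req(C) = Rmax * C / (KD + C)`
#' to equilibrium responses. A saturated series (Req flat in C) is flagged
#' `saturated` with KD at the zero boundary; a series still linear in C
#' (all C far below KD) is flagged `weak_affinity` and carries a large KD
#' standard error.
#'
#' @param concentration Concentrations (M), >= 3 values.
#' @param Req Equilibrium responses (RU).
#' @return A list of class `steady_state_fit`: `KD`, `Rmax`, `se`, `rss`,
#'   `converged`, `flags`.
#' @export
fit_steady_state <- function(concentration, Req) {
  stopifnot(length(concentration) == length(Req))
  if (length(concentration) < 3L)
    stop("steady-state fit requires >= 3 (C, Req) pairs")
  flags <- character(0)
  ord <- order(concentration)
  if (is.unsorted(Req[ord]) &&
      any(diff(Req[ord]) < -3 * stats::sd(Req) / sqrt(length(Req))))
    warning("Req not monotone in concentration beyond noise tolerance")
  rng <- diff(range(Req))
  if (rng < 1e-9 * max(abs(Req), 1)) {
    flags <- c(flags, "saturated")
    return(structure(list(KD = 0, Rmax = mean(Req),
                          se = c(KD = NA_real_, Rmax = NA_real_),
                          rss = sum((Req - mean(Req))^2),
                          converged = TRUE, flags = flags),
                     class = "steady_state_fit"))
  }
  df <- data.frame(C = concentration, R = Req)
  start <- list(Rmax = max(Req) * 1.5, KD = stats::median(concentration))
  fit <- tryCatch(
    minpack.lm::nlsLM(R ~ Rmax * C / (KD + C), data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(KD = NA_real_, Rmax = NA_real_,
                          se = c(KD = NA_real_, Rmax = NA_real_),
                          rss = NA_real_, converged = FALSE, flags = flags),
                     class = "steady_state_fit"))
  cf <- stats::coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- c(KD = NA_real_, Rmax = NA_real_)
  if (!is.null(sm)) {
    se["Rmax"] <- sm$coefficients["Rmax", "Std. Error"]
    se["KD"] <- sm$coefficients["KD", "Std. Error"]
  }
  if (is.finite(cf[["KD"]]) && cf[["KD"]] > 2 * max(concentration))
    flags <- c(flags, "weak_affinity")
  structure(list(KD = unname(cf[["KD"]]), Rmax = unname(cf[["Rmax"]])),
            class = "steady_state_fit") -> out
  out$se <- se
  out$rss <- sum(stats::resid(fit)^2)
  out$converged <- isTRUE(fit$convInfo$isConv) || !is.null(sm)
  out$flags <- flags
  out
}

#' Classify an SPR interaction
#'
#' Mirrors the instrument-software triage: `no_interaction` when the
#' maximal response at the highest concentration stays below three times
#' the baseline noise; `interaction` when a kinetic (or, failing that,
#' steady-state) fit converges and passes quality gates (relative KD
#' standard error < 0.5 and KD within the tested concentration range
#' extended one decade each way); `not_defined` when signal is present but
#' neither fit passes.
#'
#' @param fit A `kinetic_fit` (may be non-converged) or NULL.
#' @param max_response Response level at the highest tested concentration
#'   (RU); use an equilibrium estimate such as `max(extract_req(sg)$Req)`
#'   rather than a raw pointwise maximum, which rides on the noise floor.
#' @param noise_sd Baseline noise SD (RU).
#' @param concentration_range Tested concentrations (M) used for the KD
#'   plausibility gate; default `c(0.625e-6, 10e-6)`.
#' @param ss_fit Optional `steady_state_fit` fallback.
#' @return A list of class `interaction_call`: `label`
#'   (`interaction` / `no_interaction` / `not_defined`), `KD`, `KD_se`,
#'   `rationale`.
#' @export
classify_interaction <- function(fit, max_response, noise_sd,
                                 concentration_range = c(0.625e-6, 10e-6),
                                 ss_fit = NULL) {
  lo <- min(concentration_range) / 10
  hi <- max(concentration_range) * 10
  if (max_response < 3 * noise_sd)
    return(structure(list(label = "no_interaction", KD = NA_real_,
                          KD_se = NA_real_,
                          rationale = sprintf(
                            "max response %.2f RU below 3 x noise (%.2f RU)",
                            max_response, 3 * noise_sd)),
                     class = "interaction_call"))
  gate <- function(KD, KD_se) {
    is.finite(KD) && KD > 0 && KD >= lo && KD <= hi &&
      is.finite(KD_se) && KD_se / KD < 0.5
  }
  if (!is.null(fit) && isTRUE(fit$converged) &&
      gate(fit$KD, fit$se[["KD"]]))
    return(structure(list(label = "interaction", KD = fit$KD,
                          KD_se = fit$se[["KD"]],
                          rationale = "global 1:1 kinetic fit passed gates"),
                     class = "interaction_call"))
  if (!is.null(ss_fit) && isTRUE(ss_fit$converged) &&
      !("saturated" %in% ss_fit$flags) &&
      gate(ss_fit$KD, ss_fit$se[["KD"]]))
    return(structure(list(label = "interaction", KD = ss_fit$KD,
                          KD_se = ss_fit$se[["KD"]],
                          rationale = "steady-state affinity fit passed gates"),
                     class = "interaction_call"))
  structure(list(label = "not_defined", KD = NA_real_, KD_se = NA_real_,
                 rationale = "signal present but no fit passed quality gates"),
            class = "interaction_call")
}

#' Extract equilibrium responses per concentration from a titration
#'
#' Averages the late association phase (last `window` seconds before
#' `t_assoc`) per concentration as an Req estimate for steady-state
#' fitting.
#'
#' @param sg A titration sensorgram data.frame.
#' @param t_assoc Association end (s), default 180.
#' @param window Averaging window (s), default 10.
#' @return data.frame with `concentration`, `Req`.
#' @export
extract_req <- function(sg, t_assoc = 180, window = 10) {
  sel <- sg$time > t_assoc - window & sg$time <= t_assoc
  agg <- stats::aggregate(response ~ concentration, data = sg[sel, ],
                          FUN = mean)
  names(agg) <- c("concentration", "Req")
  agg[order(agg$concentration), ]
}
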