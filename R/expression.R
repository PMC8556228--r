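# qPCR relative quantification (2^-ddCt), group testing, and trajectory
# correlation.

#' Relative quantification by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the
#' calibrator-timepoint dCt and `RQ = 2^-ddCt`. By default the *mean*
#' calibrator dCt is subtracted, so the calibrator mean RQ is 1 while its
#' per-replicate RQs scatter around 1 (giving the day-0 error bars seen on
#' differentiation time courses); with `per_replicate_calibration` each
#' replicate is calibrated against its own day-0 dCt and every calibrator
#' RQ is exactly 1.
#'
#' @param ct A Ct table: data.frame with columns `sample`, `timepoint`,
#'   `replicate`, `gene`, `ct`.
#' @param target_gene,reference_gene Gene labels in `ct$gene`.
#' @param calibrator_timepoint Calibrator (default 0, i.e. day 0).
#' @param per_replicate_calibration Calibrate each replicate against its
#'   own calibrator dCt (default FALSE: mean-calibrator convention).
#' @return A list of class `rq_result`: `replicates` (per-replicate
#'   `timepoint`, `replicate`, `delta_ct`, `ddct`, `rq`) and `summary`
#'   (per-timepoint `mean_rq`, `sd_rq`, `n`), plus `calibrator`.
#' @export
delta_delta_ct <- function(ct, target_gene, reference_gene,
                           calibrator_timepoint = 0,
                           per_replicate_calibration = FALSE) {
  stopifnot(all(c("timepoint", "replicate", "gene", "ct") %in% names(ct)))
  stopifnot(all(ct$ct > 0 & ct$ct < 45))
  tgt <- ct[ct$gene == target_gene, ]
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(tgt) == 0L) stop("no records for target gene ", target_gene)
  if (nrow(ref) == 0L) stop("no records for reference gene ", reference_gene)
  key <- function(df) paste(df$timepoint, df$replicate, sep = "#")
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    warning(sum(is.na(m)), " record(s) dropped: reference Ct missing")
    tgt <- tgt[!is.na(m), ]
    m <- m[!is.na(m)]
  }
  dct <- tgt$ct - ref$ct[m]
  cal <- tgt$timepoint == calibrator_timepoint
  if (!any(cal)) stop("no calibrator records at timepoint ",
                      calibrator_timepoint)
  if (per_replicate_calibration) {
    cal_dct <- stats::setNames(dct[cal], tgt$replicate[cal])
    base <- cal_dct[as.character(tgt$replicate)]
    if (anyNA(base)) stop("calibrator dCt missing for some replicate(s)")
  } else {
    base <- mean(dct[cal])
  }
  ddct <- dct - base
  rq <- 2^(-ddct)
  reps <- data.frame(timepoint = tgt$timepoint, replicate = tgt$replicate,
                     delta_ct = dct, ddct = ddct, rq = rq)
  reps <- reps[order(reps$timepoint, reps$replicate), ]
  rownames(reps) <- NULL
  smry <- do.call(rbind, lapply(split(reps, reps$timepoint), function(g)
    data.frame(timepoint = g$timepoint[1], mean_rq = mean(g$rq),
               sd_rq = stats::sd(g$rq), n = nrow(g))))
  smry <- smry[order(smry$timepoint), ]
  rownames(smry) <- NULL
  structure(list(replicates = reps, summary = smry,
                 calibrator = calibrator_timepoint,
                 target = target_gene, reference = reference_gene),
            class = "rq_result")
}

#' @export
print.rq_result <- function(x, ...) {
  cat(sprintf("RQ (2^-ddCt) of %s vs %s, calibrator timepoint %s:\n",
              x$target, x$reference, format(x$calibrator)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Unpaired two-sample t test
#'
#' Pooled-variance Student's t by default (Welch by flag), two-tailed.
#' Degenerate zero-variance input with equal means yields p = 1; with
#' unequal means the result is flagged degenerate (p = 0).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance t (default FALSE).
#' @return A list: `t`, `df`, `p`, `stars`, `degenerate`.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  stars = "ns", degenerate = TRUE))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2L, p = 0,
                stars = significance_stars(0), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, stars = significance_stars(ht$p.value),
       degenerate = FALSE)
}

#' Map a p-value to figure-legend significance stars
#'
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001,
#' else `ns`.
#' @param p p-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment r with p from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return A list of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance; correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p = ht$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-tailed p = %.4g)\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Correlate two expression trajectories
#'
#' Pairs two RQ series on their shared timepoints (and replicates when both
#' carry them) and computes the Pearson correlation, e.g. to test whether a
#' miRNA's trajectory runs inverse to its target's.
#'
#' @param a,b Either `rq_result` objects or data.frames with columns
#'   `timepoint`, `value` (optionally `replicate`).
#' @return A `correlation_result` (see [pearson_cor()]).
#' @export
trajectory_correlation <- function(a, b) {
  norm <- function(x) {
    if (inherits(x, "rq_result"))
      return(data.frame(timepoint = x$replicates$timepoint,
                        replicate = x$replicates$replicate,
                        value = x$replicates$rq))
    stopifnot(all(c("timepoint", "value") %in% names(x)))
    x
  }
  a <- norm(a); b <- norm(b)
  by <- if ("replicate" %in% names(a) && "replicate" %in% names(b))
    c("timepoint", "replicate") else "timepoint"
  if (length(by) == 1L) {
    a <- stats::aggregate(value ~ timepoint, a, mean)
    b <- stats::aggregate(value ~ timepoint, b, mean)
  }
  mg <- merge(a, b, by = by, suffixes = c("_a", "_b"))
  if (nrow(mg) < 3L)
    stop("fewer than 3 shared points between trajectories")
  pearson_cor(mg$value_a, mg$value_b)
}

#' Per-timepoint significance tests on an RQ time course
#'
#' Tests each non-calibrator timepoint's per-replicate RQ values either
#' against the calibrator timepoint's RQs (`vs_calibrator`) or against a
#' matched undifferentiated-control series at the same timepoint
#' (`vs_control`); the contrast is an explicit choice because time-course
#' figures are commonly annotated either way.
#'
#' @param rq An `rq_result` from [delta_delta_ct()].
#' @param contrast `"vs_calibrator"` or `"vs_control"`.
#' @param control An `rq_result` for the control series (required for
#'   `vs_control`).
#' @param welch Passed to [unpaired_t()].
#' @return data.frame with `timepoint`, `t`, `df`, `p`, `stars`.
#' @export
timepoint_tests <- function(rq, contrast = c("vs_calibrator", "vs_control"),
                            control = NULL, welch = FALSE) {
  contrast <- match.arg(contrast)
  reps <- rq$replicates
  tps <- setdiff(sort(unique(reps$timepoint)), rq$calibrator)
  if (contrast == "vs_control") {
    if (is.null(control)) stop("vs_control contrast requires a control series")
    ctrl_reps <- control$replicates
  } else {
    baseline <- reps$rq[reps$timepoint == rq$calibrator]
  }
  rows <- lapply(tps, function(tp) {
    grp <- reps$rq[reps$timepoint == tp]
    other <- if (contrast == "vs_control")
      ctrl_reps$rq[ctrl_reps$timepoint == tp] else baseline
    if (length(other) < 2L) return(NULL)
    ht <- unpaired_t(grp, other, welch = welch)
    data.frame(timepoint = tp, t = ht$t, df = ht$df, p = ht$p,
               stars = ht$stars, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(timepoint = numeric(0), t = numeric(0),
                      df = numeric(0), p = numeric(0), stars = character(0))
  rownames(out) <- NULL
  out
}

#' Read a Ct CSV (`sample,timepoint,replicate,gene,ct`)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "timepoint", "replicate", "gene", "ct") %in%
                  names(tab)))
  tab
}

#' Write a Ct CSV
#' @param ct data.frame with `sample,timepoint,replicate,gene,ct`.
#' @param path Output path.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE)
  invisible(path)
}
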