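# End-to-end orchestration over a fixture directory: variant calling,
# region annotation, motif delta scoring, seed-site diffing, SPR fitting
# and expression statistics, assembled into one report.

#' Run configuration for the locus pipeline
#'
#' @param fixture_dir Directory holding the pipeline inputs (see
#'   [simulate_fixture_dir()] for the expected files).
#' @param out_dir Output directory for report files; NULL for none.
#' @param variant_threshold Quality-weight fraction for variant calls
#'   (strict), default 0.79.
#' @param pwm_threshold Motif scan threshold as a fraction of the maximal
#'   PWM score, default 0.8.
#' @param site_types miRNA site types to report.
#' @param alpha Significance level for expression statistics, default 0.05.
#' @param stages Character vector of stages to run, a subset of
#'   `c("variants", "regions", "motifs", "mirna", "spr", "expression")`.
#' @param seed RNG seed (the pipeline itself is deterministic given its
#'   inputs; the seed is recorded for provenance and used by any stage that
#'   resamples).
#' @return A list of class `run_config`.
#' @export
run_config <- function(fixture_dir, out_dir = NULL,
                       variant_threshold = 0.79, pwm_threshold = 0.8,
                       site_types = SITE_TYPES, alpha = 0.05,
                       stages = c("variants", "regions", "motifs", "mirna",
                                  "spr", "expression"),
                       seed = 1L) {
  stopifnot(dir.exists(fixture_dir),
            variant_threshold > 0, variant_threshold < 1,
            pwm_threshold >= 0, pwm_threshold <= 1,
            alpha > 0, alpha < 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

fixture_path <- function(config, name) {
  p <- file.path(config$fixture_dir, name)
  if (!file.exists(p)) return(NULL)
  p
}

#' Run the locus pipeline
#'
#' Executes the configured stages over the fixture directory and returns a
#' report list; each section equals the standalone module output on the
#' same inputs. When `out_dir` is set, writes `report.json`, `report.md`
#' and per-stage TSV tables. Missing input files skip their stage.
#'
#' @param config A [run_config()].
#' @return A list of class `locus_report` with one element per executed
#'   stage plus `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list()
  calls <- NULL

  if ("variants" %in% config$stages) {
    probes_path <- fixture_path(config, "utr_probes.fa") %||%
      system.file("extdata", "distal_3utr_probes.fa", package = "runx2reg")
    probes <- read_alleles_fasta(probes_path)
    probe_diff <- diff_sequences(probes[["AMH"]], probes[["archaic"]])
    pu_path <- fixture_path(config, "pileup.tsv")
    if (!is.null(pu_path)) {
      pu <- read_pileup_tsv(pu_path)
      calls <- call_variants(pu, threshold = config$variant_threshold)
    }
    report$variants <- list(
      distal_3UTR_substitutions = nrow(probe_diff),
      probe_diff = probe_diff,
      calls = if (is.null(calls)) NULL else as.data.frame(calls))
  }

  if ("regions" %in% config$stages && !is.null(calls)) {
    bed <- fixture_path(config, "regions.bed")
    if (!is.null(bed)) {
      map <- read_region_bed(bed)
      ann <- annotate_variants(calls, map)
      report$regions <- list(counts = as.list(ann$counts),
                             table = ann$table)
    }
  }

  if ("motifs" %in% config$stages) {
    meme <- fixture_path(config, "motifs.meme")
    fa <- fixture_path(config, "locus_alleles.fa")
    if (!is.null(meme) && !is.null(fa)) {
      pwms <- read_meme(meme)
      alle <- read_alleles_fasta(fa)
      deltas <- lapply(pwms, function(p) {
        ds <- delta_score(alle[[2]], alle[[1]], p)
        data.frame(motif = p$name, ref_best_score = ds$ref_best_score,
                   alt_best_score = ds$alt_best_score, delta = ds$delta,
                   direction = ds$direction, stringsAsFactors = FALSE)
      })
      report$motifs <- list(deltas = do.call(rbind, deltas))
    }
  }

  if ("mirna" %in% config$stages) {
    fa <- fixture_path(config, "utr_alleles.fa")
    panel_path <- fixture_path(config, "mirna_panel.tsv")
    if (!is.null(fa) && !is.null(panel_path)) {
      utrs <- read_alleles_fasta(fa)
      panel <- read_mirna_tsv(panel_path)
      sd_ <- diff_sites(utrs[["utr_ref"]], utrs[["utr_alt"]], panel,
                        site_types = config$site_types)
      report$mirna <- list(n_gained = nrow(sd_$gained),
                           n_lost = nrow(sd_$lost),
                           gained = sd_$gained, lost = sd_$lost)
    }
  }

  if ("spr" %in% config$stages) {
    csvp <- fixture_path(config, "sensorgrams.csv")
    if (!is.null(csvp)) {
      sg <- read_sensorgram_csv(csvp)
      fit <- fit_global_1to1(sg)
      req <- extract_req(sg)
      ss <- fit_steady_state(req$concentration, req$Req)
      base_sd <- stats::sd(sg$response[sg$time <= 2])
      if (!is.finite(base_sd) || base_sd == 0) base_sd <- 0.1
      call <- classify_interaction(
        fit, max_response = max(req$Req), noise_sd = base_sd,
        concentration_range = range(sg$concentration), ss_fit = ss)
      report$spr <- list(kinetic = fit[c("kon", "koff", "Rmax", "KD",
                                         "converged")],
                         KD_uM = fit$KD * 1e6,
                         steady_state_KD_uM = ss$KD * 1e6,
                         label = call$label)
    }
  }

  if ("expression" %in% config$stages) {
    ctp <- fixture_path(config, "ct_table.csv")
    if (!is.null(ctp)) {
      ct <- read_ct_csv(ctp)
      rq_target <- delta_delta_ct(ct, "RUNX2", "ACTB")
      expr <- list(target_summary = rq_target$summary,
                   tests = timepoint_tests(rq_target))
      if ("miR-3150a-3p" %in% ct$gene) {
        rq_mir <- delta_delta_ct(ct, "miR-3150a-3p", "cel-miR-39-3p")
        corr <- trajectory_correlation(rq_target, rq_mir)
        expr$mirna_summary <- rq_mir$summary
        expr$correlation <- list(r = corr$r, p = corr$p, n = corr$n)
      }
      report$expression <- expr
    }
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("runx2reg")),
    seed = config$seed,
    variant_threshold = config$variant_threshold,
    stages = config$stages,
    fixture_dir = normalizePath(config$fixture_dir))
  class(report) <- "locus_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to disk
#'
#' Emits `report.json` (full report), `report.md` (human-readable summary)
#' and per-stage TSV tables.
#'
#' @param report A `locus_report` from [run_pipeline()].
#' @param out_dir Output directory (created).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  md <- c("# RUNX2 locus regulatory report", "")
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$variants)) {
    md <- c(md, sprintf("- distal_3UTR substitutions: %d",
                        report$variants$distal_3UTR_substitutions))
    if (!is.null(report$variants$calls)) {
      md <- c(md, sprintf("- pileup variant calls: %d",
                          nrow(report$variants$calls)))
      tsv(report$variants$calls, "variant_calls.tsv")
    }
  }
  if (!is.null(report$regions)) {
    cnt <- unlist(report$regions$counts)
    md <- c(md, "- variant counts by region:",
            sprintf("    - %s: %d", names(cnt), cnt))
    tsv(report$regions$table, "region_annotation.tsv")
  }
  if (!is.null(report$motifs)) {
    md <- c(md, "- motif delta scores:",
            sprintf("    - %s: %.3f -> %.3f (%s)",
                    report$motifs$deltas$motif,
                    report$motifs$deltas$ref_best_score,
                    report$motifs$deltas$alt_best_score,
                    report$motifs$deltas$direction))
    tsv(report$motifs$deltas, "motif_deltas.tsv")
  }
  if (!is.null(report$mirna)) {
    md <- c(md, sprintf("- miRNA seed sites: %d gained, %d lost",
                        report$mirna$n_gained, report$mirna$n_lost))
    if (nrow(report$mirna$gained)) tsv(report$mirna$gained,
                                       "sites_gained.tsv")
    if (nrow(report$mirna$lost)) tsv(report$mirna$lost, "sites_lost.tsv")
  }
  if (!is.null(report$spr)) {
    md <- c(md, sprintf("- SPR: %s, kinetic KD = %.3g uM (steady state %.3g uM)",
                        report$spr$label, report$spr$KD_uM,
                        report$spr$steady_state_KD_uM))
  }
  if (!is.null(report$expression)) {
    md <- c(md, "- expression (RQ by timepoint):")
    s <- report$expression$target_summary
    md <- c(md, sprintf("    - day %g: %.2f +/- %.2f", s$timepoint,
                        s$mean_rq, s$sd_rq))
    if (!is.null(report$expression$correlation))
      md <- c(md, sprintf("- miRNA/target trajectory correlation: r = %.3f (p = %.3g)",
                          report$expression$correlation$r,
                          report$expression$correlation$p))
    tsv(s, "expression_rq.tsv")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.locus_report <- function(x, ...) {
  cat("RUNX2 locus regulatory report; stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
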