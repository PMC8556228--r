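# Seeded generators for every input the pipeline consumes, each emitting
# machine-readable planted ground truth. These stand in for ancient-genome
# alignments and wet-lab measurements, which cannot be redistributed; they
# emulate the *shapes* of those data (substitution-bearing allele pairs,
# mixed-quality pileups, planted motifs and seed sites, two-phase
# sensorgrams, replicated Ct tables), not ancient-DNA damage or instrument
# artifacts.

#' Synthetic study configuration
#'
#' Bundles the defaults used across generators: a 2-kb locus with a handful
#' of substitutions, 50x pileups with Phred ~ round(Normal(30, 5)) quality
#' (weight `1 - 10^(-Q/10)`), a five-concentration two-fold SPR dilution
#' series from 10 uM, and five qPCR replicates over differentiation days
#' 0/3/6/10/14/21.
#'
#' @param seed Integer RNG seed.
#' @param locus_length Synthetic locus length (nt).
#' @param substitution_count Planted substitutions in allele pairs.
#' @param depth Pileup read depth.
#' @param quality_mean,quality_sd Phred quality distribution.
#' @param spr_concentrations Analyte concentrations (M).
#' @param spr_noise_sd Sensorgram noise SD (RU).
#' @param timepoints Differentiation days.
#' @param n_replicates qPCR replicates per timepoint.
#' @param ct_sd Replicate Ct noise SD (cycles).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, locus_length = 2000L,
                       substitution_count = 10L, depth = 50L,
                       quality_mean = 30, quality_sd = 5,
                       spr_concentrations = c(10, 5, 2.5, 1.25, 0.625) * 1e-6,
                       spr_noise_sd = 1, timepoints = c(0, 3, 6, 10, 14, 21),
                       n_replicates = 5L, ct_sd = 0.25) {
  stopifnot(locus_length > 0, substitution_count >= 0, depth >= 0,
            quality_sd >= 0, spr_noise_sd >= 0, n_replicates >= 1,
            ct_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) paste(sample(VALID_BASES, n, replace = TRUE),
                                collapse = "")

other_base <- function(b) vapply(b, function(x)
  sample(setdiff(VALID_BASES, x), 1L), "")

#' Generate a reference/alternate allele pair with planted substitutions
#'
#' @param length Sequence length; ignored when `template` is given.
#' @param n_subs Number of planted substitutions (ignored when `positions`
#'   is given).
#' @param positions Optional explicit distinct substitution positions.
#' @param template Optional reference sequence to mutate (defaults to a
#'   random sequence of `length`).
#' @param seed RNG seed.
#' @return A list: `ref`, `alt`, `truth` (data.frame `position`,
#'   `ref_allele`, `alt_allele`).
#' @export
make_allele_pair <- function(length = 2000L, n_subs = 10L, positions = NULL,
                             template = NULL, seed = 1L) {
  set.seed(seed)
  ref <- if (is.null(template)) random_dna(length) else normalize_nt(template)
  L <- nchar(ref)
  if (is.null(positions)) {
    stopifnot(n_subs <= L)
    positions <- sort(sample.int(L, n_subs))
  } else {
    positions <- sort(as.integer(positions))
    if (anyDuplicated(positions)) stop("substitution positions collide")
    stopifnot(all(positions >= 1L & positions <= L))
  }
  alt <- ref
  refb <- if (length(positions)) substring(ref, positions, positions)
          else character(0)
  altb <- other_base(refb)
  for (i in seq_along(positions))
    substr(alt, positions[i], positions[i]) <- altb[i]
  list(ref = ref, alt = alt,
       truth = data.frame(position = positions,
                          ref_allele = unname(refb),
                          alt_allele = unname(altb),
                          stringsAsFactors = FALSE))
}

#' The two distal 3'UTR probe alleles
#'
#' Returns the packaged 36-nt modern-human and archaic
#' (Neandertal/Denisovan) probe sequences for the variable region of the
#' distal 3'UTR, which differ by two substitutions.
#'
#' @return Named character vector with elements `AMH` and `archaic`.
#' @export
runx2_probe_alleles <- function() {
  path <- system.file("extdata", "distal_3utr_probes.fa",
                      package = "runx2reg", mustWork = TRUE)
  read_alleles_fasta(path)
}

#' Simulate a quality-weighted pileup over an allele pair
#'
#' Draws `depth` reads per site; each read carries the alternate base with
#' probability `alt_fraction` (at sites where the alleles differ) and a
#' weight `1 - 10^(-Q/10)` with Phred `Q ~ round(Normal(mean, sd))`
#' truncated to `[2, 41]`.
#'
#' @param ref,alt Equal-length allele sequences.
#' @param depth Reads per site, > 0.
#' @param alt_fraction Per-read probability of the alternate allele at
#'   differing sites, in `[0, 1]`.
#' @param quality_mean,quality_sd Phred distribution parameters.
#' @param error_rate Per-read probability of a uniformly random wrong base
#'   (sequencing noise), default 0.01.
#' @param seed RNG seed.
#' @return A list of [pileup_column()] objects (positions 1..L).
#' @export
make_pileup <- function(ref, alt = ref, depth = 50L, alt_fraction = 0.9,
                        quality_mean = 30, quality_sd = 5,
                        error_rate = 0.01, seed = 1L) {
  if (depth <= 0L) stop("depth must be > 0")
  stopifnot(alt_fraction >= 0, alt_fraction <= 1)
  ref <- normalize_nt(ref); alt <- normalize_nt(alt)
  stopifnot(nchar(ref) == nchar(alt))
  set.seed(seed)
  L <- nchar(ref)
  lapply(seq_len(L), function(i) {
    rb <- substr(ref, i, i); ab <- substr(alt, i, i)
    is_alt <- stats::runif(depth) < alt_fraction & rb != ab
    bases <- ifelse(is_alt, ab, rb)
    err <- stats::runif(depth) < error_rate
    bases[err] <- sample(VALID_BASES, sum(err), replace = TRUE)
    q <- pmin(pmax(round(stats::rnorm(depth, quality_mean, quality_sd)),
                   2), 41)
    pileup_column(i, rb, bases, 1 - 10^(-q / 10))
  })
}

#' Synthetic locus region map
#'
#' Lays out a miniature locus with the region classes of the real one: a
#' distal (P1) and proximal (P2) promoter, exons with intervening introns,
#' proximal and distal 3'UTRs, an antisense lncRNA overlapping P2 (as
#' *AL096865.1* overlaps the real proximal promoter), and a second lncRNA
#' inside the last intron (as *RUNX2-AS1*). Coordinates scale with
#' `locus_length`.
#'
#' @param locus_length Total locus span (default 2000).
#' @param chrom Chromosome name.
#' @return A `GRanges` region map (see [region_map()]).
#' @export
make_region_map <- function(locus_length = 2000L, chrom = "chr6") {
  u <- locus_length / 20 # one layout unit
  iv <- function(a, b, cat) data.frame(start = round(a * u),
                                       end = round(b * u), cat = cat)
  lay <- rbind(
    iv(0, 1, "P1"), iv(1, 2, "exon"), iv(2, 6, "intron"),
    iv(6, 7, "P2"), iv(6.5, 8, "lncRNA_AL096865.1"),
    iv(7, 8, "exon"), iv(8, 12, "intron"), iv(12, 13, "exon"),
    iv(13, 14, "proximal_3UTR"), iv(14, 17, "intron"),
    iv(15, 16, "lncRNA_RUNX2-AS1"), iv(17, 18, "exon"),
    iv(18, 19, "distal_3UTR"))
  region_map(chrom, lay$start, lay$end, lay$cat)
}

#' Plant motif occurrences in a random background sequence
#'
#' @param pwm A [build_pwm()] object; its consensus string is planted.
#' @param length Background length.
#' @param positions 1-based insertion positions (consensus overwrites the
#'   background starting there).
#' @param seed RNG seed.
#' @return A list: `sequence`, `positions`, `consensus`.
#' @export
plant_motif <- function(pwm, length = 200L, positions = NULL, seed = 1L) {
  set.seed(seed)
  W <- pwm$width
  stopifnot(length >= W)
  if (is.null(positions)) positions <- sample.int(length - W + 1L, 1L)
  seqc <- random_dna(length)
  for (p in positions) {
    stopifnot(p >= 1L, p + W - 1L <= length)
    substr(seqc, p, p + W - 1L) <- pwm$consensus
  }
  list(sequence = seqc, positions = sort(positions),
       consensus = pwm$consensus)
}

#' Plant a miRNA seed site completed by a single substitution
#'
#' Builds a UTR pair in which the alternate allele carries a perfect site
#' of the requested type while the reference allele differs by one base
#' inside the 6mer core, so the site exists in the alternate allele only.
#'
#' @param mir A [mirna()] object.
#' @param utr_length UTR length.
#' @param site_position 1-based position of the 6mer core in the UTR.
#' @param site_type Planted type, default `"8mer"`.
#' @param seed RNG seed.
#' @return A list: `utr_ref`, `utr_alt`, `core_start`, `changed_position`.
#' @export
plant_seed_site <- function(mir, utr_length = 60L, site_position = 25L,
                            site_type = "8mer", seed = 1L) {
  stopifnot(inherits(mir, "mirna"))
  set.seed(seed)
  m <- chartr("U", "T", mir$mature)
  rc6 <- rc_nt(substr(m, 2L, 7L))
  rc7 <- rc_nt(substr(m, 2L, 8L))
  need_m8 <- site_type %in% c("8mer", "7mer-m8")
  need_a1 <- site_type %in% c("8mer", "7mer-A1")
  lo_pad <- if (need_m8) 1L else 0L
  hi_pad <- if (need_a1) 1L else 0L
  stopifnot(site_position - lo_pad >= 1L,
            site_position + 5L + hi_pad <= utr_length)
  utr <- random_dna(utr_length)
  # scrub accidental cores, then write the planted site
  repeat {
    hits <- Biostrings::start(Biostrings::matchPattern(rc6, utr))
    if (!length(hits)) break
    i <- hits[1] + 2L
    substr(utr, i, i) <- other_base(substr(utr, i, i))
  }
  if (need_m8) substr(utr, site_position - 1L, site_position + 5L) <- rc7
  else substr(utr, site_position, site_position + 5L) <- rc6
  if (need_a1) substr(utr, site_position + 6L, site_position + 6L) <- "A"
  else if (site_position + 6L <= utr_length &&
           substr(utr, site_position + 6L, site_position + 6L) == "A")
    substr(utr, site_position + 6L, site_position + 6L) <- "G"
  if (!need_m8 && site_position > 1L &&
      substr(utr, site_position - 1L, site_position + 5L) == rc7)
    substr(utr, site_position - 1L, site_position - 1L) <-
      other_base(substr(rc7, 1L, 1L))
  utr_alt <- utr
  # break the core in the reference allele with one substitution, choosing
  # a base that does not create a core elsewhere
  changed <- site_position + 2L
  utr_ref <- utr_alt
  for (b in sample(setdiff(VALID_BASES, substr(utr_alt, changed, changed)))) {
    substr(utr_ref, changed, changed) <- b
    if (length(Biostrings::matchPattern(rc6, utr_ref)) == 0L) break
  }
  list(utr_ref = utr_ref, utr_alt = utr_alt, core_start = site_position,
       changed_position = changed)
}

#' Simulate a replicated qPCR Ct table with a planted fold-change trajectory
#'
#' `Ct_target = baseline - log2(fold(t)) + e`, `Ct_ref = ref_baseline + e'`
#' with independent `e, e' ~ Normal(0, sd)`, so the expected RQ at
#' timepoint t equals `fold(t)`.
#'
#' @param fold Named numeric vector of fold changes, names = timepoints
#'   (days); the calibrator timepoint must have fold 1.
#' @param gene Target gene label.
#' @param reference Reference gene label (default `"ACTB"`).
#' @param baseline_ct,ref_baseline_ct Baseline Ct values.
#' @param sd Replicate Ct noise SD, >= 0.
#' @param n_replicates Replicates per timepoint (default 5).
#' @param sample Sample label.
#' @param seed RNG seed.
#' @return A Ct data.frame (`sample`, `timepoint`, `replicate`, `gene`,
#'   `ct`) containing both target and reference records.
#' @export
make_expression_table <- function(fold, gene = "RUNX2", reference = "ACTB",
                                  baseline_ct = 24, ref_baseline_ct = 18,
                                  sd = 0.25, n_replicates = 5L,
                                  sample = "CMSC", seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  stopifnot(!is.null(names(fold)), all(fold > 0))
  set.seed(seed)
  tps <- as.numeric(names(fold))
  rows <- lapply(seq_along(tps), function(i) {
    reps <- seq_len(n_replicates)
    rbind(
      data.frame(sample = sample, timepoint = tps[i], replicate = reps,
                 gene = gene,
                 ct = baseline_ct - log2(fold[i]) +
                   stats::rnorm(n_replicates, 0, sd)),
      data.frame(sample = sample, timepoint = tps[i], replicate = reps,
                 gene = reference,
                 ct = ref_baseline_ct + stats::rnorm(n_replicates, 0, sd)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default planted expression trajectories
#'
#' Target trajectory: initial down-regulation then a rise through day 21
#' (the shape seen for total target-gene levels during in vitro osteogenic
#' induction); inhibitory miRNA trajectory: monotone decline, the mirror
#' image that produces an inverse correlation.
#'
#' @return A list of named fold-change vectors `target` and `mirna` over
#'   days 0/3/6/10/14/21.
#' @export
default_trajectories <- function() {
  tps <- c(0, 3, 6, 10, 14, 21)
  list(target = stats::setNames(c(1, 0.5, 1, 2, 4, 4), tps),
       mirna = stats::setNames(c(1, 0.8, 0.6, 0.4, 0.3, 0.25), tps))
}

#' Write a self-contained synthetic fixture directory
#'
#' Emits every input the pipeline consumes — allele FASTA, pileup TSV,
#' region BED, miRNA panel TSV, UTR allele FASTA, sensorgram CSV,
#' Ct CSV — plus `truth.json` recording all planted ground truth.
#'
#' @param dir Output directory (created).
#' @param config A [sim_config()].
#' @return Invisibly, the truth list.
#' @export
simulate_fixture_dir <- function(dir, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  pair <- make_allele_pair(config$locus_length, config$substitution_count,
                           seed = seed)
  write_alleles_fasta(c(AMH = pair$alt, archaic = pair$ref),
                      file.path(dir, "locus_alleles.fa"))
  pu <- make_pileup(pair$ref, pair$alt, depth = config$depth,
                    alt_fraction = 0.9,
                    quality_mean = config$quality_mean,
                    quality_sd = config$quality_sd, seed = seed + 1L)
  write_pileup_tsv(pu, file.path(dir, "pileup.tsv"))
  map <- make_region_map(config$locus_length)
  write_region_bed(map, file.path(dir, "regions.bed"))
  mir <- mirna("cel-miR-39-3p", "UCACCGGGUGUAAAUCAGCUUG")
  site <- plant_seed_site(mir, utr_length = 60L, site_position = 25L,
                          seed = seed + 2L)
  write_alleles_fasta(c(utr_ref = site$utr_ref, utr_alt = site$utr_alt),
                      file.path(dir, "utr_alleles.fa"))
  panel <- data.frame(name = mir$name, mature_sequence = mir$mature)
  utils::write.table(panel, file.path(dir, "mirna_panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spr_true <- list(kon = 1e4, koff = 1e-2, Rmax = 100)
  sg <- simulate_titration(spr_true$kon, spr_true$koff, spr_true$Rmax,
                           concentrations = config$spr_concentrations,
                           noise_sd = config$spr_noise_sd, seed = seed + 3L)
  write_sensorgram_csv(sg, file.path(dir, "sensorgrams.csv"))
  traj <- default_trajectories()
  ct <- rbind(
    make_expression_table(traj$target, gene = "RUNX2", sd = config$ct_sd,
                          n_replicates = config$n_replicates,
                          seed = seed + 4L),
    make_expression_table(traj$mirna, gene = "miR-3150a-3p",
                          reference = "cel-miR-39-3p", sd = config$ct_sd,
                          n_replicates = config$n_replicates,
                          seed = seed + 5L))
  write_ct_csv(ct, file.path(dir, "ct_table.csv"))
  truth <- list(seed = seed,
                variants = pair$truth,
                planted_alt_fraction = 0.9,
                seed_site = site[c("core_start", "changed_position")],
                spr = c(spr_true, KD = spr_true$koff / spr_true$kon),
                trajectories = lapply(traj, as.list))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
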