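# Canonical miRNA seed-match detection in 3'UTR sequences and per-variant
# gain/loss classification between alleles.
#
# Site definitions (canonical Watson-Crick, no G:U wobble), with the UTR in
# sense (mRNA) orientation and m = mature miRNA 5'->3':
#   6mer     UTR matches rc(m[2..7])
#   7mer-m8  UTR matches rc(m[2..8])
#   7mer-A1  UTR matches rc(m[2..7]) followed by an A
#   8mer     UTR matches rc(m[2..8]) followed by an A
# A locus is keyed by the start of its 6mer core (the rc(m[2..7]) match);
# overlapping matches of the same miRNA at one locus collapse to the most
# specific type.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

rc_nt <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct a miRNA record
#'
#' @param name miRNA name.
#' @param mature Mature sequence, 5'->3', length >= 8 (RNA or DNA alphabet;
#'   T and U equivalent).
#' @return A list of class `mirna` with fields `name`, `mature` (RNA
#'   alphabet) and `seed` (nucleotides 2-8).
#' @export
mirna <- function(name, mature) {
  m <- normalize_nt(mature) # validates alphabet, U -> T
  if (nchar(m) < 8L) stop("mature miRNA must be at least 8 nt: ", name)
  structure(list(name = name, mature = chartr("T", "U", m),
                 seed = chartr("T", "U", substr(m, 2L, 8L))),
            class = "mirna")
}

#' Find canonical seed-match sites of one miRNA in a UTR
#'
#' Reports, at each matching locus, the most specific site type among those
#' requested. `utr_start` is the 1-based start of the matched span on the
#' UTR (for 7mer-m8/8mer this is one base 5' of the 6mer core, covering the
#' m8 pair).
#'
#' @param utr UTR sequence, sense orientation (T and U equivalent).
#' @param mir A [mirna()] object (or a mature-sequence string, named via
#'   `deparse`).
#' @param site_types Site types to consider, subset of
#'   `c("8mer", "7mer-m8", "7mer-A1", "6mer")`.
#' @return data.frame with `mirna`, `utr_start`, `site_type`,
#'   `matched_target_sequence`, `core_start` (start of the 6mer core; the
#'   locus key).
#' @export
find_seed_sites <- function(utr, mir, site_types = SITE_TYPES) {
  if (!inherits(mir, "mirna")) mir <- mirna("miRNA", mir)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  utr <- normalize_nt(utr)
  m <- chartr("U", "T", mir$mature)
  rc6 <- rc_nt(substr(m, 2L, 7L)) # 6mer core complement
  rc7 <- rc_nt(substr(m, 2L, 8L)) # adds the m8 pair one base 5'
  L <- nchar(utr)
  empty <- data.frame(mirna = character(0), utr_start = integer(0),
                      site_type = character(0),
                      matched_target_sequence = character(0),
                      core_start = integer(0), stringsAsFactors = FALSE)
  if (L < 6L) return(empty)
  cores <- Biostrings::start(Biostrings::matchPattern(rc6, utr))
  if (!length(cores)) return(empty)
  rows <- lapply(cores, function(cs) {
    has_m8 <- cs > 1L && substr(utr, cs - 1L, cs + 5L) == rc7
    has_a1 <- cs + 6L <= L && substr(utr, cs + 6L, cs + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer"
            else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1"
            else "6mer"
    # degrade to the most specific *requested* type that still holds
    candidates <- switch(type,
      "8mer" = SITE_TYPES,
      "7mer-m8" = c("7mer-m8", "6mer"),
      "7mer-A1" = c("7mer-A1", "6mer"),
      "6mer" = "6mer")
    type <- candidates[candidates %in% site_types][1]
    if (is.na(type)) return(NULL)
    span <- switch(type,
      "8mer"    = c(cs - 1L, cs + 6L),
      "7mer-m8" = c(cs - 1L, cs + 5L),
      "7mer-A1" = c(cs, cs + 6L),
      "6mer"    = c(cs, cs + 5L))
    data.frame(mirna = mir$name, utr_start = span[1], site_type = type,
               matched_target_sequence = substr(utr, span[1], span[2]),
               core_start = cs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Diff seed sites between two UTR alleles
#'
#' Scans both alleles against a miRNA panel and classifies sites as gained
#' (alt only), lost (ref only) or retained with a changed site type, keyed
#' by (miRNA, 6mer-core position). Only sites whose seed-matched span
#' overlaps a differing position can change; this locality is asserted
#' internally.
#'
#' @param utr_ref,utr_alt Same-length (pre-aligned) UTR allele sequences.
#' @param panel A data.frame with columns `name`, `mature_sequence`, or a
#'   list of [mirna()] objects.
#' @param site_types Passed to [find_seed_sites()].
#' @return A list of class `site_diff`: `gained`, `lost`,
#'   `retained_type_changed` (data.frames as from [find_seed_sites()]; the
#'   retained table has `site_type_ref` / `site_type_alt`), and
#'   `changed_positions`.
#' @export
diff_sites <- function(utr_ref, utr_alt, panel, site_types = SITE_TYPES) {
  mirs <- as_mirna_panel(panel)
  changed <- diff_sequences(utr_ref, utr_alt)$position
  if (length(mirs) == 0L) {
    warning("empty miRNA panel; nothing to diff")
    empty <- find_seed_sites("ACGTACGT", mirna("x", "ACGUACGU"))[0, ]
    return(structure(list(gained = empty, lost = empty,
                          retained_type_changed = empty[0, ],
                          changed_positions = changed),
                     class = "site_diff"))
  }
  ref_sites <- do.call(rbind, lapply(mirs, function(m)
    find_seed_sites(utr_ref, m, site_types)))
  alt_sites <- do.call(rbind, lapply(mirs, function(m)
    find_seed_sites(utr_alt, m, site_types)))
  key <- function(df) paste(df$mirna, df$core_start, sep = "@")
  rk <- key(ref_sites); ak <- key(alt_sites)
  gained <- alt_sites[!(ak %in% rk), , drop = FALSE]
  lost <- ref_sites[!(rk %in% ak), , drop = FALSE]
  shared <- intersect(rk, ak)
  ri <- match(shared, rk); ai <- match(shared, ak)
  changed_type <- which(ref_sites$site_type[ri] != alt_sites$site_type[ai])
  retained <- data.frame(
    mirna = ref_sites$mirna[ri][changed_type],
    core_start = ref_sites$core_start[ri][changed_type],
    site_type_ref = ref_sites$site_type[ri][changed_type],
    site_type_alt = alt_sites$site_type[ai][changed_type],
    stringsAsFactors = FALSE)
  rownames(gained) <- rownames(lost) <- NULL
  # locality: a gained/lost locus exists in one allele only, so its 6mer
  # core must contain a changed position
  overlaps_change <- function(df) {
    if (nrow(df) == 0L || length(changed) == 0L) return(TRUE)
    spans_ok <- vapply(seq_len(nrow(df)), function(i) {
      any(changed >= df$core_start[i] & changed <= df$core_start[i] + 5L)
    }, TRUE)
    all(spans_ok)
  }
  stopifnot(overlaps_change(gained), overlaps_change(lost))
  structure(list(gained = gained, lost = lost,
                 retained_type_changed = retained,
                 changed_positions = changed),
            class = "site_diff")
}

#' @export
print.site_diff <- function(x, ...) {
  cat(sprintf("seed-site diff: %d gained, %d lost, %d type-changed (%d changed position%s)\n",
              nrow(x$gained), nrow(x$lost), nrow(x$retained_type_changed),
              length(x$changed_positions),
              if (length(x$changed_positions) == 1L) "" else "s"))
  invisible(x)
}

as_mirna_panel <- function(panel) {
  if (is.data.frame(panel)) {
    stopifnot(all(c("name", "mature_sequence") %in% names(panel)))
    panel <- panel[!is.na(panel$mature_sequence) &
                     nzchar(panel$mature_sequence), , drop = FALSE]
    lapply(seq_len(nrow(panel)), function(i)
      mirna(panel$name[i], panel$mature_sequence[i]))
  } else if (all(vapply(panel, inherits, TRUE, "mirna"))) {
    panel
  } else stop("panel must be a data.frame or a list of mirna objects")
}

#' Flag whether a variant lies inside seed-matched spans
#'
#' The seed-matched span is the stretch of the UTR paired with miRNA
#' nucleotides 2-7 (plus position 8 for m8-type sites); the A1 adenine,
#' which is recognized by the silencing complex rather than paired with the
#' seed, is excluded.
#'
#' @param position 1-based variant position on the UTR.
#' @param sites data.frame from [find_seed_sites()].
#' @return Logical vector, one flag per site.
#' @export
variant_in_seed_region <- function(position, sites) {
  if (nrow(sites) == 0L) return(logical(0))
  s <- ifelse(sites$site_type %in% c("8mer", "7mer-m8"),
              sites$core_start - 1L, sites$core_start)
  e <- sites$core_start + 5L
  position >= s & position <= e
}

#' Read a miRNA panel TSV (`name<TAB>mature_sequence`)
#' @param path TSV path; rows with an empty mature sequence are kept in the
#'   table (placeholders) but dropped when the panel is scanned.
#' @return data.frame with `name`, `mature_sequence`.
#' @export
read_mirna_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
}

#' Write seed sites as TSV or UTR-local BED
#' @param sites data.frame from [find_seed_sites()].
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param utr_name Sequence name for BED records.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed"),
                        utr_name = "utr") {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    width <- nchar(sites$matched_target_sequence)
    df <- data.frame(utr_name, sites$utr_start - 1L,
                     sites$utr_start + width - 1L,
                     paste(sites$mirna, sites$site_type, sep = "|"),
                     0L, "+")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
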