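# Derived-allele calling from quality-weighted pileup evidence, and direct
# allele-sequence comparison.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a pileup column
#'
#' One aligned site with per-read base observations and non-negative quality
#' weights. Bases are `A/C/G/T`, `-` for a deletion gap, or `+SEQ` for an
#' insertion anchored immediately after the site (left-aligned convention).
#'
#' @param position 1-based site coordinate.
#' @param ref_base Reference base at the site (one of A/C/G/T).
#' @param bases Character vector of observed alleles.
#' @param weights Numeric vector of quality weights, same length as `bases`,
#'   all `>= 0`. The default mapping from a Phred score Q is
#'   `1 - 10^(-Q/10)`, but any non-negative weighting is accepted.
#' @return A list of class `pileup_column`.
#' @export
pileup_column <- function(position, ref_base, bases, weights) {
  stopifnot(length(position) == 1L, position >= 1L,
            length(bases) == length(weights))
  ref_base <- toupper(ref_base)
  if (!ref_base %in% VALID_BASES)
    stop("invalid reference base '", ref_base, "' at position ", position)
  bases <- toupper(bases)
  ok <- bases %in% VALID_BASES | bases == "-" | grepl("^\\+[ACGT]+$", bases)
  if (!all(ok))
    stop("invalid base symbol(s) at position ", position, ": ",
         paste(unique(bases[!ok]), collapse = ", "))
  if (any(weights < 0)) stop("negative quality weight at position ", position)
  structure(list(position = as.integer(position), ref_base = ref_base,
                 bases = bases, weights = as.numeric(weights)),
            class = "pileup_column")
}

#' Call derived-allele variants from a pileup
#'
#' Emits a call at a column iff the single most-weighted non-reference allele
#' accounts for strictly more than `threshold` of the total quality weight at
#' that column (the fraction is allele weight divided by total column weight).
#' The default 0.79 reads "greater than 79% of quality-weighted reads"
#' literally as a strict inequality, so an allele at exactly 79% is not
#' called. If two non-reference alleles tie for the top weight the site is
#' not called and is recorded in the `ties` attribute. Columns with zero
#' total weight carry no evidence and are skipped with a warning.
#'
#' @param pileup A list of [pileup_column()] objects.
#' @param threshold Weight-fraction threshold (strict), default 0.79.
#' @return A data.frame of class `variant_calls` with columns `position`,
#'   `ref_allele`, `alt_allele`, `alt_weight_fraction`, `kind`
#'   (substitution / insertion / deletion). Attributes: `ties` (positions
#'   skipped for a top-weight tie), `threshold`.
#' @export
call_variants <- function(pileup, threshold = 0.79) {
  stopifnot(is.list(pileup), threshold > 0, threshold < 1)
  rows <- list()
  ties <- integer(0)
  for (col in pileup) {
    if (!inherits(col, "pileup_column"))
      col <- pileup_column(col$position, col$ref_base, col$bases, col$weights)
    total <- sum(col$weights)
    if (total <= 0) {
      warning("no evidence (zero total weight) at position ", col$position,
              "; column skipped", call. = FALSE)
      next
    }
    w <- tapply(col$weights, col$bases, sum)
    w <- w[names(w) != col$ref_base]
    if (length(w) == 0L) next
    top <- max(w)
    top_alleles <- names(w)[w == top]
    if (length(top_alleles) > 1L) {
      if (top / total > threshold) ties <- c(ties, col$position)
      next
    }
    frac <- top / total
    if (frac > threshold) {
      alt <- top_alleles
      kind <- if (alt == "-") "deletion"
              else if (startsWith(alt, "+")) "insertion"
              else "substitution"
      rows[[length(rows) + 1L]] <- data.frame(
        position = col$position, ref_allele = col$ref_base, alt_allele = alt,
        alt_weight_fraction = frac, kind = kind, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), ref_allele = character(0),
               alt_allele = character(0), alt_weight_fraction = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ties") <- ties
  attr(out, "threshold") <- threshold
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Compare two aligned allele sequences position by position
#'
#' Returns every 1-based position at which the two sequences differ. `U` is
#' treated as `T` so RNA and DNA inputs mix freely; `N` never counts as a
#' difference. Sequences must be pre-aligned to equal length.
#'
#' @param seq_a,seq_b Nucleotide strings of equal length
#'   (alphabet A/C/G/T/U/N, case-insensitive).
#' @return data.frame with columns `position`, `base_a`, `base_b`, sorted by
#'   position.
#' @export
diff_sequences <- function(seq_a, seq_b) {
  seq_a <- normalize_nt(seq_a)
  seq_b <- normalize_nt(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences have unequal lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), "); align them before comparing")
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  idx <- which(a != b & a != "N" & b != "N")
  data.frame(position = idx, base_a = a[idx], base_b = b[idx],
             stringsAsFactors = FALSE)
}

# uppercase, U->T, validate alphabet
normalize_nt <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), c(VALID_BASES, "N"))
  if (length(bad))
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  x
}

#' Read a pileup TSV
#'
#' Expected columns: `pos<TAB>ref<TAB>base:weight[,base:weight...]`.
#'
#' @param path Path to the TSV file (with header).
#' @return A list of [pileup_column()] objects.
#' @export
read_pileup_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "ref", "observations") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    obs <- strsplit(tab$observations[i], ",", fixed = TRUE)[[1]]
    parts <- strsplit(obs, ":", fixed = TRUE)
    pileup_column(tab$pos[i], tab$ref[i],
                  bases = vapply(parts, `[`, "", 1L),
                  weights = as.numeric(vapply(parts, `[`, "", 2L)))
  })
}

#' Write a pileup TSV
#' @param pileup List of [pileup_column()] objects.
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileup, path) {
  lines <- vapply(pileup, function(col) {
    paste(col$position, col$ref_base,
          paste(sprintf("%s:%g", col$bases, col$weights), collapse = ","),
          sep = "\t")
  }, "")
  writeLines(c("pos\tref\tobservations", lines), path)
  invisible(path)
}

#' Write variant calls as a minimal VCF (v4.2)
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO records with the supporting
#' quality-weight fraction in `INFO/AWF`. Indels are written VCF-style,
#' anchored at the preceding reference base when `ref_seq` is supplied.
#'
#' @param calls A `variant_calls` data.frame.
#' @param path Output path.
#' @param chrom Chromosome name (default `"chr6"`).
#' @param assembly Assembly tag placed in the header (default `"hg38"`).
#' @param ref_seq Optional reference sequence (1-based over `position`) used
#'   to anchor indels; without it indel records use `N` as the anchor base.
#' @export
write_variants_vcf <- function(calls, path, chrom = "chr6",
                               assembly = "hg38", ref_seq = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##reference=%s", assembly),
           "##INFO=<ID=AWF,Number=1,Type=Float,Description=\"Alt quality-weight fraction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls)) {
    anchor <- function(pos) {
      if (is.null(ref_seq) || pos < 1L || pos > nchar(ref_seq)) "N"
      else substr(ref_seq, pos, pos)
    }
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      pos <- calls$position[i]; ref <- calls$ref_allele[i]
      alt <- calls$alt_allele[i]
      if (calls$kind[i] == "deletion") {
        a <- anchor(pos - 1L)
        pos <- pos - 1L; ref2 <- paste0(a, ref); alt2 <- a
      } else if (calls$kind[i] == "insertion") {
        ref2 <- ref; alt2 <- paste0(ref, sub("^\\+", "", alt))
      } else { ref2 <- ref; alt2 <- alt }
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAWF=%.4f",
              chrom, pos, ref2, alt2, calls$alt_weight_fraction[i])
    }, "")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write variant calls as a flat TSV
#' @param calls A `variant_calls` data.frame.
#' @param path Output path.
#' @export
write_variants_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_alleles_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write allele sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_alleles_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(vapply(seqs, normalize_nt, "")), path)
  invisible(path)
}
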