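# Position weight matrix construction, log-odds scanning, and allele delta
# scoring for transcription-factor binding sites.

#' Build a position weight matrix
#'
#' Converts a W x 4 count matrix into additive log2-odds scores with a
#' background-distributed pseudocount (the FIMO convention):
#' `score(i, b) = log2(((counts[i, b] + p * bg[b]) / (N_i + p)) / bg[b])`
#' where `N_i` is the column total and `p` the pseudocount.
#'
#' @param counts W x 4 non-negative matrix; columns A, C, G, T (column
#'   names, if present, must be in that order).
#' @param background Base frequencies (A, C, G, T), strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Non-negative pseudocount `p`, default 0.1.
#' @param name Motif name.
#' @return A list of class `pwm`: `name`, `width`, `counts`, `background`,
#'   `pseudocount`, `log_odds` (W x 4), `max_score`, `consensus`.
#' @export
build_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                      name = "motif") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A, C, G, T)")
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), VALID_BASES))
    stop("count columns must be ordered A, C, G, T")
  if (any(counts < 0)) stop("negative counts")
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6)
    stop("background must be strictly positive and sum to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  n_i <- rowSums(counts)
  if (pseudocount == 0 && any(n_i == 0))
    stop("zero column total with pseudocount 0; supply a pseudocount")
  probs <- (counts + pseudocount * matrix(background, nrow(counts), 4,
                                          byrow = TRUE)) / (n_i + pseudocount)
  lo <- log2(sweep(probs, 2, background, "/"))
  colnames(lo) <- VALID_BASES
  colnames(counts) <- VALID_BASES
  structure(list(name = name, width = nrow(counts), counts = counts,
                 background = stats::setNames(background, VALID_BASES),
                 pseudocount = pseudocount, log_odds = lo,
                 max_score = sum(apply(lo, 1, max)),
                 consensus = paste(VALID_BASES[apply(lo, 1, which.max)],
                                   collapse = "")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s, max score %.3f bits\n",
              x$name, x$width, x$consensus, x$max_score))
  invisible(x)
}

# log-odds score of every window start on the + strand of an index vector;
# windows containing N (idx NA) score NA
window_scores <- function(idx, lo) {
  W <- nrow(lo)
  n <- length(idx) - W + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(W)) s <- s + lo[i, ][idx[i:(i + n - 1L)]]
  s
}

seq_to_idx <- function(sequence) {
  match(strsplit(normalize_nt(sequence), "")[[1]], VALID_BASES)
}

#' Scan a sequence for motif occurrences
#'
#' Scores every window of the sequence (and of its reverse complement when
#' `both_strands`) against the PWM and reports windows with score at or
#' above the threshold. Windows containing `N` are skipped. Hits are
#' sorted by start position, `+` strand before `-` at the same start.
#'
#' @param sequence Nucleotide string (T and U equivalent).
#' @param pwm A [build_pwm()] object.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param threshold Minimum score in bits (default `-Inf`, all windows).
#' @return data.frame with `start` (1-based, on the input strand), `strand`,
#'   `matched_sequence` (input-strand window), `score`.
#' @export
scan_pwm <- function(sequence, pwm, both_strands = TRUE, threshold = -Inf) {
  stopifnot(inherits(pwm, "pwm"))
  sequence <- normalize_nt(sequence)
  W <- pwm$width
  if (nchar(sequence) < W) {
    warning("sequence shorter than motif width; no windows to scan")
    return(data.frame(start = integer(0), strand = character(0),
                      matched_sequence = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  idx <- seq_to_idx(sequence)
  L <- length(idx)
  fwd <- window_scores(idx, pwm$log_odds)
  starts <- which(!is.na(fwd) & fwd >= threshold)
  out <- data.frame(start = starts, strand = rep("+", length(starts)),
                    score = fwd[starts], stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sequence)))
    rev_scores <- window_scores(seq_to_idx(rc), pwm$log_odds)
    # window starting at j on the rc strand covers input positions
    # (L - j - W + 2) .. (L - j + 1)
    js <- which(!is.na(rev_scores) & rev_scores >= threshold)
    out <- rbind(out, data.frame(start = L - js - W + 2L,
                                 strand = rep("-", length(js)),
                                 score = rev_scores[js],
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$matched_sequence <- if (nrow(out))
    substring(sequence, out$start, out$start + W - 1L) else character(0)
  rownames(out) <- NULL
  out[, c("start", "strand", "matched_sequence", "score")]
}

best_score <- function(sequence, pwm, both_strands = TRUE) {
  hits <- scan_pwm(sequence, pwm, both_strands, threshold = -Inf)
  if (nrow(hits) == 0L) return(NA_real_)
  max(hits$score)
}

#' Delta matrix score between two alleles of the same window
#'
#' Computes the best motif score (both strands) within each allele's context
#' and their difference `alt - ref`. A change smaller than `tol` in absolute
#' value is reported as `unchanged`.
#'
#' @param ref_context,alt_context The same genomic window under the
#'   reference and alternate alleles; equal lengths `>=` motif width.
#' @param pwm A [build_pwm()] object.
#' @param both_strands Scan both strands (default TRUE).
#' @param tol Tolerance for calling the score unchanged (default 1e-9 bits).
#' @return A list of class `delta_score`: `ref_best_score`,
#'   `alt_best_score`, `delta`, `direction` (increased/decreased/unchanged).
#' @export
delta_score <- function(ref_context, alt_context, pwm, both_strands = TRUE,
                        tol = 1e-9) {
  ref_context <- normalize_nt(ref_context)
  alt_context <- normalize_nt(alt_context)
  if (nchar(ref_context) != nchar(alt_context))
    stop("allele contexts must have equal length")
  if (nchar(ref_context) < pwm$width)
    stop("context shorter than motif width")
  rs <- best_score(ref_context, pwm, both_strands)
  as_ <- best_score(alt_context, pwm, both_strands)
  d <- as_ - rs
  dir <- if (is.na(d) || abs(d) < tol) "unchanged"
         else if (d > 0) "increased" else "decreased"
  structure(list(ref_best_score = rs, alt_best_score = as_, delta = d,
                 direction = dir), class = "delta_score")
}

#' Delta score of a single substitution within a sequence
#'
#' Convenience wrapper: builds the `+/-(W - 1)` context around a variant,
#' substitutes the alternate allele, and calls [delta_score()].
#'
#' @param sequence Reference sequence containing the variant site.
#' @param position 1-based variant position; must carry `ref_allele`.
#' @param ref_allele,alt_allele Single bases.
#' @param pwm A [build_pwm()] object.
#' @param ... Passed to [delta_score()].
#' @return A `delta_score` object with the variant recorded in `$variant`.
#' @export
variant_delta_score <- function(sequence, position, ref_allele, alt_allele,
                                pwm, ...) {
  sequence <- normalize_nt(sequence)
  if (position < 1L || position > nchar(sequence))
    stop("variant position outside the supplied context")
  if (substr(sequence, position, position) != toupper(ref_allele))
    stop("reference allele mismatch at position ", position)
  W <- pwm$width
  lo <- max(1L, position - (W - 1L))
  hi <- min(nchar(sequence), position + (W - 1L))
  ref_ctx <- substr(sequence, lo, hi)
  alt_seq <- sequence
  substr(alt_seq, position, position) <- toupper(alt_allele)
  ds <- delta_score(ref_ctx, substr(alt_seq, lo, hi), pwm, ...)
  ds$variant <- list(position = position, ref = toupper(ref_allele),
                     alt = toupper(alt_allele), context = c(lo, hi))
  ds
}

#' Find occurrences of a degenerate (IUPAC) motif string
#'
#' Literal matching of motifs such as `CCYCCCWCCTC` (`Y = C/T`, `W = A/T`)
#' via IUPAC-aware pattern matching; distinct from PWM scoring.
#'
#' @param sequence Nucleotide string.
#' @param motif IUPAC motif string.
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return data.frame with `start`, `strand`, `matched_sequence`.
#' @export
match_degenerate <- function(sequence, motif, both_strands = TRUE) {
  subject <- Biostrings::DNAString(normalize_nt(sequence))
  hit_df <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = FALSE)
    data.frame(start = Biostrings::start(m),
               strand = rep(strand, length(m)),
               matched_sequence = as.character(m), stringsAsFactors = FALSE)
  }
  out <- hit_df(motif, "+")
  if (both_strands) {
    rc_motif <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    out <- rbind(out, hit_df(rc_motif, "-"))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read motifs from minimal MEME text format (version 4)
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections and the
#' optional `background letter frequencies` line. Probabilities are scaled
#' by the stated `nsites` (default 20) to recover pseudo-counts for
#' [build_pwm()].
#'
#' @param path Path to a MEME text file.
#' @param pseudocount Passed to [build_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^background letter frequencies", lines, ignore.case = TRUE)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)][1:4]
  }
  motif_i <- grep("^MOTIF\\b", lines)
  if (!length(motif_i)) stop("no MOTIF blocks found in ", path)
  out <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr_i <- mi + grep("letter-probability matrix",
                       lines[seq(mi + 1L, length(lines))])[1]
    hdr <- lines[hdr_i]
    get_num <- function(key, default) {
      m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([0-9.]+)"), hdr))[[1]]
      if (length(m) == 2L) as.numeric(m[2]) else default
    }
    w <- get_num("w", NA)
    nsites <- get_num("nsites", 20)
    rows <- list()
    j <- hdr_i + 1L
    while (j <= length(lines)) {
      toks <- suppressWarnings(as.numeric(
        strsplit(trimws(lines[j]), "\\s+")[[1]]))
      if (length(toks) != 4L || anyNA(toks)) break
      rows[[length(rows) + 1L]] <- toks
      j <- j + 1L
      if (!is.na(w) && length(rows) == w) break
    }
    probs <- do.call(rbind, rows)
    if (!is.na(w) && nrow(probs) != w)
      stop("motif ", name, ": expected ", w, " rows, found ", nrow(probs))
    out[[name]] <- build_pwm(probs * nsites, background = bg,
                             pseudocount = pseudocount, name = name)
  }
  out
}

#' Write motif hits as TSV or GFF3
#' @param hits data.frame from [scan_pwm()].
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @param seqid Sequence name for GFF3 records.
#' @param motif_name Motif name for GFF3 attributes.
#' @export
write_hits <- function(hits, path, format = c("tsv", "gff3"),
                       seqid = "seq", motif_name = "motif") {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    W <- nchar(hits$matched_sequence)
    recs <- sprintf(
      "%s\trunx2reg\tTF_binding_site\t%d\t%d\t%.4f\t%s\t.\tName=%s",
      seqid, hits$start, hits$start + W - 1L, hits$score, hits$strand,
      motif_name)
    writeLines(c("##gff-version 3", recs), path)
  }
  invisible(path)
}
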