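# Brute-force oracles kept deliberately independent of the implementation
# paths they check.

BASES <- c("A", "C", "G", "T")

rc_str <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# score every window of seq (and its reverse complement) one position at a
# time with explicit loops
oracle_scan <- function(seq, lo, threshold = -Inf, both_strands = TRUE) {
  W <- nrow(lo)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  rows <- list()
  add_hits <- function(chars_s, strand) {
    for (s in seq_len(length(chars_s) - W + 1L)) {
      sc <- 0
      for (i in seq_len(W)) sc <- sc + lo[i, chars_s[s + i - 1L]]
      if (!is.na(sc) && sc >= threshold) {
        start <- if (strand == "+") s else L - s - W + 2L
        rows[[length(rows) + 1L]] <<- data.frame(
          start = start, strand = strand, score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  add_hits(chars, "+")
  if (both_strands)
    add_hits(strsplit(rc_str(seq), "")[[1]], "-")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), strand = character(0),
               score = numeric(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# direct substring search for each canonical seed-site pattern
oracle_seed_sites <- function(utr, mature) {
  mature <- chartr("U", "T", mature)
  rc6 <- rc_str(substr(mature, 2, 7))
  rc7 <- rc_str(substr(mature, 2, 8))
  find_all <- function(pat) {
    out <- integer(0)
    s <- 1L
    repeat {
      i <- regexpr(pat, substr(utr, s, nchar(utr)), fixed = TRUE)
      if (i == -1L) break
      out <- c(out, s + i - 1L)
      s <- s + i
    }
    out
  }
  cores <- find_all(rc6)
  types <- vapply(cores, function(cs) {
    m8 <- cs > 1 && substr(utr, cs - 1, cs + 5) == rc7
    a1 <- cs + 6 <= nchar(utr) && substr(utr, cs + 6, cs + 6) == "A"
    if (m8 && a1) "8mer" else if (m8) "7mer-m8"
    else if (a1) "7mer-A1" else "6mer"
  }, "")
  data.frame(core_start = cores, site_type = types,
             stringsAsFactors = FALSE)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# random count-matrix PWM
random_pwm <- function(W, pseudocount = 0.1) {
  counts <- matrix(rpois(W * 4, lambda = 5), W, 4)
  build_pwm(counts, pseudocount = pseudocount,
            name = paste0("rand", W))
}
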