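test_that("log-odds construction matches the direct formula", {
  pwm <- build_pwm(matrix(c(4, 0, 0, 0), 1, 4), pseudocount = 0.1)
  expect_equal(unname(pwm$log_odds[1, "A"]),
               log2(((4 + 0.1 * 0.25) / 4.1) / 0.25), tolerance = 1e-12)
  expect_equal(unname(pwm$log_odds[1, "A"]), 1.9735, tolerance = 1e-4)

  # counts proportional to background in every column score 0 everywhere
  bg <- c(0.4, 0.1, 0.2, 0.3)
  counts <- matrix(rep(bg * 10, 3), 3, 4, byrow = TRUE)
  flat <- build_pwm(counts, background = bg, pseudocount = 0.1)
  expect_true(all(abs(flat$log_odds) < 1e-12))
})

test_that("consensus achieves the maximal scan score", {
  set.seed(1)
  for (i in 1:10) {
    pwm <- random_pwm(sample(4:10, 1))
    hits <- scan_pwm(pwm$consensus, pwm, both_strands = FALSE)
    expect_equal(max(hits$score), pwm$max_score, tolerance = 1e-12)
  }
})

test_that("pseudocount -> 0 limit: doubling all counts leaves log-odds unchanged", {
  set.seed(2)
  counts <- matrix(rpois(24, 10) + 1, 6, 4)
  p1 <- build_pwm(counts, pseudocount = 1e-9)
  p2 <- build_pwm(counts * 2, pseudocount = 1e-9)
  expect_equal(p1$log_odds, p2$log_odds, tolerance = 1e-8)
  expect_error(build_pwm(matrix(0, 2, 4), pseudocount = 0), "pseudocount")
})

test_that("scan agrees exactly with the brute-force all-windows oracle", {
  set.seed(3)
  for (i in 1:60) {
    pwm <- random_pwm(sample(4:12, 1))
    seq <- random_seq(sample(pwm$width:200, 1))
    thr <- runif(1, -5, pwm$max_score)
    got <- scan_pwm(seq, pwm, both_strands = TRUE, threshold = thr)
    want <- oracle_scan(seq, pwm$log_odds, threshold = thr)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("windows containing N are skipped; short sequences warn", {
  pwm <- random_pwm(5)
  hits <- scan_pwm("ACGNTACGTACG", pwm, both_strands = FALSE)
  expect_true(all(hits$start > 4)) # windows covering the N are absent
  expect_warning(res <- scan_pwm("ACG", pwm), "shorter")
  expect_equal(nrow(res), 0L)
})

test_that("planted consensus is found at the planted position", {
  set.seed(4)
  for (i in 1:10) {
    pwm <- random_pwm(8)
    planted <- plant_motif(pwm, length = 150, seed = i)
    hits <- scan_pwm(planted$sequence, pwm,
                     threshold = 0.9 * pwm$max_score)
    expect_true(all(planted$positions %in% hits$start))
  }
})

test_that("scanning the reverse complement swaps strands, same scores", {
  set.seed(5)
  pwm <- random_pwm(7)
  seq <- random_seq(90)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  a <- scan_pwm(seq, pwm, both_strands = TRUE)
  b <- scan_pwm(rc, pwm, both_strands = TRUE)
  expect_equal(sort(a$score), sort(b$score), tolerance = 1e-12)
  expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
})

test_that("delta_score reports direction and is antisymmetric", {
  set.seed(6)
  pwm <- random_pwm(8)
  planted <- plant_motif(pwm, length = 40, positions = 10, seed = 7)
  ref <- planted$sequence
  alt <- ref
  # destroy the strongest consensus base
  best_col <- which.max(apply(pwm$log_odds, 1, max))
  pos <- 10 + best_col - 1
  worst <- colnames(pwm$log_odds)[which.min(pwm$log_odds[best_col, ])]
  substr(alt, pos, pos) <- worst
  ds <- delta_score(ref, alt, pwm)
  expect_lt(ds$delta, 0)
  expect_equal(ds$direction, "decreased")
  flipped <- delta_score(alt, ref, pwm)
  expect_equal(flipped$delta, -ds$delta, tolerance = 1e-12)
  expect_equal(flipped$direction, "increased")
  same <- delta_score(ref, ref, pwm)
  expect_equal(same$delta, 0)
  expect_equal(same$direction, "unchanged")
})

test_that("variant_delta_score validates the variant and matches delta_score", {
  set.seed(8)
  pwm <- random_pwm(6)
  seq <- random_seq(60)
  pos <- 30
  ref <- substr(seq, pos, pos)
  alt <- setdiff(BASES, ref)[1]
  ds <- variant_delta_score(seq, pos, ref, alt, pwm)
  ctx <- substr(seq, pos - 5, pos + 5)
  alt_ctx <- ctx
  substr(alt_ctx, 6, 6) <- alt
  expect_equal(ds$delta, delta_score(ctx, alt_ctx, pwm)$delta,
               tolerance = 1e-12)
  expect_error(variant_delta_score(seq, pos, alt, ref, pwm), "mismatch")
  expect_error(variant_delta_score(seq, 100, ref, alt, pwm), "outside")
})

test_that("degenerate motif matching expands IUPAC codes", {
  # CCYCCCWCCTC: Y = C/T, W = A/T
  seq <- paste0("GG", "CCTCCCACCTC", "AA", "CCCCCCTCCTC", "TT")
  hits <- match_degenerate(seq, "CCYCCCWCCTC", both_strands = FALSE)
  expect_equal(hits$start, c(3L, 16L))
  expect_equal(hits$matched_sequence, c("CCTCCCACCTC", "CCCCCCTCCTC"))
  none <- match_degenerate("GGGGGGGGGGGGGG", "CCYCCCWCCTC")
  expect_equal(nrow(none), 0L)
})

test_that("MEME text motifs round-trip into equivalent PWMs", {
  meme <- c("MEME version 4", "",
            "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.25 C 0.25 G 0.25 T 0.25", "",
            "MOTIF ZNF_like", "",
            "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
            " 0.8 0.1 0.05 0.05",
            " 0.05 0.8 0.1 0.05",
            " 0.1 0.05 0.05 0.8")
  tmp <- tempfile(fileext = ".meme")
  writeLines(meme, tmp)
  pwms <- read_meme(tmp)
  expect_named(pwms, "ZNF_like")
  pwm <- pwms[[1]]
  expect_equal(pwm$width, 3L)
  expect_equal(pwm$consensus, "ACT")
  expect_equal(unname(pwm$counts[1, "A"]), 16)
})

test_that("hit tables serialize to TSV and GFF3", {
  pwm <- random_pwm(5)
  hits <- scan_pwm(random_seq(50), pwm, threshold = -Inf)
  tsv <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  write_hits(hits, tsv, "tsv")
  write_hits(hits, gff, "gff3", seqid = "P2", motif_name = pwm$name)
  expect_equal(nrow(read.delim(tsv)), nrow(hits))
  g <- readLines(gff)
  expect_equal(g[1], "##gff-version 3")
  expect_equal(length(g) - 1L, nrow(hits))
})
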