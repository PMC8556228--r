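cel39 <- mirna("cel-miR-39-3p", "UCACCGGGUGUAAAUCAGCUUG")

test_that("the spike-in control miRNA finds its canonical sites", {
  expect_equal(cel39$seed, "CACCGGG")
  # seed nt 2-8 = CACCGGG, reverse complement CCCGGTG
  s8 <- find_seed_sites("AACCCGGTGATT", cel39)
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$site_type, "8mer")
  expect_equal(s8$utr_start, 3L)
  expect_equal(s8$matched_target_sequence, "CCCGGTGA")

  # losing the downstream A degrades the site to 7mer-m8
  s7 <- find_seed_sites("AACCCGGTGCTT", cel39)
  expect_equal(s7$site_type, "7mer-m8")
  expect_equal(s7$utr_start, 3L)

  expect_equal(nrow(find_seed_sites("GGGGGGGGGGGG", cel39)), 0L)
})

test_that("RNA and DNA UTR input are equivalent (T == U)", {
  rna <- find_seed_sites("AACCCGGUGAUU", cel39)
  dna <- find_seed_sites("AACCCGGTGATT", cel39)
  expect_equal(rna$site_type, dna$site_type)
  expect_equal(rna$utr_start, dna$utr_start)
})

test_that("miRNAs shorter than 8 nt are rejected", {
  expect_error(mirna("tiny", "ACGUACG"), "at least 8")
})

test_that("seed matcher equals the substring-search oracle on random cases", {
  set.seed(21)
  for (i in 1:80) {
    mat <- random_seq(sample(18:24, 1))
    utr <- random_seq(sample(30:500, 1))
    mir <- mirna("rand", mat)
    got <- find_seed_sites(utr, mir)
    want <- oracle_seed_sites(utr, mat)
    expect_equal(got$core_start, want$core_start)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("site-type hierarchy: 8mer loci are 7mer-m8 loci are 6mer loci", {
  set.seed(22)
  checked <- 0L
  for (i in 1:200) {
    mat <- random_seq(20)
    utr <- random_seq(800)
    mir <- mirna("rand", mat)
    all_types <- find_seed_sites(utr, mir)
    if (nrow(all_types) == 0L) next
    loci6 <- find_seed_sites(utr, mir, site_types = "6mer")$core_start
    loci7m8 <- find_seed_sites(utr, mir,
                               site_types = c("7mer-m8"))$core_start
    loci8 <- all_types$core_start[all_types$site_type == "8mer"]
    expect_true(all(loci8 %in% loci7m8))
    expect_true(all(loci7m8 %in% loci6))
    checked <- checked + 1L
  }
  expect_gt(checked, 15L)
})

test_that("a 1-bp change completing a planted site is one gained site, none lost", {
  for (s in 1:10) {
    planted <- plant_seed_site(cel39, utr_length = 80, site_position = 30,
                               site_type = "8mer", seed = s)
    panel <- data.frame(name = cel39$name,
                        mature_sequence = cel39$mature)
    d <- diff_sites(planted$utr_ref, planted$utr_alt, panel)
    expect_equal(nrow(d$gained), 1L)
    expect_equal(nrow(d$lost), 0L)
    expect_equal(d$gained$core_start, planted$core_start)
    expect_equal(d$gained$site_type, "8mer")
  }
})

test_that("identical alleles diff to nothing; empty panel warns", {
  utr <- random_seq(100)
  panel <- data.frame(name = cel39$name, mature_sequence = cel39$mature)
  d <- diff_sites(utr, utr, panel)
  expect_equal(nrow(d$gained) + nrow(d$lost) +
                 nrow(d$retained_type_changed), 0L)
  expect_warning(d0 <- diff_sites(utr, utr,
                                  data.frame(name = character(0),
                                             mature_sequence = character(0))),
                 "empty")
  expect_equal(nrow(d0$gained), 0L)
})

test_that("sites far from any changed position never appear in the diff", {
  set.seed(23)
  planted <- plant_seed_site(cel39, utr_length = 120, site_position = 20,
                             seed = 3)
  # introduce an unrelated change far downstream of the planted site
  ref2 <- planted$utr_alt
  alt2 <- ref2
  substr(alt2, 100, 100) <- setdiff(BASES, substr(ref2, 100, 100))[1]
  panel <- data.frame(name = cel39$name, mature_sequence = cel39$mature)
  d <- diff_sites(ref2, alt2, panel)
  # the intact planted site at 20 is in both alleles: not gained, not lost
  expect_false(planted$core_start %in% c(d$gained$core_start,
                                         d$lost$core_start))
})

test_that("gained/lost sites always overlap a changed position", {
  set.seed(24)
  checked <- 0L
  for (i in 1:40) {
    mir <- mirna("rand", random_seq(20))
    panel <- data.frame(name = mir$name, mature_sequence = mir$mature)
    # half the cases carry a planted gain so changed loci are guaranteed
    if (i %% 2 == 0) {
      planted <- plant_seed_site(mir, utr_length = 200,
                                 site_position = sample(30:150, 1),
                                 seed = i)
      ref <- planted$utr_ref; alt <- planted$utr_alt
    } else {
      pair <- make_allele_pair(length = 200, n_subs = sample(1:6, 1),
                               seed = i)
      ref <- pair$ref; alt <- pair$alt
    }
    d <- diff_sites(ref, alt, panel)
    for (cs in c(d$gained$core_start, d$lost$core_start)) {
      expect_true(any(d$changed_positions >= cs &
                        d$changed_positions <= cs + 5L))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 15L)
})

test_that("variant_in_seed_region flags positions inside the matched span", {
  sites <- find_seed_sites("AACCCGGTGATT", cel39) # 8mer, span 3..9 + A at 10
  expect_true(variant_in_seed_region(6, sites))   # inside
  expect_true(variant_in_seed_region(3, sites))   # m8 base
  expect_false(variant_in_seed_region(10, sites)) # the A1 adenine
  expect_false(variant_in_seed_region(12, sites)) # downstream
  expect_length(variant_in_seed_region(5, sites[0, ]), 0L)
})

test_that("the shipped miRNA panel has placeholders and the control sequence", {
  panel <- read_mirna_tsv(system.file("extdata", "mirna_panel.tsv",
                                      package = "runx2reg"))
  expect_equal(nrow(panel), 16L)
  expect_equal(sum(nzchar(panel$mature_sequence)), 1L)
  expect_equal(panel$mature_sequence[panel$name == "cel-miR-39-3p"],
               "UCACCGGGUGUAAAUCAGCUUG")
  # placeholder rows are skipped, not errors, when the panel is scanned
  expect_silent(d <- diff_sites("AACCCGGTGATT", "AACCCGGTGATT", panel))
})
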