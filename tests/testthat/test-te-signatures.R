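# TSD, TIR, tandem period, interspersed-copy scan, TE classification.

test_that("planted target-site duplications are detected at their length", {
  te <- make_te_intron(tsd_len = 4, seed = 11)
  cand <- detect_tsd(te$flank5, te$intron, te$flank3)
  expect_gt(nrow(cand), 0L)
  expect_equal(cand$length[1], 4L)
  expect_equal(cand$seq[1], te$truth$tsd)

  ## a longer duplication also surfaces its internal sub-repeats
  te6 <- make_te_intron(tsd_len = 6, seed = 12)
  c6 <- detect_tsd(te6$flank5, te6$intron, te6$flank3)
  expect_equal(c6$length[1], 6L)
  expect_true(all(c(5L, 4L, 3L) %in% c6$length))
})

test_that("a minimal intron with unrelated flanks yields no candidates", {
  ## flanks chosen so the whole construct contains no repeated 3-mer
  cand <- detect_tsd("ctggtgacca", "gtag", "ggcgcatcta")
  expect_equal(nrow(cand), 0L)
})

test_that("TSD detection is strand-symmetric", {
  set.seed(5)
  for (s in 1:5) {
    te <- make_te_intron(tsd_len = 4, seed = s)
    fwd <- detect_tsd(te$flank5, te$intron, te$flank3)
    rev <- detect_tsd(rc(te$flank3), rc(te$intron), rc(te$flank5))
    expect_equal(sort(fwd$length), sort(rev$length), info = paste("seed", s))
    expect_equal(fwd$length[1], rev$length[1])
  }
})

test_that("terminal inverted repeats: exact arms, palindromes, random nulls", {
  set.seed(8)
  arm <- paste0("tgt", random_seq(9))
  inner <- random_seq(60)
  element <- paste0(arm, inner, rc(arm))
  tir <- detect_tir(element)
  expect_gte(tir$arm_length, 12L)
  expect_equal(tir$identity, 1.0)
  expect_equal(tir$left_start3, "tgt")
  expect_equal(tir$right_end3, "aca")

  ## an element equal to its own reverse complement: arms cover half
  half <- random_seq(20)
  pal <- paste0(half, rc(half))
  expect_equal(detect_tir(pal)$arm_length, 20L)

  ## seeded random 200-mer: no arm at threshold 0.8, min arm 12
  set.seed(99)
  rnd <- random_seq(200)
  expect_null(detect_tir(rnd, min_arm = 12, max_mismatch = 0.2))
  ## brute confirmation on the same draw
  ch <- strsplit(rnd, "")[[1]]; rcch <- strsplit(rc(rnd), "")[[1]]
  ids <- vapply(12:100, function(a) mean(ch[1:a] == rcch[1:a]), 0)
  expect_true(all(ids < 0.8))
})

test_that("tandem period detection: exact arrays, planted 37-nt unit, homopolymers", {
  tp <- tandem_period(strrep("acgtt", 10))
  expect_equal(tp$unit_length, 5L)
  expect_equal(tp$copies, 10)
  expect_equal(tp$match_fraction, 1.0)

  ## seeded 37-nt unit x 4 with 2 point mutations, inside a TE intron
  te <- make_te_intron(unit_len = 37, copies = 4, n_mutations = 2, seed = 20)
  tp37 <- tandem_period(te$intron)
  expect_equal(tp37$unit_length, 37L)
  expect_gte(tp37$copies, 3.9)

  ## homopolymer: smallest admissible unit, flagged low complexity
  hp <- tandem_period(strrep("a", 120))
  expect_equal(hp$unit_length, 5L)
  expect_true(hp$low_complexity)

  ## non-repetitive sequence: nothing qualifies
  set.seed(42)
  expect_null(tandem_period(random_seq(150)))
})

test_that("tandem period agrees with the brute-force oracle on short seeded sequences", {
  set.seed(17)
  cases <- list()
  for (i in 1:6) {
    u <- sample(5:20, 1)
    unit <- random_seq(u)
    arr <- strrep(unit, sample(3:5, 1))
    ## a couple of point mutations
    ch <- strsplit(arr, "")[[1]]
    for (j in sample(length(ch), 2)) ch[j] <- sample(c("a","c","g","t"), 1)
    cases[[i]] <- paste0(random_seq(15), paste(ch, collapse = ""),
                         random_seq(15))
  }
  cases[[7]] <- strrep("acgacgt", 8)
  for (s in cases) {
    got <- tandem_period(s, min_unit = 5, max_unit = 30)
    want <- tandem_oracle_unit(s, min_unit = 5, max_unit = 30)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$unit_length, want)
    }
  }
})

test_that("interspersed scan finds planted copies with correct coverage and identity", {
  set.seed(33)
  q <- random_seq(200)
  ctg <- make_decoy_contigs(q, n_copies = 3, n_empty = 2, seed = 34)
  hits <- scan_interspersed(q, ctg)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$query_coverage == 1.0))
  expect_true(all(hits$identity == 1.0))

  ## 10% point mutations: still found, identity >= 0.8
  ctg_mut <- make_decoy_contigs(q, n_copies = 2, n_empty = 2,
                                mutation_rate = 0.1, seed = 35)
  hits_mut <- scan_interspersed(q, ctg_mut)
  expect_equal(nrow(hits_mut), 2L)
  expect_true(all(hits_mut$identity >= 0.8))

  ## absent query
  expect_equal(nrow(scan_interspersed(q, make_decoy_contigs(random_seq(200),
                                                            n_copies = 0,
                                                            n_empty = 3,
                                                            seed = 36))), 0L)
})

test_that("scan completeness: every planted exact copy is recovered", {
  set.seed(44)
  for (rep in 1:3) {
    q <- random_seq(sample(80:300, 1))
    n <- sample(2:6, 1)
    ctg <- make_decoy_contigs(q, n_copies = n, n_empty = 2, seed = rep)
    expect_equal(nrow(scan_interspersed(q, ctg)), n)
  }
})

test_that("TE classification integrates all evidence and honors the locus threshold", {
  te <- make_te_intron(seed = 50)
  ctg5 <- make_decoy_contigs(te$intron, n_copies = 5, n_empty = 2, seed = 51)
  cls <- classify_te(te$flank5, te$intron, te$flank3, ctg5)
  expect_true(cls$is_putative_te)
  expect_equal(cls$n_loci, 5L)
  expect_equal(cls$evidence$tsd$length[1], 4L)
  expect_gte(cls$evidence$tir$arm_length, 12L)
  expect_equal(cls$evidence$tandem$unit_length, 37L)

  ## threshold boundary: 2 loci is not "multiple" at min 3, but is at min 2
  ctg2 <- make_decoy_contigs(te$intron, n_copies = 2, n_empty = 3, seed = 52)
  expect_false(classify_te(te$flank5, te$intron, te$flank3, ctg2)$is_putative_te)
  expect_true(classify_te(te$flank5, te$intron, te$flank3, ctg2,
                          min_loci = 2)$is_putative_te)

  ## a unique random intron is not a TE
  set.seed(53)
  rnd_intron <- paste0("gt", random_seq(150), "ag")
  cls_rnd <- classify_te(random_seq(50), rnd_intron, random_seq(50),
                         make_decoy_contigs(random_seq(100), n_copies = 0,
                                            n_empty = 4, seed = 54))
  expect_false(cls_rnd$is_putative_te)
})

test_that("TE intron generator honors its switches", {
  ## disabled TSD: no boundary-spanning pair involving a planted repeat
  te0 <- make_te_intron(tsd_len = 0, seed = 60)
  expect_equal(te0$truth$tsd, "")
  expect_true(substr(te0$intron, 1, 2) == "gt")
  ## single copy: no array, so no 37-nt period; whatever chance repeat the
  ## random construct may contain must agree with the exhaustive oracle
  te1 <- make_te_intron(copies = 1, n_mutations = 0, seed = 61)
  got <- tandem_period(te1$intron)
  want <- tandem_oracle_unit(te1$intron)
  if (is.null(want)) {
    expect_null(got)
  } else {
    expect_equal(got$unit_length, want)
  }
  expect_false(!is.null(got) && got$unit_length == 37L)
})
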