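test_that("sdp counts the bin-set intersection", {
  b <- function(x) binned_spectrum(x, 0.5)
  expect_equal(sdp(b(1:5), b(1:5)), 5L)                 # self-match
  expect_equal(sdp(b(1:5), b(6:10)), 0L)                # disjoint
  expect_equal(sdp(b(c(100, 200, 300, 400)), b(c(200, 400, 500))), 2L)
  expect_error(sdp(b(1:3), binned_spectrum(1:3, 0.2)), "bin width")
})

test_that("sdp equals the dense brute-force oracle and is symmetric (property)", {
  set.seed(42)
  for (i in 1:200) {
    bc <- sample.int(500, sample(1:60, 1)) - 1L
    bt <- sample.int(500, sample(1:60, 1)) - 1L
    c_ <- binned_spectrum(bc, 0.5); t_ <- binned_spectrum(bt, 0.5)
    expect_identical(sdp(c_, t_), dense_sdp_oracle(bc, bt))
    expect_identical(sdp(c_, t_), sdp(t_, c_))
    expect_identical(sdp(c_, c_), length(c_$bins))
    expect_lte(sdp(c_, t_), min(length(c_$bins), length(t_$bins)))
  }
})

test_that("candidate window equals the linear-scan oracle", {
  masses <- c(500, 600, 700, 800)
  w <- candidate_window(masses, 650, 60)
  expect_equal(seq.int(w$lo, w$hi - 1L), window_oracle(masses, 650, 60))
  expect_equal(w$lo, 2L); expect_equal(w$hi, 4L)  # {600, 700}
  w0 <- candidate_window(masses, 650, 0)
  expect_equal(w0$lo, w0$hi)                      # empty: no exact match
  expect_equal({w <- candidate_window(masses, 10, 5); w$hi - w$lo}, 0L)
  expect_equal({w <- candidate_window(masses, 1e5, 5); w$hi - w$lo}, 0L)

  set.seed(9)
  for (i in 1:300) {
    m <- sort(stats::runif(sample(1:80, 1), 100, 4000))
    q <- stats::runif(1, 0, 4500)
    tol <- stats::runif(1, 0, 100)
    w <- candidate_window(m, q, tol)
    got <- if (w$hi > w$lo) seq.int(w$lo, w$hi - 1L) else integer()
    expect_equal(got, window_oracle(m, q, tol))
    # widening the tolerance never shrinks the window
    w2 <- candidate_window(m, q, tol * 2)
    expect_lte(w2$lo, w$lo); expect_gte(w2$hi, w$hi)
  }
})

test_that("a perfect-match spectrum ranks its peptide first with score 2(L-1)", {
  idx <- tiny_index(c("PEPTIDEK", "AAAGGK", "WYWYWK"))
  cfg <- search_config(min_len = 2, mods = list())
  sp <- perfect_spectrum("PEPTIDEK")
  psms <- score_spectrum_alg1(sp, idx, cfg)
  expect_equal(psms$peptide_sequence[1], "PEPTIDEK")
  expect_equal(psms$rank[1], 1L)
  expect_equal(psms$sdp_score[1], 2L * (nchar("PEPTIDEK") - 1L))
})

test_that("a precursor outside every window yields an empty PSM list", {
  idx <- tiny_index(c("PEPTIDEK", "AAAGGK"))
  cfg <- search_config(mods = list())
  sp <- perfect_spectrum("PEPTIDEK")
  sp$precursor_mz <- 5000  # far beyond any candidate
  expect_equal(nrow(score_spectrum_alg1(sp, idx, cfg)), 0L)
  expect_equal(nrow(score_spectrum_micsdp(sp, idx, cfg)), 0L)
})

test_that("candidate scores match brute-force scoring of every pair", {
  # wide precursor window: all three candidates are in H; expected scores
  # come from the dense dot-product oracle applied to each (c, t) pair
  cfg <- search_config(mods = list(), precursor_tolerance_da = 1000,
                       fragment_tolerance_da = 0.5, min_len = 2)
  idx <- tiny_index(c("AAAGGK", "GGAAGK", "WWWWWK"))
  frA <- fragment_mzs("AAAGGK"); frB <- fragment_mzs("GGAAGK")
  onlyB <- frB[!floor(frB / 0.5) %in% floor(frA / 0.5)]
  mz <- sort(c(frA[1:4], onlyB[1:2]))
  sp <- list(spectrum_id = "h1", precursor_mz = peptide_mass("AAAGGK") / 2 +
               PROTON_MASS, precursor_charge = 2L,
             peaks = data.frame(mz = mz, intensity = rep(1, length(mz))),
             source_index = 1L)
  cbins <- floor(mz / 0.5)
  expected <- vapply(idx$peptides$sequence, function(s)
    dense_sdp_oracle(cbins, floor(fragment_mzs(s) / 0.5)), 0L)
  psms <- score_spectrum_alg1(sp, idx, cfg)
  # the spectrum was built from AAAGGK fragments, so it must rank first
  expect_equal(psms$peptide_sequence[1], "AAAGGK")
  expect_equal(psms$rank, seq_len(nrow(psms)))
  expect_true(all(diff(psms$sdp_score) <= 0))
  # every reported score equals the brute-force pair score; zero-score
  # candidates are absent
  for (i in seq_len(nrow(psms)))
    expect_equal(psms$sdp_score[i],
                 unname(expected[psms$peptide_sequence[i]]))
  expect_setequal(psms$peptide_sequence,
                  names(expected)[expected > 0L])
})

test_that("ranking drops zeros, caps at k, and breaks ties by mass then sequence", {
  scored <- data.frame(sequence = c("AAA", "CCC", "GGG", "TTT"),
                       neutral_mass = c(500.0, 500.2, 500.1, 600),
                       protein_accession = c("p1", "p2", "p3", "p4"),
                       score = c(4L, 2L, 2L, 0L),
                       stringsAsFactors = FALSE)
  r <- rank_psms(scored, query_mass = 500.1, k = 10)
  expect_equal(r$rank, 1:3)                       # zero dropped
  expect_equal(r$peptide_sequence[1], "AAA")      # top score
  expect_equal(r$peptide_sequence[2], "GGG")      # closer mass wins the tie
  r2 <- rank_psms(scored, 500.1, k = 2)
  expect_equal(nrow(r2), 2L)
  expect_equal(nrow(rank_psms(transform(scored, score = 0L), 500.1, 10)), 0L)
  # equal score and equal mass delta: lexicographic sequence
  scored2 <- data.frame(sequence = c("ZZZ", "BAA"), neutral_mass = c(500, 500),
                        protein_accession = c("p", "q"), score = c(3L, 3L),
                        stringsAsFactors = FALSE)
  expect_equal(rank_psms(scored2, 500, 10)$peptide_sequence, c("BAA", "ZZZ"))
})

test_that("the fused scorer is field-for-field identical to the reference", {
  for (seed in 1:40) {
    case <- random_search_case(seed)
    for (sp in case$spectra) {
      a <- score_spectrum_alg1(sp, case$index, case$config)
      b <- score_spectrum_micsdp(sp, case$index, case$config)
      expect_identical(a, b)
    }
  }
})

test_that("only the reference algorithm materializes candidate lists", {
  idx <- tiny_index(c("PEPTIDEK", "AAAGGK"))
  cfg <- search_config(mods = list())
  sp <- perfect_spectrum("PEPTIDEK")
  reset_counters()
  invisible(score_spectrum_micsdp(sp, idx, cfg))
  expect_null(counters()$candidate_materializations)
  invisible(score_spectrum_alg1(sp, idx, cfg))
  expect_equal(counters()$candidate_materializations, 1L)
  reset_counters()
})

test_that("adding a matching peak never decreases the score (monotonicity)", {
  set.seed(5)
  idx <- tiny_index(c("PEPTIDEK"))
  cfg <- search_config(mods = list())
  base <- perfect_spectrum("PEPTIDEK", drop = 1:6)
  s0 <- score_spectrum_alg1(base, idx, cfg)$sdp_score[1]
  more <- perfect_spectrum("PEPTIDEK", drop = 1:5)
  s1 <- score_spectrum_alg1(more, idx, cfg)$sdp_score[1]
  expect_gte(s1, s0)
})
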