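test_that("cleavage rules reproduce enumerated digests", {
  # trypsin: cut after K at 1; after R at 2 blocked by P; K at 4 is terminus
  d <- digest(list(accession = "P1", sequence = "AKRPK"),
              enzyme_preset("trypsin"), max_missed = 0, min_len = 1,
              max_len = 50)
  expect_equal(d$sequence, c("AK", "RPK"))
  expect_equal(d$start, c(0L, 2L))

  # AspN cuts before D
  d <- digest("AGDK", enzyme_preset("aspn"), 0, 1, 50)
  expect_equal(d$sequence, c("AG", "DK"))

  # LysC with one missed cleavage adds the concatenation
  d <- digest("AKGK", enzyme_preset("lysc"), 1, 1, 50)
  expect_equal(sort(d$sequence), c("AK", "AKGK", "GK"))
  expect_equal(d$missed_cleavages[d$sequence == "AKGK"], 1L)
})

test_that("peptide masses match the residue-table oracle", {
  expect_equal(peptide_mass("G"), 57.02146 + 18.010565, tolerance = 1e-9)
  expect_equal(peptide_mass("C", list(fixed_mod("C", 57.021464))),
               103.00919 + 57.021464 + 18.010565, tolerance = 1e-9)
  # additivity of residue masses
  expect_equal(peptide_mass("AG") - peptide_mass("A") - peptide_mass("G") +
                 WATER_MASS, 0, tolerance = 1e-9)
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("AXZ"), "unknown residue")
})

test_that("peptide_mass is additive over residues (property)", {
  set.seed(11)
  for (i in 1:20) {
    aa <- sample(names(RESIDUE_MASSES), sample(2:20, 1), replace = TRUE)
    pep <- paste(aa, collapse = "")
    expect_equal(peptide_mass(pep),
                 sum(RESIDUE_MASSES[aa]) + WATER_MASS, tolerance = 1e-9)
  }
})

test_that("digestion is sound: fragments tile the protein, missed cleavages
           concatenate adjacent fragments", {
  set.seed(7)
  for (i in 1:15) {
    prot <- paste(sample(names(RESIDUE_MASSES), sample(40:90, 1),
                         replace = TRUE), collapse = "")
    rule <- enzyme_preset(sample(c("trypsin", "lysc", "aspn"), 1))
    mm <- sample(0:2, 1)
    d <- digest(prot, rule, max_missed = mm, min_len = 1, max_len = 200)
    # every peptide is the substring of the protein at its stated offset
    for (j in seq_len(nrow(d)))
      expect_equal(substr(prot, d$start[j] + 1L,
                          d$start[j] + nchar(d$sequence[j])), d$sequence[j])
    expect_true(all(d$missed_cleavages <= mm))
    # fully-cleaved fragments (missed = 0) tile the protein exactly
    frag <- d[d$missed_cleavages == 0L, ]
    frag <- frag[order(frag$start), ]
    expect_equal(paste(frag$sequence, collapse = ""), prot)
    # a peptide with k missed cleavages is the concatenation of exactly
    # k + 1 adjacent fully-cleaved fragments
    for (j in which(d$missed_cleavages > 0L)) {
      parts <- frag[frag$start >= d$start[j] &
                    frag$start < d$start[j] + nchar(d$sequence[j]), ]
      expect_equal(nrow(parts), d$missed_cleavages[j] + 1L)
      expect_equal(paste(parts$sequence, collapse = ""), d$sequence[j])
    }
    # self-consistency of neutral masses
    expect_equal(d$neutral_mass,
                 vapply(d$sequence, peptide_mass, 0, USE.NAMES = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("peptides with non-standard residues are skipped with a warning", {
  expect_warning(
    d <- digest(list(accession = "PX", sequence = "AAAKXGGGK"),
                enzyme_preset("lysc"), 0, 1, 50),
    "non-standard")
  expect_equal(d$sequence, "AAAK")
})

test_that("peptide index is mass-sorted and de-duplicates shared peptides", {
  proteins <- data.frame(
    accession = c("A1", "A2"),
    description = "",
    sequence = c("GGGAKAAAR", "CCCCKGGGAK"),  # both yield GGGAK
    stringsAsFactors = FALSE
  )
  cfg <- search_config(enzyme = "trypsin", min_len = 2, max_len = 50,
                       max_missed = 0, mods = list())
  idx <- build_peptide_index(proteins, cfg)
  expect_true(all(diff(idx$masses) >= 0))          # non-decreasing masses
  expect_equal(sum(idx$peptides$sequence == "GGGAK"), 1L)  # one entry
  expect_equal(idx$peptides$protein_accession[idx$peptides$sequence == "GGGAK"],
               "A1;A2")                            # both provenances kept
  # index masses equal peptide_mass recomputed from the sequence
  expect_equal(idx$masses,
               vapply(idx$peptides$sequence, peptide_mass, 0, USE.NAMES = FALSE),
               tolerance = 1e-9)
})

test_that("index of a single tryptic protein composes digest and mass", {
  proteins <- data.frame(accession = "P1", description = "",
                         sequence = "AKRPK", stringsAsFactors = FALSE)
  cfg <- search_config(enzyme = "trypsin", min_len = 1, max_len = 50,
                       max_missed = 0, mods = list())
  idx <- build_peptide_index(proteins, cfg)
  expect_equal(nrow(idx$peptides), 2L)
  expect_equal(sort(idx$peptides$sequence), c("AK", "RPK"))
  expect_equal(idx$masses, sort(c(peptide_mass("AK"), peptide_mass("RPK"))),
               tolerance = 1e-9)
})
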