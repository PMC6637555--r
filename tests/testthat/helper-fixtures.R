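# Shared helpers: tiny deterministic inputs built in code.

# A minimal index over explicit sequences, bypassing digestion.
tiny_index <- function(sequences, accessions = NULL, mods = list()) {
  if (is.null(accessions)) accessions <- sprintf("P%d", seq_along(sequences))
  masses <- vapply(sequences, peptide_mass, 0, mods = mods, USE.NAMES = FALSE)
  ord <- order(masses, sequences)
  peptides <- data.frame(sequence = sequences[ord],
                         neutral_mass = masses[ord],
                         protein_accession = accessions[ord],
                         missed_cleavages = 0L,
                         stringsAsFactors = FALSE)
  structure(list(peptides = peptides, masses = peptides$neutral_mass),
            class = "peptide_index")
}

# A spectrum whose peaks are exactly the b/y fragments of `sequence`.
perfect_spectrum <- function(sequence, charge = 2L, id = "s1",
                             source_index = 1L, mods = list(),
                             extra_mz = numeric(), drop = integer()) {
  mz <- fragment_mzs(sequence, mods)
  if (length(drop) > 0L) mz <- mz[-drop]
  mz <- sort(c(mz, extra_mz))
  mass <- peptide_mass(sequence, mods)
  list(spectrum_id = id,
       precursor_mz = (mass + charge * PROTON_MASS) / charge,
       precursor_charge = as.integer(charge),
       peaks = data.frame(mz = mz, intensity = rep(1, length(mz))),
       source_index = as.integer(source_index))
}

# Dense brute-force SDP oracle: sum of elementwise products of the boolean
# vectors reconstructed from the sparse encodings.
dense_sdp_oracle <- function(bins_c, bins_t) {
  n <- max(c(bins_c, bins_t, 0L)) + 1L
  cv <- logical(n); cv[bins_c + 1L] <- TRUE
  tv <- logical(n); tv[bins_t + 1L] <- TRUE
  sum(cv & tv)
}

# Linear-scan candidate-window oracle.
window_oracle <- function(masses, query, tol) {
  which(abs(masses - query) <= tol)
}

# Random small database + spectra pair used by the algorithm-equivalence
# checks: returns list(index, spectra, config).
random_search_case <- function(seed, n_proteins = 3L) {
  set.seed(seed)
  cfg <- search_config(min_len = 4L, max_len = 30L, max_missed = 1L,
                       precursor_tolerance_da = stats::runif(1, 0.5, 5),
                       fragment_tolerance_da = sample(c(0.2, 0.5, 1.0), 1L),
                       top_k = sample(1:5, 1L))
  proteins <- data.frame(
    accession = sprintf("R%d_%d", seed, seq_len(n_proteins)),
    description = "",
    sequence = vapply(seq_len(n_proteins), function(i)
      paste(sample(names(RESIDUE_MASSES), sample(30:60, 1L), replace = TRUE),
            collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  index <- build_peptide_index(proteins, cfg)
  spectra <- lapply(seq_len(3L), function(i) {
    if (nrow(index$peptides) > 0L && stats::runif(1) < 0.8) {
      pep <- index$peptides$sequence[sample.int(nrow(index$peptides), 1L)]
      nf <- length(fragment_mzs(pep))
      perfect_spectrum(pep, charge = sample(2:3, 1L),
                       id = sprintf("r%d_%d", seed, i), source_index = i,
                       mods = cfg$mods,
                       extra_mz = stats::runif(sample(0:5, 1L), 100, 1500),
                       drop = if (nf > 2L) sample.int(nf, sample(0:2, 1L))
                              else integer())
    } else {
      list(spectrum_id = sprintf("r%d_%d", seed, i),
           precursor_mz = stats::runif(1, 300, 1200),
           precursor_charge = sample(2:3, 1L),
           peaks = data.frame(mz = sort(stats::runif(20, 100, 1500)),
                              intensity = stats::runif(20)),
           source_index = i)
    }
  })
  list(index = index, spectra = spectra, config = cfg)
}
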