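# Deterministic synthetic data: random proteomes, spike-in spectra with
# controlled noise, and scheduler workloads. Everything is seeded, so the
# same specification always produces byte-identical files.

#' Fixture specification
#'
#' Parameters of the synthetic data generator. Residues are drawn uniformly
#' over the 20-letter alphabet; spiked spectra take their peaks from a
#' randomly chosen peptide's b/y ions, with a fraction of fragments
#' removed, uniform-random noise peaks added, and the precursor m/z
#' perturbed within a Da error range. Charges are drawn from
#' `charge_states`; intensities are uniform in (0, 1] since scoring
#' ignores them.
#'
#' @param n_proteins number of proteins.
#' @param protein_length_range integer length bounds, e.g. `c(60, 100)`.
#' @param enzyme enzyme name or [enzyme_rule()] used for the truth table.
#' @param n_spike_spectra number of spiked spectra.
#' @param noise_peaks uniform-random noise peaks per spectrum.
#' @param missing_fraction fraction of true fragments removed, in \[0, 1\].
#' @param mass_error_da half-width of the uniform precursor m/z error (Da).
#' @param charge_states precursor charges to draw from (default 2:3).
#' @param seed integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 20L,
                         protein_length_range = c(60L, 120L),
                         enzyme = "trypsin",
                         n_spike_spectra = 20L,
                         noise_peaks = 0L,
                         missing_fraction = 0,
                         mass_error_da = 0,
                         charge_states = c(2L, 3L),
                         seed = 1L) {
  stopifnot(n_proteins >= 0, n_spike_spectra >= 0, noise_peaks >= 0,
            missing_fraction >= 0, missing_fraction <= 1,
            mass_error_da >= 0, all(charge_states >= 1),
            length(protein_length_range) == 2L,
            protein_length_range[1L] <= protein_length_range[2L])
  if (is.character(enzyme)) enzyme <- enzyme_preset(enzyme)
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 enzyme = enzyme,
                 n_spike_spectra = as.integer(n_spike_spectra),
                 noise_peaks = as.integer(noise_peaks),
                 missing_fraction = missing_fraction,
                 mass_error_da = mass_error_da,
                 charge_states = as.integer(charge_states),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic proteome with its digestion truth table
#'
#' Random protein sequences (uniform residue draw) written as FASTA,
#' together with a truth table of every peptide the configured enzyme
#' produces from each protein (at the given digestion settings), written
#' as TSV.
#'
#' @param spec a [fixture_spec()].
#' @param fasta_path output FASTA path.
#' @param truth_path output TSV path for the peptide truth table.
#' @param config a [search_config()] providing digestion settings.
#' @return list with `proteins` (data.frame) and `truth` (data.frame of
#'   peptides with provenance), invisibly also written to the two paths.
#' @export
make_proteome <- function(spec, fasta_path, truth_path,
                          config = search_config(enzyme = spec$enzyme,
                                                 seed = spec$seed)) {
  set.seed(spec$seed)
  lens <- if (spec$n_proteins > 0L)
    sample(seq.int(spec$protein_length_range[1L],
                   spec$protein_length_range[2L]),
           spec$n_proteins, replace = TRUE) else integer()
  sequences <- vapply(lens, function(L)
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = ""), "")
  proteins <- data.frame(
    accession = sprintf("SYN%04d", seq_len(spec$n_proteins)),
    description = sprintf("synthetic protein %d", seq_len(spec$n_proteins)),
    sequence = sequences,
    stringsAsFactors = FALSE
  )
  write_fasta(proteins, fasta_path)
  parts <- lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], config$enzyme, config$max_missed,
           config$min_len, config$max_len, config$mods))
  truth <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(truth))
    truth <- data.frame(sequence = character(), protein_accession = character(),
                        start = integer(), missed_cleavages = integer(),
                        neutral_mass = numeric(), stringsAsFactors = FALSE)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(proteins = proteins, truth = truth)
}

#' Generate spike-in spectra from a peptide truth table
#'
#' For each spiked spectrum a peptide is drawn from the truth table; its
#' peak list is the peptide's b/y fragment m/z values with
#' `missing_fraction` of them removed at random, plus `noise_peaks`
#' uniform-random m/z values in \[100, 2000\] Da; the precursor m/z is
#' `(mass + z * proton) / z` perturbed uniformly within
#' `mass_error_da / z`. The generating peptide of every spectrum is
#' recorded in a truth map.
#'
#' @param truth peptide truth table from [make_proteome()].
#' @param spec a [fixture_spec()].
#' @param mgf_path output MGF path.
#' @param map_path output TSV path for the spectrum-to-peptide truth map.
#' @param config a [search_config()] providing the fixed modifications.
#' @return list with `spectra` (as from [read_mgf()]) and `truth_map`
#'   (data.frame `spectrum_id`, `peptide_sequence`, `protein_accession`).
#' @export
make_spectra <- function(truth, spec, mgf_path, map_path,
                         config = search_config(enzyme = spec$enzyme,
                                                seed = spec$seed)) {
  if (nrow(truth) == 0L) stop("empty truth table")
  # only peptides long enough to survive fragment loss make useful spikes
  if (spec$n_spike_spectra > nrow(truth))
    stop("requested ", spec$n_spike_spectra, " spikes but only ",
         nrow(truth), " peptides available")
  set.seed(spec$seed + 1L)
  picks <- sample.int(nrow(truth), spec$n_spike_spectra)
  spectra <- vector("list", spec$n_spike_spectra)
  for (i in seq_along(picks)) {
    row <- truth[picks[i], ]
    frags <- fragment_mzs(row$sequence, config$mods)
    n_remove <- floor(spec$missing_fraction * length(frags))
    if (n_remove > 0L)
      frags <- frags[-sample.int(length(frags), n_remove)]
    noise <- if (spec$noise_peaks > 0L)
      stats::runif(spec$noise_peaks, 100, 2000) else numeric()
    mz <- c(frags, noise)
    z <- if (length(spec$charge_states) == 1L) spec$charge_states
         else sample(spec$charge_states, 1L)
    err <- if (spec$mass_error_da > 0)
      stats::runif(1L, -spec$mass_error_da, spec$mass_error_da) / z else 0
    prec_mz <- (row$neutral_mass + z * PROTON_MASS) / z + err
    ord <- order(mz)
    spectra[[i]] <- list(
      spectrum_id = sprintf("spike_%04d", i),
      precursor_mz = prec_mz,
      precursor_charge = z,
      peaks = data.frame(mz = mz[ord],
                         intensity = stats::runif(length(mz))[ord]),
      source_index = i
    )
  }
  write_mgf(spectra, mgf_path)
  truth_map <- data.frame(
    spectrum_id = vapply(spectra, `[[`, "", "spectrum_id"),
    peptide_sequence = truth$sequence[picks],
    protein_accession = truth$protein_accession[picks],
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(spectra = spectra, truth_map = truth_map)
}

#' Generate a simulated scheduling workload
#'
#' Per-chunk costs with lognormal jitter around a unit base cost, and a
#' worker table with the given relative speeds — the input to
#' [simulate_schedule()].
#'
#' @param n_chunks number of chunks (>= 0).
#' @param worker_speeds positive relative speeds, one per worker.
#' @param seed integer seed.
#' @param jitter_sigma lognormal sigma of the per-chunk cost jitter
#'   (0 disables it).
#' @return list with `chunk_costs` and `workers` (data.frame `worker_id`,
#'   `speed_factor`).
#' @export
make_schedule_workload <- function(n_chunks, worker_speeds, seed = 1L,
                                   jitter_sigma = 0.1) {
  stopifnot(n_chunks >= 0, all(worker_speeds > 0), jitter_sigma >= 0)
  set.seed(as.integer(seed))
  costs <- if (jitter_sigma > 0)
    stats::rlnorm(n_chunks, meanlog = 0, sdlog = jitter_sigma)
  else rep(1, n_chunks)
  list(chunk_costs = costs,
       workers = data.frame(worker_id = sprintf("w%d", seq_along(worker_speeds)),
                            speed_factor = worker_speeds,
                            stringsAsFactors = FALSE))
}

#' Write a complete fixture set to a directory
#'
#' Convenience wrapper producing `proteome.fasta`, `peptides.tsv`,
#' `spectra.mgf` and `spectra_truth.tsv` under `dir`.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @param config a [search_config()].
#' @return list with `fasta` and `mgf` paths, `paths` (all four files), and
#'   the in-memory `truth` table and `truth_map`.
#' @export
make_fixture_set <- function(spec, dir,
                             config = search_config(enzyme = spec$enzyme,
                                                    seed = spec$seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "proteome.fasta"),
                truth = file.path(dir, "peptides.tsv"),
                mgf = file.path(dir, "spectra.mgf"),
                truth_map = file.path(dir, "spectra_truth.tsv"))
  prot <- make_proteome(spec, paths$fasta, paths$truth, config)
  sp <- make_spectra(prot$truth, spec, paths$mgf, paths$truth_map, config)
  list(fasta = paths$fasta, mgf = paths$mgf, paths = paths,
       truth = prot$truth, truth_map = sp$truth_map)
}
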