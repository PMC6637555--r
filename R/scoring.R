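# The SDP kernel, precursor-window candidate retrieval, and the two scoring
# algorithms: the two-pass reference (alg1) and the fused single-pass
# variant (micsdp). Their outputs are identical by contract; they differ in
# loop structure and memory behaviour only.

#' Spectrum dot product
#'
#' The boolean dot product of two binned spectra: the number of bins
#' occupied in both, i.e. the size of the intersection of the two bin sets.
#' Both arguments must be binned at the same width.
#'
#' @param c experimental [binned_spectrum()].
#' @param t theoretical [binned_spectrum()].
#' @return Non-negative integer score.
#' @examples
#' sdp(binarize(c(100, 200, 300, 400), 1), binarize(c(200, 400, 500), 1)) # 2
#' @export
sdp <- function(c, t) {
  if (!isTRUE(all.equal(c$bin_width, t$bin_width)))
    stop("mismatched bin widths: ", c$bin_width, " vs ", t$bin_width)
  sum(t$bins %in% c$bins)
}

#' Precursor-tolerance candidate window
#'
#' Binary search (via `findInterval`) for the maximal half-open window
#' `[lo, hi)` of entries in a mass-sorted peptide index whose neutral mass
#' lies within `tol` Da of `query_mass`. Indices are 1-based; the window is
#' empty when `lo == hi`.
#'
#' @param index a `peptide_index` from [build_peptide_index()], or a sorted
#'   numeric mass vector.
#' @param query_mass query neutral mass in Da.
#' @param tol symmetric tolerance in Da (>= 0).
#' @return list with `lo` and `hi` (half-open, 1-based).
#' @export
candidate_window <- function(index, query_mass, tol) {
  if (tol < 0) stop("tol must be >= 0")
  masses <- if (inherits(index, "peptide_index")) index$masses else index
  lo <- findInterval(query_mass - tol, masses, left.open = TRUE) + 1L
  hi <- findInterval(query_mass + tol, masses) + 1L
  if (hi < lo) hi <- lo
  list(lo = lo, hi = hi)
}

# Neutral precursor mass from measured m/z and charge.
precursor_neutral_mass <- function(precursor_mz, charge) {
  (precursor_mz - PROTON_MASS) * charge
}

# Ordering key shared by both scorers: score descending, then smaller
# |peptide mass - query mass|, then lexicographic sequence. Sequences are
# unique in the index, so the key is total.
psm_order <- function(score, mass_delta, sequence) {
  order(-score, mass_delta, sequence)
}

#' Rank scored candidates into PSMs
#'
#' Sorts candidates by score (descending), breaking ties by smaller
#' absolute mass difference to the precursor, then lexicographic sequence;
#' drops zero scores; keeps at most `k`; assigns ranks 1..n.
#'
#' @param scored data.frame with columns `sequence`, `neutral_mass`,
#'   `protein_accession`, `score`.
#' @param query_mass precursor neutral mass in Da (for the tie-break).
#' @param k maximum PSMs returned.
#' @return data.frame with `peptide_sequence`, `protein_accession`,
#'   `peptide_mass`, `sdp_score`, `rank`.
#' @export
rank_psms <- function(scored, query_mass, k) {
  stopifnot(k >= 1)
  keep <- scored$score > 0
  scored <- scored[keep, , drop = FALSE]
  if (nrow(scored) == 0L) return(empty_psm_df())
  delta <- abs(scored$neutral_mass - query_mass)
  ord <- psm_order(scored$score, delta, scored$sequence)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    peptide_sequence = scored$sequence[ord],
    protein_accession = scored$protein_accession[ord],
    peptide_mass = scored$neutral_mass[ord],
    sdp_score = as.integer(scored$score[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}

empty_psm_df <- function() {
  data.frame(peptide_sequence = character(), protein_accession = character(),
             peptide_mass = numeric(), sdp_score = integer(),
             rank = integer(), stringsAsFactors = FALSE)
}

finalize_psms <- function(psms, spectrum) {
  if (nrow(psms) == 0L)
    return(data.frame(spectrum_id = character(), peptide_sequence = character(),
                      protein_accession = character(), peptide_mass = numeric(),
                      precursor_neutral_mass = numeric(), sdp_score = integer(),
                      rank = integer(), source_index = integer(),
                      stringsAsFactors = FALSE))
  qm <- precursor_neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
  data.frame(spectrum_id = spectrum$spectrum_id,
             peptide_sequence = psms$peptide_sequence,
             protein_accession = psms$protein_accession,
             peptide_mass = psms$peptide_mass,
             precursor_neutral_mass = qm,
             sdp_score = psms$sdp_score,
             rank = psms$rank,
             source_index = spectrum$source_index,
             stringsAsFactors = FALSE)
}

#' Score one spectrum: two-pass reference algorithm
#'
#' The classical two-part scorer: first the precursor-window binary search
#' materializes the full candidate list H, then every candidate is scored
#' with [sdp()] and the scores are ranked. Serves as the reference the
#' fused scorer must reproduce exactly.
#'
#' @param spectrum a spectrum from [read_mgf()].
#' @param index a `peptide_index`.
#' @param config a [search_config()].
#' @return data.frame of ranked PSMs for this spectrum (possibly empty).
#' @export
score_spectrum_alg1 <- function(spectrum, index, config) {
  w <- config$fragment_tolerance_da
  cbin <- binarize_experimental(spectrum, w, config$top_n_peaks)
  qm <- precursor_neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
  win <- candidate_window(index, qm, config$precursor_tolerance_da)
  if (win$hi <= win$lo) return(finalize_psms(empty_psm_df(), spectrum))
  # pass 1: materialize the candidate list H
  cand <- index$peptides[win$lo:(win$hi - 1L), , drop = FALSE]
  bump_counter("candidate_materializations")
  # pass 2: score every candidate
  cand$score <- vapply(cand$sequence, function(s)
    sdp(cbin, theoretical_spectrum(s, w, config$mods)), 0L, USE.NAMES = FALSE)
  finalize_psms(rank_psms(cand, qm, config$top_k), spectrum)
}

#' Score one spectrum: fused single-pass algorithm
#'
#' Merges candidate retrieval and peak matching into one streaming pass:
#' after a single binary search, each candidate is scored immediately and
#' pushed through a bounded top-k buffer, so no candidate list (and no
#' full score vector) is ever materialized. The unit of work is one whole
#' spectrum, which is what makes per-spectrum parallel dispatch possible.
#' Output is identical to [score_spectrum_alg1()] on every input.
#'
#' @inheritParams score_spectrum_alg1
#' @return data.frame of ranked PSMs, field-for-field equal to the
#'   reference scorer's output.
#' @export
score_spectrum_micsdp <- function(spectrum, index, config) {
  w <- config$fragment_tolerance_da
  cbin <- binarize_experimental(spectrum, w, config$top_n_peaks)
  qm <- precursor_neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
  win <- candidate_window(index, qm, config$precursor_tolerance_da)
  k <- config$top_k
  # bounded top-k buffer: never holds more than k + 1 entries
  buf_seq <- character(0); buf_mass <- numeric(0)
  buf_acc <- character(0); buf_score <- integer(0)
  if (win$hi > win$lo) {
    for (i in win$lo:(win$hi - 1L)) {
      s <- index$peptides$sequence[i]
      sc <- sdp(cbin, theoretical_spectrum(s, w, config$mods))
      if (sc == 0L) next
      buf_seq <- c(buf_seq, s)
      buf_mass <- c(buf_mass, index$peptides$neutral_mass[i])
      buf_acc <- c(buf_acc, index$peptides$protein_accession[i])
      buf_score <- c(buf_score, sc)
      if (length(buf_score) > k) {
        keep <- psm_order(buf_score, abs(buf_mass - qm), buf_seq)[seq_len(k)]
        buf_seq <- buf_seq[keep]; buf_mass <- buf_mass[keep]
        buf_acc <- buf_acc[keep]; buf_score <- buf_score[keep]
      }
    }
  }
  if (length(buf_score) == 0L) return(finalize_psms(empty_psm_df(), spectrum))
  ord <- psm_order(buf_score, abs(buf_mass - qm), buf_seq)
  psms <- data.frame(
    peptide_sequence = buf_seq[ord],
    protein_accession = buf_acc[ord],
    peptide_mass = buf_mass[ord],
    sdp_score = as.integer(buf_score[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  finalize_psms(psms, spectrum)
}

#' Score one spectrum with the configured algorithm
#'
#' @inheritParams score_spectrum_alg1
#' @export
score_spectrum <- function(spectrum, index, config) {
  if (config$algorithm == "alg1") score_spectrum_alg1(spectrum, index, config)
  else score_spectrum_micsdp(spectrum, index, config)
}
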