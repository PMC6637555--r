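# Theoretical fragment spectra and the boolean bin-vector representation.
#
# A spectrum (experimental or theoretical) is reduced to a sparse boolean
# vector over m/z bins: bin i is 1 iff some peak falls in [i*w, (i+1)*w)
# where w is the bin width. The sparse encoding is the strictly increasing
# integer vector of occupied bins.

#' Sparse binned spectrum
#'
#' @param bins integer vector of occupied bin indices (deduplicated and
#'   sorted by the constructor).
#' @param bin_width bin width in Da.
#' @return A `binned_spectrum` object.
#' @export
binned_spectrum <- function(bins, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  bins <- sort(unique(as.integer(bins)))
  if (length(bins) > 0L && bins[1L] < 0L) stop("negative bin index")
  structure(list(bins = bins, bin_width = bin_width),
            class = "binned_spectrum")
}

#' Binarize a peak list
#'
#' Maps each m/z to bin `floor(mz / bin_width)` and collapses duplicates —
#' the boolean peak-presence vector in sparse form. No neighbour-bin
#' matching is performed: the fragment tolerance enters only as the bin
#' width.
#'
#' @param mzs numeric vector of m/z values (Da), all non-negative.
#' @param bin_width bin width in Da (> 0).
#' @return A [binned_spectrum()].
#' @examples
#' binarize(c(500.0), 0.5)          # bin 1000
#' binarize(c(100.1, 100.3), 0.5)   # both collapse into bin 200
#' @export
binarize <- function(mzs, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(mzs) > 0L && any(mzs < 0)) stop("negative m/z")
  binned_spectrum(floor(mzs / bin_width), bin_width)
}

#' Binarize an experimental spectrum
#'
#' Optionally keeps only the `top_n` most intense peaks (ties broken by
#' intensity descending, then m/z ascending) before binning. Intensities
#' play no further role: scoring is boolean.
#'
#' @param spectrum a spectrum as returned by [read_mgf()].
#' @param bin_width bin width in Da.
#' @param top_n number of peaks to keep; `Inf` disables filtering.
#' @return A [binned_spectrum()].
#' @export
binarize_experimental <- function(spectrum, bin_width, top_n = Inf) {
  pk <- spectrum$peaks
  if (is.finite(top_n)) {
    if (top_n < 1) stop("top_n must be >= 1 or Inf")
    ord <- order(-pk$intensity, pk$mz)
    pk <- pk[ord[seq_len(min(top_n, nrow(pk)))], , drop = FALSE]
  }
  binarize(pk$mz, bin_width)
}

#' Singly-protonated b/y fragment m/z values
#'
#' For a peptide of length L, the b series is the prefix residue sums plus a
#' proton (b1..b(L-1)) and the y series is the suffix residue sums plus
#' water and a proton (y1..y(L-1)). Fixed modifications shift the affected
#' residues. Returned in ascending m/z order; a length-1 peptide has no
#' internal cleavage and yields an empty vector.
#'
#' @param sequence peptide sequence string.
#' @param mods list of [fixed_mod()] objects.
#' @return Numeric vector of 2(L-1) fragment m/z values, ascending.
#' @examples
#' fragment_mzs("AG")  # b1 = 72.044386, y1 = 76.039301
#' @export
fragment_mzs <- function(sequence, mods = list()) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  if (L < 2L) return(numeric())
  tab <- residue_mass_table(mods)
  m <- unname(tab[aa])
  if (anyNA(m)) stop("unknown residue(s) in ", sequence)
  prefix <- cumsum(m)[seq_len(L - 1L)]
  suffix <- cumsum(rev(m))[seq_len(L - 1L)]
  b <- prefix + PROTON_MASS
  y <- suffix + WATER_MASS + PROTON_MASS
  sort(c(b, y))
}

#' Theoretical binned spectrum for a peptide
#'
#' @param sequence peptide sequence.
#' @param bin_width bin width in Da (the fragment tolerance).
#' @param mods list of [fixed_mod()] objects.
#' @return A [binned_spectrum()] of the b/y fragment bins.
#' @export
theoretical_spectrum <- function(sequence, bin_width, mods = list()) {
  binarize(fragment_mzs(sequence, mods), bin_width)
}
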