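# Monoisotopic mass constants. Residue masses are the standard monoisotopic
# values for the 20 canonical amino acids (residue = amino acid minus water).

#' Monoisotopic mass constants
#'
#' Physical constants used throughout the package: the proton mass (charge
#' carrier for singly protonated ions) and the mass of one water molecule
#' (added once per intact peptide).
#'
#' @format Named numeric scalars, in Da.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.007276

#' @rdname mass-constants
#' @export
WATER_MASS <- 18.010565

#' Monoisotopic residue masses
#'
#' Named numeric vector of monoisotopic residue masses (Da) for the 20
#' standard amino acids, keyed by one-letter code.
#'
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Fixed modification descriptor
#'
#' A fixed (static) modification applied to every occurrence of a target
#' residue, e.g. carbamidomethylation of cysteine (+57.021464 Da).
#'
#' @param target_residue single one-letter amino-acid code.
#' @param delta_mass finite mass shift in Da.
#' @return A `fixed_mod` object (list with `target_residue`, `delta_mass`).
#' @examples
#' carbamidomethyl <- fixed_mod("C", 57.021464)
#' @export
fixed_mod <- function(target_residue, delta_mass) {
  stopifnot(is.character(target_residue), nchar(target_residue) == 1L,
            target_residue %in% names(RESIDUE_MASSES))
  if (!is.finite(delta_mass)) stop("delta_mass must be finite")
  structure(list(target_residue = target_residue, delta_mass = delta_mass),
            class = "fixed_mod")
}

#' Parse modification strings of the form "C:+57.021464"
#'
#' @param specs character vector, each `"<residue>:<delta>"`.
#' @return list of [fixed_mod()] objects.
#' @export
parse_mods <- function(specs) {
  if (length(specs) == 0L) return(list())
  lapply(specs, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("bad modification spec: ", s)
    delta <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(delta)) stop("bad modification delta in: ", s)
    fixed_mod(parts[1L], delta)
  })
}

# Per-residue mass vector with fixed modifications folded in.
residue_mass_table <- function(mods = list()) {
  tab <- RESIDUE_MASSES
  for (m in mods) tab[[m$target_residue]] <- tab[[m$target_residue]] + m$delta_mass
  tab
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide: the sum of its (possibly fixed-
#' modified) residue masses plus one water.
#'
#' @param sequence non-empty string over the 20 standard one-letter codes.
#' @param mods list of [fixed_mod()] objects (default none).
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")                               # 75.032025
#' peptide_mass("C", list(fixed_mod("C", 57.021464)))
#' @export
peptide_mass <- function(sequence, mods = list()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a non-empty string")
  tab <- residue_mass_table(mods)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- tab[aa]
  if (anyNA(m)) stop("unknown residue(s): ",
                     paste(unique(aa[is.na(m)]), collapse = ", "))
  sum(m) + WATER_MASS
}
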