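# In-silico enzymatic digestion and the mass-sorted peptide index.

#' Enzymatic cleavage rule
#'
#' Describes where an enzyme cuts: either C-terminal to any residue in
#' `cleave_after`, or N-terminal to any residue in `cleave_before` (exactly
#' one of the two must be non-empty). Residues in `restrict_next`
#' immediately following a C-terminal site block the cut (the proline rule
#' for trypsin).
#'
#' @param name enzyme name.
#' @param cleave_after residues cut after (C-terminal rule), or `character()`.
#' @param cleave_before residues cut before (N-terminal rule), or
#'   `character()`.
#' @param restrict_next residues that suppress a C-terminal cut when they
#'   follow the site.
#' @return An `enzyme_rule` object.
#' @examples
#' trypsin <- enzyme_rule("trypsin", cleave_after = c("K", "R"),
#'                        restrict_next = "P")
#' @export
enzyme_rule <- function(name, cleave_after = character(),
                        cleave_before = character(),
                        restrict_next = character()) {
  if ((length(cleave_after) > 0L) == (length(cleave_before) > 0L))
    stop("exactly one of cleave_after / cleave_before must be non-empty")
  structure(list(name = name,
                 cleave_after = cleave_after,
                 cleave_before = cleave_before,
                 restrict_next = restrict_next),
            class = "enzyme_rule")
}

#' Built-in enzyme definitions
#'
#' Standard Expasy-style rules: trypsin cleaves after K or R unless the next
#' residue is P; LysC after K with no restriction; AspN before D.
#'
#' @param name one of `"trypsin"`, `"lysc"`, `"aspn"` (case-insensitive).
#' @return An [enzyme_rule()] object.
#' @export
enzyme_preset <- function(name) {
  switch(tolower(name),
    trypsin = enzyme_rule("trypsin", cleave_after = c("K", "R"),
                          restrict_next = "P"),
    lysc = enzyme_rule("lysc", cleave_after = "K"),
    aspn = enzyme_rule("aspn", cleave_before = "D"),
    stop("unknown enzyme: ", name, " (expected trypsin, lysc or aspn)")
  )
}

# 0-based positions after which the chain is cut (boundaries between
# residues i and i+1, for i in 1..L-1), given a cleavage rule.
cleavage_sites <- function(aa, rule) {
  L <- length(aa)
  if (L < 2L) return(integer())
  idx <- seq_len(L - 1L)
  if (length(rule$cleave_after) > 0L) {
    hit <- aa[idx] %in% rule$cleave_after
    if (length(rule$restrict_next) > 0L)
      hit <- hit & !(aa[idx + 1L] %in% rule$restrict_next)
  } else {
    hit <- aa[idx + 1L] %in% rule$cleave_before
  }
  idx[hit]
}

#' Digest one protein in silico
#'
#' Applies the cleavage rule to produce all fully-cleaved fragments, then
#' every concatenation of up to `max_missed` adjacent fragments, filtered by
#' peptide length. Peptides containing non-standard residues are skipped
#' with a warning. Output order is deterministic: by start offset, then
#' length.
#'
#' @param protein one-row data.frame (or list) with `accession` and
#'   `sequence`, or a plain sequence string (accession `"?"`).
#' @param rule an [enzyme_rule()].
#' @param max_missed maximum missed cleavages.
#' @param min_len,max_len inclusive peptide length bounds.
#' @param mods list of [fixed_mod()] objects used for `neutral_mass`.
#' @return data.frame with columns `sequence`, `protein_accession`, `start`
#'   (0-based), `missed_cleavages`, `neutral_mass`.
#' @examples
#' digest(list(accession = "P1", sequence = "AKRPK"),
#'        enzyme_preset("trypsin"), max_missed = 0,
#'        min_len = 1, max_len = 50)
#' @export
digest <- function(protein, rule, max_missed = 2L, min_len = 6L,
                   max_len = 50L, mods = list()) {
  if (is.character(protein)) protein <- list(accession = "?", sequence = protein)
  stopifnot(max_missed >= 0, min_len >= 1, min_len <= max_len)
  seqstr <- protein$sequence
  aa <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  sites <- cleavage_sites(aa, rule)
  bounds <- c(0L, sites, L)           # fragment boundaries, 0-based
  nfrag <- length(bounds) - 1L
  tab <- residue_mass_table(mods)
  out <- list()
  skipped <- character()
  for (i in seq_len(nfrag)) {
    for (k in 0:max_missed) {
      j <- i + k
      if (j > nfrag) break
      start <- bounds[i]
      end <- bounds[j + 1L]
      len <- end - start
      if (len < min_len || len > max_len) next
      pep_aa <- aa[(start + 1L):end]
      pep <- paste(pep_aa, collapse = "")
      m <- tab[pep_aa]
      if (anyNA(m)) { skipped <- c(skipped, pep); next }
      out[[length(out) + 1L]] <- list(sequence = pep, start = start,
                                      missed_cleavages = k,
                                      neutral_mass = sum(m) + WATER_MASS)
    }
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped),
            " peptide(s) with non-standard residues in ",
            protein$accession)
  if (length(out) == 0L)
    return(data.frame(sequence = character(), protein_accession = character(),
                      start = integer(), missed_cleavages = integer(),
                      neutral_mass = numeric(), stringsAsFactors = FALSE))
  df <- data.frame(
    sequence = vapply(out, `[[`, "", "sequence"),
    protein_accession = protein$accession,
    start = vapply(out, `[[`, 0L, "start"),
    missed_cleavages = vapply(out, `[[`, 0L, "missed_cleavages"),
    neutral_mass = vapply(out, `[[`, 0, "neutral_mass"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$start, nchar(df$sequence)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the mass-sorted peptide index
#'
#' Digests every protein and assembles the searchable candidate set:
#' identical sequences collapse to one scored entry carrying all protein
#' provenances (semicolon-joined, sorted), sorted ascending by neutral mass
#' with ties broken by sequence. This is the structure the precursor-window
#' binary search runs against.
#'
#' @param proteins data.frame from [read_fasta()].
#' @param config a [search_config()].
#' @return A `peptide_index`: list with `peptides` (data.frame `sequence`,
#'   `neutral_mass`, `protein_accession`, `missed_cleavages`) and `masses`
#'   (the sorted numeric vector used for binary search).
#' @export
build_peptide_index <- function(proteins, config) {
  parts <- lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], config$enzyme, config$max_missed,
           config$min_len, config$max_len, config$mods))
  all <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(all) || nrow(all) == 0L) {
    peptides <- data.frame(sequence = character(), neutral_mass = numeric(),
                           protein_accession = character(),
                           missed_cleavages = integer(),
                           stringsAsFactors = FALSE)
    return(structure(list(peptides = peptides, masses = numeric()),
                     class = "peptide_index"))
  }
  # provenance kept per distinct sequence; ties in the sort broken by
  # (sequence, accession, start) via the pre-ordering below
  all <- all[order(all$sequence, all$protein_accession, all$start), ,
             drop = FALSE]
  acc <- vapply(split(all$protein_accession, all$sequence),
                function(a) paste(sort(unique(a)), collapse = ";"), "")
  first <- all[!duplicated(all$sequence), , drop = FALSE]
  first$protein_accession <- acc[first$sequence]
  ord <- order(first$neutral_mass, first$sequence)
  peptides <- first[ord, c("sequence", "neutral_mass", "protein_accession",
                           "missed_cleavages"), drop = FALSE]
  rownames(peptides) <- NULL
  structure(list(peptides = peptides, masses = peptides$neutral_mass),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("peptide_index:", nrow(x$peptides), "peptides, mass range [",
      if (length(x$masses)) sprintf("%.4f, %.4f", min(x$masses), max(x$masses))
      else "empty", "] Da\n")
  invisible(x)
}
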