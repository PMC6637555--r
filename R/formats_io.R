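# Input/output: FASTA protein databases, MGF spectrum files, TSV PSM report.

AA_STANDARD <- names(RESIDUE_MASSES)
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

#' Read a FASTA protein database
#'
#' Parses a FASTA file into a protein table. Headers are split at the first
#' whitespace into accession and description; multi-line sequences are
#' concatenated and uppercased. Non-standard residue codes (B, J, O, U, X,
#' Z) are tolerated here; peptides containing them are dropped later, at
#' digestion time, with a warning.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L)
    return(data.frame(accession = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(aa))
  empty <- !nzchar(sequence)
  if (any(empty))
    stop("empty sequence for accession(s): ",
         paste(accession[empty], collapse = ", "))
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0L)
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "))
  bad <- vapply(sequence, function(s)
    any(!strsplit(s, "")[[1L]] %in% c(AA_STANDARD, AA_NONSTANDARD)), logical(1L))
  if (any(bad))
    stop("invalid residue characters in: ",
         paste(accession[bad], collapse = ", "))
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records as FASTA
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path output file path.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$accession, proteins$description),
                proteins$accession)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read MS/MS spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. Each block must carry `PEPMASS`
#' (precursor m/z; a second token, if present, is the precursor intensity
#' and is ignored). `CHARGE` is optional and defaults to `default_charge`;
#' `TITLE` supplies the spectrum id, otherwise one is synthesized from the
#' block's ordinal position. Peaks are sorted ascending by m/z.
#'
#' @param path MGF file path.
#' @param default_charge precursor charge assumed when a block has no
#'   `CHARGE` line (default 2).
#' @return List of spectra; each is a list with `spectrum_id`,
#'   `precursor_mz`, `precursor_charge`, `peaks` (data.frame `mz`,
#'   `intensity`) and `source_index`.
#' @export
read_mgf <- function(path, default_charge = 2L) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      in_block <- TRUE
      block <- list(title = NULL, pepmass = NULL, charge = NULL,
                    mz = numeric(), intensity = numeric(), start_line = i)
      next
    }
    if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i)
      if (is.null(block$pepmass))
        stop("spectrum block starting at line ", block$start_line,
             " has no PEPMASS")
      idx <- length(spectra) + 1L
      ord <- order(block$mz)
      spectra[[idx]] <- list(
        spectrum_id = if (is.null(block$title)) sprintf("index=%d", idx)
                      else block$title,
        precursor_mz = block$pepmass,
        precursor_charge = if (is.null(block$charge)) as.integer(default_charge)
                           else block$charge,
        peaks = data.frame(mz = block$mz[ord], intensity = block$intensity[ord]),
        source_index = idx
      )
      in_block <- FALSE
      next
    }
    if (!in_block) next  # header junk outside blocks is ignored
    if (grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") block$title <- val
      else if (key == "PEPMASS") {
        mz <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1L]][1L]))
        if (is.na(mz) || mz <= 0) stop("bad PEPMASS at line ", i)
        block$pepmass <- mz
      } else if (key == "CHARGE") {
        z <- suppressWarnings(as.integer(sub("\\+$", "", trimws(val))))
        if (is.na(z) || z < 1) stop("bad CHARGE at line ", i)
        block$charge <- z
      }
      next
    }
    toks <- strsplit(ln, "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < 1L || anyNA(vals[seq_len(min(2L, length(vals)))]))
      stop("non-numeric peak line at line ", i, ": ", ln)
    block$mz <- c(block$mz, vals[1L])
    block$intensity <- c(block$intensity,
                         if (length(vals) >= 2L) vals[2L] else 1)
  }
  if (in_block) stop("unterminated spectrum block at end of file")
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of spectra in the shape produced by [read_mgf()].
#' @param path output file path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.5f %.6f", s$peaks$mz, s$peaks$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

PSM_COLUMNS <- c("spectrum_id", "peptide_sequence", "protein_accession",
                 "peptide_mass", "precursor_neutral_mass", "sdp_score", "rank")

#' Write ranked PSMs as a tab-separated report
#'
#' Masses are printed to 5 decimal places; SDP scores are integers (the
#' boolean dot product is a count). Row order is taken from the input,
#' which [merge_results()] guarantees to be (spectrum source order, rank).
#'
#' @param psms data.frame of PSMs (see [merge_results()]).
#' @param path output file path.
#' @export
write_psm_report <- function(psms, path) {
  if (is.null(psms) || nrow(psms) == 0L) {
    writeLines(paste(PSM_COLUMNS, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(
    spectrum_id = psms$spectrum_id,
    peptide_sequence = psms$peptide_sequence,
    protein_accession = psms$protein_accession,
    peptide_mass = sprintf("%.5f", psms$peptide_mass),
    precursor_neutral_mass = sprintf("%.5f", psms$precursor_neutral_mass),
    sdp_score = as.integer(psms$sdp_score),
    rank = as.integer(psms$rank),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PSM report written by [write_psm_report()]
#'
#' @param path report path.
#' @return data.frame with the report columns, numerics parsed.
#' @export
read_psm_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric", "integer", "integer"),
                    stringsAsFactors = FALSE)
}
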