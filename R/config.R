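#' Search configuration
#'
#' Assembles and validates every tunable of an end-to-end search: digestion
#' rules, mass tolerances, scoring algorithm and worker-pool settings.
#' Tolerances are symmetric and in Da. `algorithm` selects the two-pass
#' reference scorer (`"alg1"`) or the fused single-pass scorer (`"micsdp"`);
#' both produce identical results by contract.
#'
#' @param enzyme one of `"trypsin"`, `"aspn"`, `"lysc"`, or an
#'   [enzyme_rule()] object.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len,max_len peptide length bounds (defaults 6 and 50).
#' @param mods list of [fixed_mod()] objects or character specs like
#'   `"C:+57.021464"` (default: carbamidomethylation of cysteine).
#' @param precursor_tolerance_da precursor mass tolerance in Da (default 3).
#' @param fragment_tolerance_da fragment tolerance in Da, used as the
#'   m/z bin width (default 0.5).
#' @param top_k PSMs reported per spectrum (default 10).
#' @param algorithm `"micsdp"` (default) or `"alg1"`.
#' @param top_n_peaks keep only the n most intense experimental peaks before
#'   binning; `Inf` (default) disables filtering.
#' @param default_charge precursor charge assumed when the input omits it
#'   (default 2).
#' @param n_workers logical workers in the pipeline pool (default 1).
#' @param queue_capacity bounded-queue capacity, at least 2 (default 2,
#'   i.e. double buffering).
#' @param imbalance_threshold scheduler load-imbalance target (default 0.08).
#' @param alpha geometric smoothing coefficient for worker weights
#'   (default 0.5).
#' @param seed integer seed governing all randomness (default 1).
#' @return A validated `search_config` list.
#' @examples
#' cfg <- search_config(enzyme = "trypsin", precursor_tolerance_da = 3,
#'                      fragment_tolerance_da = 0.5)
#' @export
search_config <- function(enzyme = "trypsin",
                          max_missed = 2L,
                          min_len = 6L,
                          max_len = 50L,
                          mods = list(fixed_mod("C", 57.021464)),
                          precursor_tolerance_da = 3,
                          fragment_tolerance_da = 0.5,
                          top_k = 10L,
                          algorithm = c("micsdp", "alg1"),
                          top_n_peaks = Inf,
                          default_charge = 2L,
                          n_workers = 1L,
                          queue_capacity = 2L,
                          imbalance_threshold = 0.08,
                          alpha = 0.5,
                          seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.character(enzyme)) enzyme <- enzyme_preset(enzyme)
  if (is.character(mods)) mods <- parse_mods(mods)
  stopifnot(inherits(enzyme, "enzyme_rule"),
            max_missed >= 0, min_len >= 1, min_len <= max_len,
            precursor_tolerance_da > 0, fragment_tolerance_da > 0,
            top_k >= 1, default_charge >= 1,
            n_workers >= 1, queue_capacity >= 2,
            imbalance_threshold > 0, alpha >= 0, alpha <= 1)
  if (!(is.infinite(top_n_peaks) || top_n_peaks >= 1))
    stop("top_n_peaks must be >= 1 or Inf")
  structure(list(
    enzyme = enzyme,
    max_missed = as.integer(max_missed),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    mods = mods,
    precursor_tolerance_da = precursor_tolerance_da,
    fragment_tolerance_da = fragment_tolerance_da,
    top_k = as.integer(top_k),
    algorithm = algorithm,
    top_n_peaks = top_n_peaks,
    default_charge = as.integer(default_charge),
    n_workers = as.integer(n_workers),
    queue_capacity = as.integer(queue_capacity),
    imbalance_threshold = imbalance_threshold,
    alpha = alpha,
    seed = as.integer(seed)
  ), class = "search_config")
}

# Instrumentation counters (e.g. candidate-list materializations) live in a
# package-local environment so tests can observe algorithmic behaviour
# without timing anything.
.counters <- new.env(parent = emptyenv())

#' Reset or read instrumentation counters
#'
#' The scorers maintain lightweight counters (such as the number of
#' materialized candidate lists) used to verify structural claims about the
#' algorithms, not performance.
#'
#' @return `counters()` returns a named list of counter values.
#' @export
reset_counters <- function() {
  rm(list = ls(.counters), envir = .counters)
  invisible(NULL)
}

#' @rdname reset_counters
#' @export
counters <- function() as.list(.counters)

bump_counter <- function(name, by = 1L) {
  cur <- if (exists(name, envir = .counters, inherits = FALSE))
    get(name, envir = .counters) else 0L
  assign(name, cur + by, envir = .counters)
  invisible(NULL)
}
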