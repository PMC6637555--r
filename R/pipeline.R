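# End-to-end search pipeline: four phases (partition, candidate retrieval,
# per-chunk scoring through bounded request/response queues, merge), plus
# the bounded circular queue primitive realizing double buffering.

#' Bounded circular queue
#'
#' Fixed-capacity FIFO with head/tail counters, the building block of the
#' request/response queue pair between the host and a worker. `queue_put`
#' returns `FALSE` instead of blocking when the queue is full (the
#' cooperative pipeline retries), `queue_get` returns `NULL` when empty.
#' Enqueue/dequeue totals are tracked so conservation can be audited.
#'
#' @param capacity number of slots, at least 2 (2 = double buffering).
#' @return A `bounded_queue` environment.
#' @export
bounded_queue <- function(capacity = 2L) {
  stopifnot(capacity >= 2L)
  q <- new.env(parent = emptyenv())
  q$slots <- vector("list", capacity)
  q$capacity <- as.integer(capacity)
  q$head <- 0L   # next slot to read
  q$tail <- 0L   # next slot to write
  q$count <- 0L
  q$enqueued <- 0L
  q$dequeued <- 0L
  class(q) <- "bounded_queue"
  q
}

#' @rdname bounded_queue
#' @param q a `bounded_queue`.
#' @param msg payload to enqueue.
#' @export
queue_put <- function(q, msg) {
  if (q$count == q$capacity) return(FALSE)
  q$slots[[q$tail + 1L]] <- msg
  q$tail <- (q$tail + 1L) %% q$capacity
  q$count <- q$count + 1L
  q$enqueued <- q$enqueued + 1L
  TRUE
}

#' @rdname bounded_queue
#' @export
queue_get <- function(q) {
  if (q$count == 0L) return(NULL)
  msg <- q$slots[[q$head + 1L]]
  q$slots[q$head + 1L] <- list(NULL)
  q$head <- (q$head + 1L) %% q$capacity
  q$count <- q$count - 1L
  q$dequeued <- q$dequeued + 1L
  msg
}

#' @rdname bounded_queue
#' @export
queue_size <- function(q) q$count

#' Pipelined chunk transfer through bounded queue pairs
#'
#' Cooperative host/worker loop: each worker owns a request queue and a
#' response queue of fixed capacity. The host keeps every live worker's
#' request queue primed (so the next chunk is in transit while the current
#' one is scored — double buffering), workers repeatedly dequeue a chunk,
#' process it, and enqueue the result; the host drains responses. At no
#' point does a worker hold more unacknowledged chunks than the queue
#' capacity. If a worker dies mid-run its in-flight and queued chunks are
#' requeued to the remaining workers, so every chunk is processed exactly
#' once.
#'
#' @param chunks list of chunk payloads.
#' @param n_workers number of logical workers.
#' @param process function applied to one chunk payload.
#' @param capacity per-queue capacity (>= 2).
#' @param kill_worker optional worker id to kill mid-run (for fault tests).
#' @param kill_after number of chunks that worker completes before dying.
#' @return list with `results` (in completion order, each
#'   `list(chunk_id, value, worker)`), and `stats` (per-queue enqueue and
#'   dequeue totals, max in-flight observed, per-worker completion counts).
#' @export
pipelined_transfer <- function(chunks, n_workers, process,
                               capacity = 2L, kill_worker = NULL,
                               kill_after = 0L) {
  stopifnot(n_workers >= 1L, capacity >= 2L)
  n <- length(chunks)
  pending <- if (n > 0L) seq_len(n) else integer()  # not yet dispatched
  req <- lapply(seq_len(n_workers), function(i) bounded_queue(capacity))
  res <- lapply(seq_len(n_workers), function(i) bounded_queue(capacity))
  alive <- rep(TRUE, n_workers)
  unacked <- integer(n_workers)    # dispatched, response not yet drained
  completed <- integer(n_workers)
  results <- list()
  n_done <- 0L
  max_unacked <- 0L
  drain <- function(w) {
    repeat {
      msg <- queue_get(res[[w]])
      if (is.null(msg)) return(invisible(NULL))
      results[[length(results) + 1L]] <<- msg
      unacked[w] <<- unacked[w] - 1L
      n_done <<- n_done + 1L
    }
  }
  while (n_done < n) {
    # host: prime request queues of live workers
    for (w in seq_len(n_workers)) {
      while (alive[w] && length(pending) > 0L && unacked[w] < capacity &&
             queue_put(req[[w]], pending[1L])) {
        pending <- pending[-1L]
        unacked[w] <- unacked[w] + 1L
        max_unacked <- max(max_unacked, unacked[w])
      }
    }
    dispatched_any <- FALSE
    # workers: take one request each, score, respond
    for (w in seq_len(n_workers)) {
      if (!alive[w]) next
      chunk_id <- queue_get(req[[w]])
      if (is.null(chunk_id)) next
      dispatched_any <- TRUE
      # injected fault: worker dies before finishing this chunk; it and any
      # chunks still queued to the dead worker go back to the pending pool
      if (!is.null(kill_worker) && w == kill_worker &&
          completed[w] >= kill_after) {
        alive[w] <- FALSE
        requeue <- chunk_id
        repeat {
          lost <- queue_get(req[[w]])
          if (is.null(lost)) break
          requeue <- c(requeue, lost)
        }
        drain(w)                     # completed responses are still valid
        if (!any(alive)) stop("all workers dead with chunks remaining")
        pending <- c(requeue, pending)
        unacked[w] <- 0L
        next
      }
      value <- process(chunks[[chunk_id]])
      if (!queue_put(res[[w]], list(chunk_id = chunk_id, value = value,
                                    worker = w))) {
        drain(w)  # response queue full: host must drain before worker proceeds
        queue_put(res[[w]], list(chunk_id = chunk_id, value = value,
                                 worker = w))
      }
      completed[w] <- completed[w] + 1L
    }
    # host: drain all responses
    for (w in seq_len(n_workers)) drain(w)
    if (n_done < n && !dispatched_any)
      stop("pipeline deadlock: no progress with ",
           n - n_done, " chunks outstanding")
  }
  stats <- list(
    enqueued = sum(vapply(c(req, res), function(q) q$enqueued, 0L)),
    dequeued = sum(vapply(c(req, res), function(q) q$dequeued, 0L)),
    per_queue = data.frame(
      queue = c(sprintf("req%d", seq_len(n_workers)),
                sprintf("res%d", seq_len(n_workers))),
      enqueued = vapply(c(req, res), function(q) q$enqueued, 0L),
      dequeued = vapply(c(req, res), function(q) q$dequeued, 0L)
    ),
    max_in_flight = max_unacked,
    completed = completed
  )
  list(results = results, stats = stats)
}

#' Merge per-chunk PSM lists into the final report order
#'
#' Concatenates the ranked PSM frames of all chunks and sorts by spectrum
#' source order, then rank — independent of chunk arrival order. Duplicate
#' (spectrum_id, rank) pairs indicate overlapping chunks and raise an
#' error.
#'
#' @param per_chunk_results list of PSM data.frames.
#' @return One PSM data.frame in deterministic global order.
#' @export
merge_results <- function(per_chunk_results) {
  per_chunk_results <- Filter(function(x) !is.null(x) && nrow(x) > 0L,
                              per_chunk_results)
  if (length(per_chunk_results) == 0L)
    return(finalize_psms(empty_psm_df(),
                         list(spectrum_id = character(0), precursor_mz = 0,
                              precursor_charge = 1L,
                              source_index = integer(0)))[0, ])
  all <- do.call(rbind, per_chunk_results)
  key <- paste(all$spectrum_id, all$rank, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (spectrum_id, rank) across chunks: overlapping chunks?")
  all <- all[order(all$source_index, all$rank), , drop = FALSE]
  rownames(all) <- NULL
  all
}

# Split 1..n into contiguous chunks of about `target` spectra.
make_chunks <- function(n, target) {
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = target)
  lapply(starts, function(s) seq.int(s, min(s + target - 1L, n)))
}

#' Run a full database search
#'
#' The four-phase pipeline: (1) load inputs and partition the spectra into
#' chunks; (2) build the mass-sorted peptide index and retrieve each
#' spectrum's precursor candidate window (the unrefined search); (3) score
#' every chunk through the worker pool, each spectrum against its
#' candidates with the configured algorithm, chunks travelling through
#' bounded request/response queues; (4) merge per-chunk results and write
#' the TSV report. Output is identical for any worker count.
#'
#' @param fasta_path protein database (FASTA).
#' @param mgf_path spectra (MGF).
#' @param out_path output TSV report.
#' @param config a [search_config()].
#' @return Invisibly, the merged PSM data.frame.
#' @export
run_search <- function(fasta_path, mgf_path, out_path, config = search_config()) {
  phase <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (file.exists(out_path)) unlink(out_path)
      stop("[phase: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  t0 <- proc.time()[["elapsed"]]
  log_phase <- function(name)
    message(sprintf("[%s] t=%.2fs", name, proc.time()[["elapsed"]] - t0))

  # phase 1: load + partition
  loaded <- phase("load/partition", {
    proteins <- read_fasta(fasta_path)
    spectra <- read_mgf(mgf_path, default_charge = config$default_charge)
    chunks <- make_chunks(length(spectra), chunk_target(config, length(spectra)))
    list(proteins = proteins, spectra = spectra, chunks = chunks)
  })
  log_phase("partition")

  # phase 2: index + unrefined (precursor window) search
  index <- phase("index/unrefined-search", {
    idx <- build_peptide_index(loaded$proteins, config)
    idx
  })
  log_phase("unrefined-search")

  # phase 3: per-chunk SDP scoring through the worker pool
  scored <- phase("scoring", {
    process <- function(spec_ids) {
      parts <- lapply(loaded$spectra[spec_ids], score_spectrum,
                      index = index, config = config)
      do.call(rbind, parts)
    }
    pipelined_transfer(loaded$chunks, config$n_workers, process,
                       capacity = config$queue_capacity)
  })
  log_phase("scoring")

  # phase 4: sort/merge + report
  merged <- phase("merge/report", {
    m <- merge_results(lapply(scored$results, `[[`, "value"))
    write_psm_report(m, out_path)
    m
  })
  log_phase("merge")
  invisible(merged)
}

# Chunk size: small enough that every worker's queues stay busy, large
# enough to amortize dispatch; bounded below by 1.
chunk_target <- function(config, n_spectra) {
  max(1L, min(16L, ceiling(n_spectra / (4L * config$n_workers))))
}
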