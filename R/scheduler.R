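# Dynamic feedback task scheduling: performance factors, proportional chunk
# partitioning, and the rebalancing loop that keeps the load imbalance of a
# heterogeneous worker pool below a threshold.

#' Memory utilization from meminfo-style counters
#'
#' `(MT - MF - Buffers - Cached) / MT`: the fraction of total memory that is
#' actually used, counting neither free memory nor reclaimable file cache
#' and block-device buffers. On Linux the four inputs come from
#' `/proc/meminfo`; tests and simulations supply them directly.
#'
#' @param MT total memory (> 0).
#' @param MF free memory.
#' @param Buffers block-device buffers.
#' @param Cached file cache.
#' @return Fraction in \[0, 1\].
#' @examples
#' mem_usage(100, 20, 10, 10)  # 0.6
#' @export
mem_usage <- function(MT, MF, Buffers, Cached) {
  if (MT <= 0) stop("MT must be positive")
  if (MF < 0 || Buffers < 0 || Cached < 0) stop("memory components must be >= 0")
  if (MF + Buffers + Cached > MT)
    stop("free + buffers + cached exceed total memory")
  (MT - MF - Buffers - Cached) / MT
}

#' Worker performance factor
#'
#' A worker's composite load descriptor: CPU utilization, average run-queue
#' length per core, memory usage (see [mem_usage()]) and the throughput
#' estimated by a sample probe.
#'
#' @param worker_id worker identifier.
#' @param cpu_utilization fraction in \[0, 1\].
#' @param avg_queue_length non-negative run-queue length per core.
#' @param mem_usage fraction in \[0, 1\].
#' @param throughput_estimate spectra per second, > 0 for a live worker.
#' @param alive logical; dead workers are excluded from partitioning.
#' @return A `performance_factor` object.
#' @export
performance_factor <- function(worker_id, cpu_utilization, avg_queue_length,
                               mem_usage, throughput_estimate, alive = TRUE) {
  stopifnot(cpu_utilization >= 0, cpu_utilization <= 1,
            avg_queue_length >= 0, mem_usage >= 0, mem_usage <= 1)
  if (alive && throughput_estimate <= 0)
    stop("live worker must have positive throughput")
  structure(list(worker_id = worker_id,
                 cpu_utilization = cpu_utilization,
                 avg_queue_length = avg_queue_length,
                 mem_usage = mem_usage,
                 throughput_estimate = throughput_estimate,
                 alive = alive),
            class = "performance_factor")
}

#' Simulated worker model
#'
#' Abstracts a computing node so the scheduler is testable without
#' hardware: `speed_factor` is the worker's relative throughput and the
#' load statistics are drawn from a seeded simulation instead of `/proc`.
#'
#' @param worker_id identifier.
#' @param speed_factor relative throughput, > 0.
#' @param cpu_utilization,avg_queue_length,mem_usage simulated load stats.
#' @param alive logical.
#' @return A `worker_model` object.
#' @export
worker_model <- function(worker_id, speed_factor = 1,
                         cpu_utilization = 0.5, avg_queue_length = 0.5,
                         mem_usage = 0.3, alive = TRUE) {
  stopifnot(speed_factor > 0)
  structure(list(worker_id = worker_id, speed_factor = speed_factor,
                 cpu_utilization = cpu_utilization,
                 avg_queue_length = avg_queue_length,
                 mem_usage = mem_usage, alive = alive),
            class = "worker_model")
}

#' Probe a worker's performance
#'
#' Runs (or simulates) a small sample batch on the worker and reports its
#' performance factor: throughput is probe size over measured processing
#' time, and the load statistics come from the worker's source. A dead
#' worker is returned flagged `alive = FALSE` so partitioning skips it.
#'
#' @param worker a [worker_model()].
#' @param probe_size number of probe spectra (> 0).
#' @param jitter_sigma lognormal sigma of the simulated timing noise.
#' @param seed integer seed making the probe reproducible.
#' @return A [performance_factor()].
#' @export
sample_probe <- function(worker, probe_size = 10L, jitter_sigma = 0.05,
                         seed = 1L) {
  stopifnot(probe_size > 0)
  if (!worker$alive)
    return(performance_factor(worker$worker_id, 0, 0, 0, 0, alive = FALSE))
  noise <- local({
    set.seed(as.integer(seed))
    stats::rlnorm(1L, meanlog = 0, sdlog = jitter_sigma)
  })
  elapsed <- probe_size / worker$speed_factor * noise
  performance_factor(worker$worker_id,
                     cpu_utilization = worker$cpu_utilization,
                     avg_queue_length = worker$avg_queue_length,
                     mem_usage = worker$mem_usage,
                     throughput_estimate = probe_size / elapsed)
}

#' Probe the host's live load statistics
#'
#' Optional plumbing: reads `/proc/meminfo` and `/proc/loadavg` when
#' available (Linux) and returns a [performance_factor()] for the host,
#' with a nominal throughput of 1. On systems without `/proc` the
#' simulated defaults are returned. All scheduling tests use simulated
#' workers; this exists for the command-line `probe` subcommand.
#'
#' @param worker_id identifier for the host (default `"host"`).
#' @return A [performance_factor()].
#' @export
host_performance_factor <- function(worker_id = "host") {
  mu <- 0.3; ql <- 0.5
  if (file.exists("/proc/meminfo")) {
    mi <- readLines("/proc/meminfo")
    grab <- function(key) {
      ln <- grep(paste0("^", key, ":"), mi, value = TRUE)
      if (length(ln) == 0L) return(NA_real_)
      as.numeric(strsplit(trimws(sub("^[^:]+:", "", ln[1L])), "\\s+")[[1L]][1L])
    }
    mt <- grab("MemTotal"); mf <- grab("MemFree")
    bu <- grab("Buffers"); ca <- grab("Cached")
    if (!anyNA(c(mt, mf, bu, ca)) && mt > 0 && mf + bu + ca <= mt)
      mu <- mem_usage(mt, mf, bu, ca)
  }
  if (file.exists("/proc/loadavg")) {
    la <- suppressWarnings(
      as.numeric(strsplit(readLines("/proc/loadavg")[1L], "\\s+")[[1L]][1L]))
    ncores <- max(1L, parallel_cores())
    if (!is.na(la)) ql <- la / ncores
  }
  performance_factor(worker_id, cpu_utilization = 0.5,
                     avg_queue_length = ql, mem_usage = min(max(mu, 0), 1),
                     throughput_estimate = 1)
}

parallel_cores <- function() {
  n <- tryCatch(as.integer(Sys.getenv("NUMBER_OF_PROCESSORS", "")),
                warning = function(w) NA_integer_)
  if (!is.na(n) && n > 0L) return(n)
  if (file.exists("/proc/cpuinfo"))
    return(sum(grepl("^processor", readLines("/proc/cpuinfo"))))
  1L
}

# Effective scheduling weight: probe throughput, penalized when the worker
# is already overloaded (CPU above 90%): scaled by free-memory fraction and
# divided by (1 + run-queue length).
effective_weight <- function(f) {
  if (!f$alive) return(0)
  w <- f$throughput_estimate
  if (f$cpu_utilization > 0.9)
    w <- w * (1 - f$mem_usage) / (1 + f$avg_queue_length)
  w
}

# Largest-remainder apportionment of `total` items to `weights`, ties on
# fractional part broken by position (worker order).
apportion <- function(total, weights) {
  if (total == 0L) return(integer(length(weights)))
  if (all(weights <= 0)) stop("no live workers with positive weight")
  share <- total * weights / sum(weights)
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0L) {
    frac <- share - base
    extra <- order(-frac, seq_along(weights))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Partition spectra into per-worker chunks
#'
#' Splits `spectra_count` spectra into contiguous, disjoint, order-
#' preserving ranges with sizes proportional to each live worker's
#' effective weight (probe throughput with an overload penalty). Rounding
#' distributes the remainder by largest fractional part, then worker order.
#'
#' @param spectra_count number of spectra (>= 0).
#' @param factors list of [performance_factor()] objects.
#' @return data.frame with `chunk_id`, `worker_id`, `from`, `to`, `size`
#'   (1-based inclusive ranges; zero-size chunks omitted).
#' @export
partition <- function(spectra_count, factors) {
  stopifnot(spectra_count >= 0)
  live <- Filter(function(f) f$alive, factors)
  if (length(live) == 0L) stop("no live workers")
  if (spectra_count == 0L)
    return(data.frame(chunk_id = integer(), worker_id = character(),
                      from = integer(), to = integer(), size = integer(),
                      stringsAsFactors = FALSE))
  weights <- vapply(live, effective_weight, 0)
  sizes <- apportion(as.integer(spectra_count), weights)
  keep <- sizes > 0L
  starts <- cumsum(c(1L, sizes))[seq_along(sizes)]
  data.frame(
    chunk_id = seq_len(sum(keep)),
    worker_id = vapply(live, `[[`, "", "worker_id")[keep],
    from = starts[keep],
    to = (starts + sizes - 1L)[keep],
    size = sizes[keep],
    stringsAsFactors = FALSE
  )
}

#' Load imbalance of completed work
#'
#' `(max - mean) / mean` over per-worker busy totals: 0 when all workers
#' did equal work, and by convention 0 when all totals are zero.
#'
#' @param completion_loads numeric vector of per-worker busy totals (>= 0).
#' @return Non-negative fraction.
#' @examples
#' load_imbalance(c(12, 10, 8))  # 0.2
#' @export
load_imbalance <- function(completion_loads) {
  if (length(completion_loads) == 0L) stop("need at least one worker")
  if (any(completion_loads < 0)) stop("loads must be >= 0")
  m <- mean(completion_loads)
  if (m == 0) return(0)
  (max(completion_loads) - m) / m
}

# ---- feedback scheduling simulation ------------------------------------

new_schedule_state <- function(workload, weights) {
  n_workers <- nrow(workload$workers)
  sizes <- apportion(length(workload$chunk_costs), weights)
  starts <- cumsum(c(1L, sizes))[seq_len(n_workers)]
  queues <- lapply(seq_len(n_workers), function(w)
    if (sizes[w] > 0L) seq.int(starts[w], starts[w] + sizes[w] - 1L)
    else integer())
  list(workload = workload, weights = weights, queues = queues,
       busy = numeric(n_workers), done = logical(length(workload$chunk_costs)),
       started = logical(length(workload$chunk_costs)))
}

#' One feedback-rebalance step
#'
#' Applies the scheduler's correction to a schedule state: worker weights
#' are geometrically smoothed toward the observed processing rates
#' (`w <- alpha * w + (1 - alpha) * w_observed`), and while the projected
#' finish times are imbalanced beyond `threshold`, unstarted chunks are
#' moved from the worker projected to finish last to the one projected to
#' finish first. Started chunks are never reassigned.
#'
#' @param state schedule state (see [simulate_schedule()]).
#' @param alpha geometric smoothing coefficient in \[0, 1\]; `alpha = 1`
#'   freezes the weights.
#' @param threshold projected-imbalance tolerance.
#' @return Updated state.
#' @export
feedback_rebalance <- function(state, alpha = 0.5, threshold = 0.08) {
  costs <- state$workload$chunk_costs
  speeds <- state$workload$workers$speed_factor
  # observed rate: work completed per unit busy time
  for (w in seq_along(state$queues)) {
    if (state$busy[w] > 0) {
      done_w <- state$done_cost[w]
      obs <- done_w / state$busy[w]
      state$weights[w] <- alpha * state$weights[w] + (1 - alpha) * obs
    }
  }
  repeat {
    remaining <- vapply(state$queues, function(q) sum(costs[q]), 0)
    projected <- state$busy + remaining / pmax(state$weights, 1e-12)
    m <- mean(projected)
    if (m == 0 || (max(projected) - m) / m <= threshold) break
    donor <- which.max(projected)
    movable <- state$queues[[donor]]
    movable <- movable[!state$started[movable]]
    if (length(movable) == 0L) break
    recipient <- which.min(projected)
    if (recipient == donor) break
    chunk <- movable[length(movable)]
    state$queues[[donor]] <- setdiff(state$queues[[donor]], chunk)
    state$queues[[recipient]] <- c(state$queues[[recipient]], chunk)
  }
  state
}

#' Simulate a dynamic-feedback scheduling run
#'
#' Event-driven simulation of the full scheduling loop on a synthetic
#' workload (see [make_schedule_workload()]): a sample probe estimates each
#' worker's throughput, chunks are partitioned proportionally, and at every
#' chunk-completion report the feedback step smooths the weights and
#' migrates unstarted chunks away from workers projected to finish late.
#'
#' @param workload a workload from [make_schedule_workload()].
#' @param alpha geometric smoothing coefficient (default 0.5).
#' @param threshold imbalance target (default 0.08).
#' @param feedback logical; `FALSE` runs the initial static assignment with
#'   no rebalancing (for comparison).
#' @param probe_seed seed for the probe noise.
#' @return list with `busy` (per-worker busy totals), `imbalance`
#'   (final [load_imbalance()]), `weights`, and `completed` (chunk count).
#' @export
simulate_schedule <- function(workload, alpha = 0.5, threshold = 0.08,
                              feedback = TRUE, probe_seed = 1L) {
  workers <- workload$workers
  factors <- lapply(seq_len(nrow(workers)), function(i)
    sample_probe(worker_model(workers$worker_id[i], workers$speed_factor[i]),
                 seed = probe_seed + i))
  weights <- vapply(factors, effective_weight, 0)
  state <- new_schedule_state(workload, weights)
  state$done_cost <- numeric(nrow(workers))
  costs <- workload$chunk_costs
  speeds <- workers$speed_factor
  while (any(vapply(state$queues, length, 0L) > 0L)) {
    # every active worker's head chunk is in flight: mark it started so the
    # feedback step can never migrate it
    active <- which(vapply(state$queues, length, 0L) > 0L)
    for (a in active) state$started[state$queues[[a]][1L]] <- TRUE
    finish <- vapply(active, function(w)
      state$busy[w] + costs[state$queues[[w]][1L]] / speeds[w], 0)
    w <- active[which.min(finish)]
    chunk <- state$queues[[w]][1L]
    state$queues[[w]] <- state$queues[[w]][-1L]
    state$busy[w] <- state$busy[w] + costs[chunk] / speeds[w]
    state$done[chunk] <- TRUE
    state$done_cost[w] <- state$done_cost[w] + costs[chunk]
    if (feedback)
      state <- feedback_rebalance(state, alpha = alpha, threshold = threshold)
  }
  list(busy = state$busy, imbalance = load_imbalance(state$busy),
       weights = state$weights, completed = sum(state$done))
}
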