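test_that("memory utilization follows the meminfo formula with guards", {
  expect_equal(mem_usage(100, 20, 10, 10), 0.6)
  expect_equal(mem_usage(100, 100, 0, 0), 0)       # fully free
  expect_error(mem_usage(0, 0, 0, 0), "positive")
  expect_error(mem_usage(-5, 0, 0, 0), "positive")
  expect_error(mem_usage(100, 90, 10, 10), "exceed")
  expect_error(mem_usage(100, -1, 0, 0), ">= 0")
})

test_that("sample probes reflect relative speeds deterministically", {
  w2 <- worker_model("fast", speed_factor = 2)
  w1 <- worker_model("slow", speed_factor = 1)
  f2 <- sample_probe(w2, probe_size = 10, seed = 5)
  f1 <- sample_probe(w1, probe_size = 10, seed = 5)
  expect_equal(f2$throughput_estimate / f1$throughput_estimate, 2,
               tolerance = 1e-9)   # same seed, same noise: exact ratio
  expect_identical(sample_probe(w1, seed = 7), sample_probe(w1, seed = 7))
  dead <- sample_probe(worker_model("gone", alive = FALSE))
  expect_false(dead$alive)
})

test_that("partition is proportional, conservative and excludes dead workers", {
  pf <- function(id, thr, alive = TRUE)
    performance_factor(id, 0.5, 0.5, 0.3, thr, alive = alive)
  eq4 <- lapply(1:4, function(i) pf(paste0("w", i), 1))
  p <- partition(100, eq4)
  expect_equal(p$size, rep(25L, 4))
  p2 <- partition(90, list(pf("a", 2), pf("b", 1)))
  expect_equal(p2$size, c(60L, 30L))
  expect_equal(nrow(partition(0, eq4)), 0L)
  expect_error(partition(10, list(pf("x", 0, alive = FALSE))), "no live")
  # dead worker excluded; the rest cover everything
  p3 <- partition(50, list(pf("a", 1), pf("dead", 0, alive = FALSE), pf("c", 1)))
  expect_equal(sum(p3$size), 50L)
  expect_false("dead" %in% p3$worker_id)
  # chunks partition the range: disjoint, complete, order-preserving
  covered <- unlist(lapply(seq_len(nrow(p3)), function(i)
    seq.int(p3$from[i], p3$to[i])))
  expect_equal(covered, 1:50)
})

test_that("partition is scale-invariant in the weights (property)", {
  set.seed(21)
  for (i in 1:20) {
    thr <- stats::runif(4, 0.1, 5)
    fs <- lapply(1:4, function(j)
      performance_factor(paste0("w", j), 0.5, 0.5, 0.3, thr[j]))
    fs_scaled <- lapply(1:4, function(j)
      performance_factor(paste0("w", j), 0.5, 0.5, 0.3, thr[j] * 17.3))
    n <- sample(10:500, 1)
    expect_identical(partition(n, fs), partition(n, fs_scaled))
    expect_equal(sum(partition(n, fs)$size), n)
  }
})

test_that("overloaded workers are penalized in the effective weight", {
  calm <- performance_factor("a", cpu_utilization = 0.5, avg_queue_length = 3,
                             mem_usage = 0.8, throughput_estimate = 1)
  hot <- performance_factor("b", cpu_utilization = 0.95, avg_queue_length = 3,
                            mem_usage = 0.8, throughput_estimate = 1)
  p <- partition(100, list(calm, hot))
  expect_gt(p$size[p$worker_id == "a"], p$size[p$worker_id == "b"])
})

test_that("load imbalance matches (max - mean) / mean", {
  expect_equal(load_imbalance(c(10, 10, 10)), 0)
  expect_equal(load_imbalance(c(12, 10, 8)), 0.2)
  expect_equal(load_imbalance(42), 0)            # single worker
  expect_equal(load_imbalance(c(0, 0)), 0)       # all-zero convention
  expect_error(load_imbalance(numeric()), "at least one")
  expect_error(load_imbalance(c(-1, 2)), ">= 0")
})

test_that("feedback rebalancing fixes imbalance and respects started chunks", {
  wl <- make_schedule_workload(60, c(1, 1), seed = 2, jitter_sigma = 0)
  st <- sdpsearch:::new_schedule_state(wl, weights = c(1, 1))
  st$done_cost <- c(0, 0)
  # balanced state is a fixed point
  st2 <- feedback_rebalance(st, alpha = 0.5, threshold = 0.08)
  expect_identical(st2$queues, st$queues)
  # alpha = 1 freezes weights even with observations
  st$busy <- c(10, 10); st$done_cost <- c(30, 5)
  stf <- feedback_rebalance(st, alpha = 1, threshold = 1e9)
  expect_equal(stf$weights, st$weights)
  # a slowed worker sheds unstarted chunks
  wl3 <- make_schedule_workload(100, c(1, 1), seed = 3, jitter_sigma = 0)
  st3 <- sdpsearch:::new_schedule_state(wl3, weights = c(1, 1))
  st3$done_cost <- c(10, 10); st3$busy <- c(40, 10)  # worker 1 is 4x slower
  st3$weights <- c(0.25, 1)
  before <- length(st3$queues[[1]])
  st3$started[st3$queues[[1]][1]] <- TRUE
  st4 <- feedback_rebalance(st3, alpha = 1, threshold = 0.08)
  expect_lt(length(st4$queues[[1]]), before)
  expect_true(st3$queues[[1]][1] %in% st4$queues[[1]])  # started chunk stays
})

test_that("simulated heterogeneous runs finish well balanced", {
  wl <- make_schedule_workload(300, c(1, 1.5, 2), seed = 4)
  r <- simulate_schedule(wl, probe_seed = 4)
  expect_equal(r$completed, 300L)
  expect_lte(r$imbalance, 0.08)
  # without feedback the static split on noisy estimates is typically worse
  r0 <- simulate_schedule(wl, feedback = FALSE, probe_seed = 4)
  expect_gte(r0$imbalance, r$imbalance)
})

test_that("host probe returns a valid performance factor", {
  f <- host_performance_factor()
  expect_s3_class(f, "performance_factor")
  expect_gte(f$mem_usage, 0); expect_lte(f$mem_usage, 1)
  expect_gte(f$avg_queue_length, 0)
})
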