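# Event reading, density gating and size-conditioned medians.

make_events <- function(FSC, SSC = FSC, FL1 = FSC, ...) {
  df <- data.frame(FSC = FSC, SSC = SSC, FL1 = FL1)
  class(df) <- c("event_table", "data.frame")
  df
}

test_that("CSV round trip preserves events and metadata", {
  tr <- gate_truth("PhlF-P1", 0.05, 3, 0.1, 3)
  ev <- simulate_events(tr, default_sensor(), 50, n_events = 3,
                        noise = noise_model(), seed = 1, context_label = "pAN:EcDH5a")
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$FL1, ev$FL1, tolerance = 1e-12)
  expect_equal(attr(back, "gate"), "PhlF-P1")
  expect_equal(attr(back, "iptg_uM"), 50)
  unlink(c(path, paste0(path, ".json")))
})

test_that("missing channel columns raise a format error naming the channel", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(FSC = 1:3, SSC = 1:3), path, row.names = FALSE)
  expect_error(read_events(path), "FL1")
  write.csv(data.frame(x = numeric(0), FSC = numeric(0), SSC = numeric(0),
                       FL1 = numeric(0)), path, row.names = FALSE)
  expect_error(read_events(path), "no events")
  unlink(path)
})

test_that("density gating retains the requested coverage from the densest region", {
  set.seed(42)
  n <- 5000
  ev <- make_events(FSC = exp(rnorm(n, log(5e4), 0.3)),
                    SSC = exp(rnorm(n, log(3e4), 0.3)),
                    FL1 = rnorm(n, 1000, 10))
  all_kept <- scatter_gate(ev, coverage = 1)
  expect_equal(nrow(all_kept), n)

  g <- scatter_gate(ev, coverage = 0.5)
  frac <- nrow(g) / n
  expect_gte(frac, 0.5)
  expect_lte(frac, 1)
  expect_lte(diff(range(g$FSC)), diff(range(ev$FSC)))
  expect_lte(sd(g$FSC), sd(ev$FSC))

  expect_error(scatter_gate(ev[0, ], coverage = 0.5), "empty")
})

test_that("gating on two well-separated clusters keeps only the dense one", {
  set.seed(7)
  n_dense <- 700; n_sparse <- 300
  dense <- cbind(rnorm(n_dense, 100, 2), rnorm(n_dense, 100, 2))
  sparse <- cbind(rnorm(n_sparse, 1000, 2), rnorm(n_sparse, 1000, 2))
  ev <- make_events(FSC = c(dense[, 1], sparse[, 1]),
                    SSC = c(dense[, 2], sparse[, 2]),
                    FL1 = rep(1, n_dense + n_sparse))
  g <- scatter_gate(ev, coverage = 0.5)
  expect_true(all(g$FSC < 500))  # every retained event from the 70% cluster
})

test_that("scatter reference is the pooled histogram mode", {
  expect_equal(choose_scatter_reference(make_events(rep(5, 10))), 5)

  set.seed(11)
  pooled <- exp(rnorm(20000, log(5e4), 0.3))
  samples <- list(make_events(pooled[1:10000]), make_events(pooled[10001:20000]))
  ref <- choose_scatter_reference(samples, bins = 100)
  # histogram oracle: recompute the modal bin directly
  h <- hist(pooled, breaks = seq(min(pooled), max(pooled), length.out = 101),
            plot = FALSE)
  i <- which.max(h$counts)
  expect_gte(ref, h$breaks[i])
  expect_lte(ref, h$breaks[i + 1])

  # two samples with disjoint ranges: reference lies in the denser one
  a <- make_events(runif(9000, 0, 10))
  b <- make_events(runif(1000, 100, 110))
  expect_lt(choose_scatter_reference(list(a, b)), 10.01)

  expect_error(choose_scatter_reference(list()), "no samples")
})

test_that("size-conditioned median works on a constructed linear coupling", {
  set.seed(3)
  FSC <- runif(5000, 5, 15)
  ev <- make_events(FSC = FSC, SSC = FSC, FL1 = 2 * FSC)
  s <- size_conditioned_median(ev, scatter_reference = 10,
                               window_halfwidth = 0.5, min_events = 10)
  expect_equal(s$median_fluorescence, 20, tolerance = 0.06)
  expect_lte(s$n_events_used, 5000)

  # infinite window degenerates to the plain median
  s_inf <- size_conditioned_median(ev)
  expect_equal(s_inf$median_fluorescence, median(ev$FL1))
  expect_equal(s_inf$gating_coverage, 1)

  expect_error(
    size_conditioned_median(ev, scatter_reference = 10,
                            window_halfwidth = 1e-5, min_events = 100),
    "widen the window")
})

test_that("size-conditioned median is invariant to event order", {
  set.seed(5)
  ev <- make_events(FSC = runif(2000, 5, 15), FL1 = rnorm(2000, 50, 5))
  ev$SSC <- ev$FSC
  perm <- ev[sample(nrow(ev)), ]
  class(perm) <- c("event_table", "data.frame")
  s1 <- size_conditioned_median(ev, 10, 2, min_events = 10)
  s2 <- size_conditioned_median(perm, 10, 2, min_events = 10)
  expect_equal(s1$median_fluorescence, s2$median_fluorescence)
})

test_that("conditioning on a common scatter window removes cell-size shifts", {
  # same construct measured on days with different cell sizes: plain medians
  # drift with scatter, size-conditioned medians do not
  tr <- gate_truth("AmtR-A1", 0.1, 2, 0.1, 3)
  sensor <- default_sensor()
  sizes <- c(3.5e4, 5e4, 7e4)
  samples <- lapply(seq_along(sizes), function(i) {
    nm <- noise_model(sigma_lognormal = 0.05, scatter_mean = sizes[i],
                      scatter_sigma = 0.3, size_coupling = 1)
    simulate_events(tr, sensor, 0, n_events = 20000, noise = nm, seed = i)
  })
  ref <- choose_scatter_reference(samples)
  plain <- vapply(samples, function(s) size_conditioned_median(s)$median_fluorescence, 0)
  cond <- vapply(samples, function(s)
    size_conditioned_median(s, ref, window_halfwidth = 0.05 * ref,
                            min_events = 50)$median_fluorescence, 0)
  rel_sd <- function(v) sd(v) / mean(v)
  expect_lt(rel_sd(cond), rel_sd(plain))
})
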