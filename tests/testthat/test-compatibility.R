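# Compatibility scoring and discrete-Frechet shape similarity.

fake_thresholds <- function(OL, OH, IL, IH) {
  structure(list(OL = OL, OH = OH, IL = IL, IH = IH, operational = TRUE),
            class = "thresholds")
}

fake_fit_row <- function(gate, backbone = "pAN", host = "EcDH5a",
                         OL, OH, IL, IH, operational = TRUE,
                         family = sub("-.*$", "", gate)) {
  data.frame(gate = gate, repressor_family = family, backbone = backbone,
             host = host, ymin = OL / 2, ymax = OH * 2, k = 1, n = 2,
             residual = 0, converged = TRUE, OL = OL, OH = OH, IL = IL,
             IH = IH, operational = operational)
}

test_that("compatibility score matches hand evaluation and strict positivity", {
  a <- fake_thresholds(OL = 0.2, OH = 1.0, IL = 0.5, IH = 0.8)
  b <- fake_thresholds(OL = 0.1, OH = 0.9, IL = 0.3, IH = 0.9)
  s <- compatibility_score(a, b)
  expect_equal(s$score, min(log(0.3 / 0.2), log(1.0 / 0.9)))  # ~0.1054
  expect_true(s$compatible)

  b0 <- fake_thresholds(OL = 0.1, OH = 0.9, IL = 0.2, IH = 1.0)
  s0 <- compatibility_score(a, b0)
  expect_equal(s0$score, 0)
  expect_false(s0$compatible)  # zero score excluded

  bneg <- fake_thresholds(OL = 0.1, OH = 0.9, IL = 0.1, IH = 0.9)
  sneg <- compatibility_score(a, bneg)
  expect_equal(sneg$score, log(0.1 / 0.2))  # min(-0.693, 0.105)
  expect_false(sneg$compatible)

  bad <- structure(list(OL = 1, OH = 1, IL = NA, IH = NA, operational = FALSE),
                   class = "thresholds")
  expect_error(compatibility_score(a, bad), "operational")
})

test_that("the pair matrix matches exhaustive pairwise scoring", {
  # engineered so exactly A -> B and B -> C are compatible
  fits <- rbind(
    fake_fit_row("AmtR-A1", OL = 0.10, OH = 2.00, IL = 0.30, IH = 1.50),
    fake_fit_row("BetI-B1", OL = 0.05, OH = 1.00, IL = 0.30, IH = 1.50),
    fake_fit_row("LitR-L1", OL = 0.50, OH = 3.00, IL = 0.08, IH = 0.90)
  )
  cm <- compatibility_matrix(fits)
  expect_equal(cm$n_compatible, 2)
  # oracle: score every ordered pair directly
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    s <- compatibility_score(
      fake_thresholds(fits$OL[i], fits$OH[i], fits$IL[i], fits$IH[i]),
      fake_thresholds(fits$OL[j], fits$OH[j], fits$IL[j], fits$IH[j]))
    expect_equal(unname(cm$compatible[i, j]), as.integer(s$compatible))
    expect_equal(unname(cm$score[i, j]),
                 min(log(fits$IL[j] / fits$OL[i]), log(fits$OH[i] / fits$IH[j])))
  }
  expect_equal(compatibility_matrix(fits[1, , drop = FALSE])$n_compatible, 0)
})

test_that("same-repressor pairs are excluded when the policy is on", {
  fits <- rbind(
    fake_fit_row("PhlF-P1", OL = 0.10, OH = 2.00, IL = 0.30, IH = 1.50),
    fake_fit_row("PhlF-P2", backbone = "pSEVA221",
                 OL = 0.05, OH = 1.00, IL = 0.30, IH = 1.50)
  )
  expect_equal(compatibility_matrix(fits)$n_compatible, 0)
  expect_equal(compatibility_matrix(fits, exclude_same_repressor = FALSE)$n_compatible, 1)
})

test_that("relaxing a context filter never loses compatible pairs", {
  lib <- make_library(12, seed = 5, heterogeneity = 0.2)
  fits <- truth_fits(lib)
  restricted <- compatibility_matrix(fits, context_filter = function(r)
    r$host == "EcDH5a")$n_compatible
  full <- compatibility_matrix(fits)$n_compatible
  expect_lte(restricted, full)
})

test_that("discrete Frechet DP agrees with exhaustive coupling enumeration", {
  p <- rbind(c(0, 0), c(1, 0))
  expect_equal(discrete_frechet(p, p), 0)
  expect_equal(discrete_frechet(p, rbind(c(0, 1), c(1, 1))), 1.0)
  expect_equal(discrete_frechet(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 0))), 1.0)

  set.seed(9)
  for (i in 1:40) {
    a <- matrix(runif(2 * sample(1:6, 1)), ncol = 2)
    b <- matrix(runif(2 * sample(1:6, 1)), ncol = 2)
    expect_equal(discrete_frechet(a, b), brute_frechet(a, b), tolerance = 1e-12)
    expect_equal(discrete_frechet(a, b), discrete_frechet(b, a))  # symmetry
  }
  expect_error(discrete_frechet(matrix(numeric(0), ncol = 2), p), "non-empty")
})

test_that("similarity is shape-only under per-curve normalization", {
  gc <- gate_context("PhlF-P1", "pAN", "EcDH5a")
  x <- exp(seq(log(0.01), log(3), length.out = 10))
  a <- characterization(gc, x, hill_eval(list(ymin = 0.1, ymax = 2, k = 0.3, n = 2.5), x))
  expect_equal(curve_similarity(a, a)$similarity, 1)

  # both axes scaled by 10: identical shape in log space
  b <- characterization(gc, 10 * x, 10 * a$points$output_rpu)
  expect_equal(curve_similarity(a, b)$similarity, 1, tolerance = 1e-12)
  # under joint normalization the scale difference does count
  expect_lt(curve_similarity(a, b, joint_normalization = TRUE)$similarity, 1)

  # a step-like curve is less similar to a shallow one than to its own shape
  steep <- characterization(gc, x, hill_eval(list(ymin = 0.1, ymax = 2, k = 0.3, n = 6), x))
  steep2 <- characterization(gc, 3 * x, 3 * steep$points$output_rpu)
  shallow <- characterization(gc, x, hill_eval(list(ymin = 0.1, ymax = 2, k = 0.3, n = 0.7), x))
  expect_lt(curve_similarity(steep, shallow)$similarity,
            curve_similarity(steep, steep2)$similarity)

  flat <- characterization(gc, x, rep(0.5, 10))
  expect_error(curve_similarity(a, flat), "degenerate")
  withneg <- characterization(gc, x, c(rep(1, 9), 0))
  expect_error(curve_similarity(a, withneg), "positive")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  lib <- make_library(1, seed = 3, heterogeneity = 0.1)
  chrs <- lapply(viable_truths(lib), truth_characterization)
  m <- similarity_matrix(chrs)
  expect_equal(dim(m), c(7, 7))
  expect_equal(unname(diag(m)), rep(1, 7))
  expect_equal(m, t(m))
  expect_true(all(m <= 1))
})
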