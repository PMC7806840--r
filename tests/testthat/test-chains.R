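# Longest repressor-distinct chains in the compatibility graph.

toy_graph <- function(adj, fams, gates = NULL) {
  n <- nrow(adj)
  if (is.null(gates)) gates <- paste0("G", seq_len(n))
  nodes <- data.frame(gate = gates, repressor_family = fams,
                      backbone = "pAN", host = "EcDH5a")
  dimnames(adj) <- list(paste0(gates, "|pAN|EcDH5a"),
                        paste0(gates, "|pAN|EcDH5a"))
  structure(list(nodes = nodes, adjacency = adj, repressor_of = fams),
            class = "compatibility_graph")
}

test_that("graph construction restricts nodes and uses strict positivity", {
  lib <- make_library(6, seed = 4, heterogeneity = 0.2)
  fits <- truth_fits(lib)
  cm <- compatibility_matrix(fits)
  g_all <- build_graph(cm)
  g_one <- build_graph(cm, context_filter = function(r) r$host == "EcDH5a")
  expect_lt(nrow(g_one$nodes), nrow(g_all$nodes))
  expect_true(all(g_one$nodes$host == "EcDH5a"))
  # adjacency equals the sign oracle on the score matrix (same-family off)
  same_fam <- outer(g_all$nodes$repressor_family, g_all$nodes$repressor_family, "==")
  keep <- rownames(g_all$adjacency)
  oracle <- (cm$score[keep, keep] > 0) & !same_fam
  diag(oracle) <- FALSE
  expect_equal(unname(g_all$adjacency == 1L), unname(oracle))

  expect_error(build_graph(cm, context_filter = function(r) FALSE), "no operational")
})

test_that("edgeless graphs have depth 1 with singleton chains", {
  g <- toy_graph(matrix(0L, 5, 5), paste0("R", 1:5))
  lc <- longest_chains(g)
  expect_equal(lc$max_depth, 1)
  expect_length(lc$chains, 5)
})

test_that("repressor reuse truncates otherwise longer paths", {
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- 1L; adj[2, 3] <- 1L
  g <- toy_graph(adj, c("R1", "R2", "R1"))
  lc <- longest_chains(g)
  expect_equal(lc$max_depth, 2)  # G1-G2-G3 blocked: R1 twice
  got <- lapply(lc$chains, function(ch) sub("\\|.*$", "", ch))
  expect_equal(got, list(c("G1", "G2"), c("G2", "G3")))
})

test_that("a complete 4-clique with distinct repressors yields 4! chains", {
  adj <- matrix(1L, 4, 4); diag(adj) <- 0L
  lc <- longest_chains(toy_graph(adj, paste0("R", 1:4)))
  expect_equal(lc$max_depth, 4)
  expect_length(lc$chains, 24)
})

test_that("DFS equals brute-force enumeration on random small graphs", {
  set.seed(13)
  for (trial in 1:60) {
    n <- sample(2:8, 1)
    adj <- matrix(as.integer(runif(n * n) < 0.35), n, n)
    diag(adj) <- 0L
    fams <- paste0("R", sample(1:5, n, replace = TRUE))
    g <- toy_graph(adj, fams)
    lc <- longest_chains(g)
    oracle <- brute_longest(adj, fams)
    expect_equal(lc$max_depth, oracle$max_depth)
    got <- sort(vapply(lc$chains, function(ch)
      paste(sub("\\|.*$", "", ch), collapse = ">"), ""))
    want <- sort(unique(vapply(oracle$paths, function(p)
      paste(paste0("G", p), collapse = ">"), "")))
    expect_equal(got, want)
  }
})

test_that("max depth never exceeds the number of distinct repressor families", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(4:10, 1)
    n_fam <- sample(2:4, 1)
    adj <- matrix(as.integer(runif(n * n) < 0.7), n, n)
    diag(adj) <- 0L
    fams <- paste0("R", sample(seq_len(n_fam), n, replace = TRUE))
    lc <- longest_chains(toy_graph(adj, fams), enumerate = FALSE)
    expect_lte(lc$max_depth, length(unique(fams)))
  }
})

test_that("adding edges never decreases the maximum depth", {
  set.seed(31)
  n <- 7
  fams <- paste0("R", 1:7)
  adj <- matrix(as.integer(runif(n * n) < 0.2), n, n); diag(adj) <- 0L
  d1 <- longest_chains(toy_graph(adj, fams), enumerate = FALSE)$max_depth
  adj2 <- adj
  adj2[2, 5] <- 1L; adj2[5, 6] <- 1L
  d2 <- longest_chains(toy_graph(adj2, fams), enumerate = FALSE)$max_depth
  expect_gte(d2, d1)
})

test_that("nested context policies give non-decreasing depth", {
  lib <- make_library(20, seed = 1, n_nonviable = 5)
  fits <- truth_fits(lib)
  rep <- depth_by_context_policy(fits, nested_policies())
  expect_true(all(diff(rep$max_depth) >= 0))
  expect_true(all(diff(rep$n_compatible) >= 0))
  expect_error(
    depth_by_context_policy(fits, list(none = function(r) FALSE)),
    "no operational")
})

test_that("a chain engineered across backbones is invisible to a single-backbone policy", {
  # 5 gates whose bands tile only when alternating backbones: within one
  # backbone each gate keeps the same band, so no pair nests
  mk <- function(gate, backbone, OL, OH, IL, IH) {
    data.frame(gate = gate, repressor_family = sub("-.*$", "", gate),
               backbone = backbone, host = "EcDH5a", ymin = OL / 2,
               ymax = OH * 2, k = 1, n = 2, residual = 0, converged = TRUE,
               OL = OL, OH = OH, IL = IL, IH = IH, operational = TRUE)
  }
  fits <- rbind(
    mk("AmtR-A1", "pAN",      OL = 0.10, OH = 4.0, IL = 0.09, IH = 4.5),
    mk("BetI-B1", "pSEVA221", OL = 0.10, OH = 4.0, IL = 0.15, IH = 3.5),
    mk("LitR-L1", "pAN",      OL = 0.20, OH = 3.0, IL = 0.25, IH = 2.5),
    mk("PhlF-P1", "pSEVA221", OL = 0.30, OH = 2.0, IL = 0.35, IH = 1.5),
    mk("QacR-Q1", "pAN",      OL = 0.40, OH = 1.0, IL = 0.45, IH = 0.9),
    # same gates in their other backbone keep their own band (no nesting)
    mk("BetI-B2", "pAN",      OL = 0.10, OH = 4.0, IL = 0.09, IH = 4.5),
    mk("LitR-L2", "pSEVA221", OL = 0.10, OH = 4.0, IL = 0.09, IH = 4.5)
  )
  rep <- depth_by_context_policy(fits, list(
    pan_only = function(r) r$backbone == "pAN",
    mixed = NULL))
  expect_lt(rep$max_depth[rep$policy == "pan_only"], 5)
  expect_equal(rep$max_depth[rep$policy == "mixed"], 5)
  chains <- attr(rep, "chains")$mixed
  expect_true(any(vapply(chains, function(ch)
    identical(sub("\\|.*", "", ch),
              c("AmtR-A1", "BetI-B1", "LitR-L1", "PhlF-P1", "QacR-Q1")), TRUE)))
})

test_that("chain annotations count host switches and group backbones", {
  ann <- annotate_chain(c("A-A1|pAN|EcDH5a", "B-B1|pSEVA221|EcDH5a",
                          "C-C1|pSEVA221|PpKT2440"))
  expect_equal(ann$n_host_switches, 1)
  expect_setequal(ann$backbones_by_host$EcDH5a, c("pAN", "pSEVA221"))
})
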