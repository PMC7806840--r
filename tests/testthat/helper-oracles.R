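# Independent brute-force oracles used to validate the dynamic-programming
# and closed-form implementations. Deliberately naive.

# Discrete Frechet by exhaustive recursion over all monotone couplings:
# from (i, j) the coupling may advance either index or both.
brute_frechet <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  d <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  n <- nrow(p); m <- nrow(q)
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == n && j == m) return(here)
    opts <- c()
    if (i < n) opts <- c(opts, rec(i + 1, j))
    if (j < m) opts <- c(opts, rec(i, j + 1))
    if (i < n && j < m) opts <- c(opts, rec(i + 1, j + 1))
    max(here, min(opts))
  }
  rec(1, 1)
}

# Longest repressor-distinct simple paths by exhaustive path enumeration.
# Returns max depth and all maximal paths (lists of node indices).
brute_longest <- function(adj, fams) {
  n <- nrow(adj)
  best_depth <- 0L
  best_paths <- list()
  extend <- function(path, used_fams) {
    d <- length(path)
    if (d > best_depth) {
      best_depth <<- d
      best_paths <<- list(path)
    } else if (d == best_depth) {
      best_paths[[length(best_paths) + 1L]] <<- path
    }
    last <- path[d]
    for (nb in seq_len(n)) {
      if (adj[last, nb] == 1L && !(fams[nb] %in% used_fams)) {
        extend(c(path, nb), c(used_fams, fams[nb]))
      }
    }
  }
  for (i in seq_len(n)) extend(i, fams[i])
  list(max_depth = best_depth, paths = best_paths)
}

# Root-finding oracle for the input thresholds: solve h(x) = level on a log
# grid bracket (h is strictly decreasing).
root_threshold <- function(ymin, ymax, k, n, level) {
  h <- function(lx) {
    x <- exp(lx)
    ymin + (ymax - ymin) * k^n / (k^n + x^n) - level
  }
  exp(stats::uniroot(h, c(log(k) - 60, log(k) + 60), tol = 1e-13)$root)
}

# Dense grid-search oracle for the (k, n) Hill fit with pinned ymin/ymax.
grid_hill <- function(x, y, ymin, ymax, k_lim, n_lim, steps = 200) {
  ks <- exp(seq(log(k_lim[1]), log(k_lim[2]), length.out = steps))
  ns <- seq(n_lim[1], n_lim[2], length.out = steps)
  best <- c(Inf, NA, NA)
  for (k in ks) {
    for (n in ns) {
      h <- ymin + (ymax - ymin) * k^n / (k^n + x^n)
      r <- sum((log(h) - log(y))^2)
      if (r < best[1]) best <- c(r, k, n)
    }
  }
  list(residual = best[1], k = best[2], n = best[3])
}

# A small analytic characterization straight from a truth (no event stage).
truth_characterization <- function(tr, sensor = default_sensor()) {
  gc <- gate_context(tr$truth$gate_name, tr$backbone, tr$host,
                     tr$truth$repressor_family)
  out <- if (tr$truth$functional) hill_eval(tr$truth, sensor$input_rpu)
         else rep(tr$truth$ymin, length(sensor$input_rpu))
  characterization(gc, sensor$input_rpu, out, sensor$iptg_uM)
}

# Fits table built directly from ground-truth parameters.
truth_fits <- function(lib) {
  vt <- viable_truths(lib)
  do.call(rbind, lapply(vt, function(tr) {
    t <- thresholds(c(tr$truth, converged = TRUE))
    data.frame(gate = tr$truth$gate_name,
               repressor_family = tr$truth$repressor_family,
               backbone = tr$backbone, host = tr$host,
               ymin = tr$truth$ymin, ymax = tr$truth$ymax,
               k = tr$truth$k, n = tr$truth$n, residual = 0, converged = TRUE,
               OL = t$OL, OH = t$OH, IL = t$IL, IH = t$IH,
               operational = t$operational)
  }))
}

# Random valid Hill parameter draws for property sweeps.
random_hill_params <- function(n, ratio_range = c(2.1, 100), seed = 1) {
  set.seed(seed)
  data.frame(
    ymin = exp(runif(n, log(1e-3), log(0.5))),
    ratio = exp(runif(n, log(ratio_range[1]), log(ratio_range[2]))),
    k = exp(runif(n, log(1e-2), log(10))),
    n = runif(n, 0.5, 4)
  )
}
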