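# Pairwise gate compatibility scoring and discrete-Frechet shape similarity.

#' Compatibility score of an ordered gate pair
#'
#' For operational inverters A (driving) and B (driven), the score is
#' \deqn{\min\left(\ln\frac{IL_B}{OL_A},\; \ln\frac{OH_A}{IH_B}\right).}
#' A positive score means A's output bands sit strictly inside B's input
#' bands — a high (low) output from A is read as high (low) by B — so A can
#' drive B. The pair is compatible iff the score is strictly positive.
#'
#' @param a,b `thresholds` of the driving (A) and driven (B) gate; both
#'   must be operational.
#' @return List with `score` and `compatible`.
#' @export
compatibility_score <- function(a, b) {
  if (!is_operational(a) || !is_operational(b)) {
    stop("compatibility is defined only for operational inverters", call. = FALSE)
  }
  score <- min(log(b$IL / a$OL), log(a$OH / b$IH))
  list(score = score, compatible = score > 0)
}

#' Score all ordered pairs in a library
#'
#' Builds the full score matrix over operational gate-contexts and the 0/1
#' compatibility table used downstream as a graph adjacency matrix.
#' Self-pairs are never compatible; pairs sharing a repressor family are
#' excluded by default (a repressor cannot feed its own cognate promoter in
#' a chain), controllable via `exclude_same_repressor`.
#'
#' @param fits A fits/thresholds data.frame as returned by [fit_library()]
#'   (columns gate, repressor_family, backbone, host, OL, OH, IL, IH,
#'   operational).
#' @param context_filter Optional predicate taking a row of `fits` (as a
#'   one-row data.frame) and returning TRUE to keep it; applied before
#'   scoring.
#' @param exclude_same_repressor Exclude same-family pairs from
#'   compatibility (default TRUE).
#' @return A `compatibility_matrix`: list with `nodes` (data.frame of kept
#'   operational gate-contexts), `score` (matrix), `compatible` (0/1
#'   matrix), `n_compatible`, and `edges` (long-form data.frame).
#' @export
compatibility_matrix <- function(fits, context_filter = NULL,
                                 exclude_same_repressor = TRUE) {
  if (nrow(fits) == 0) stop("empty fits table", call. = FALSE)
  keep <- fits$operational
  if (!is.null(context_filter)) {
    keep <- keep & vapply(seq_len(nrow(fits)),
                          function(i) isTRUE(context_filter(fits[i, ])), TRUE)
  }
  nodes <- fits[keep, , drop = FALSE]
  n <- nrow(nodes)
  labels <- paste(nodes$gate, nodes$backbone, nodes$host, sep = "|")
  score <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  compatible <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (n > 0) {
    IL <- nodes$IL; IH <- nodes$IH; OL <- nodes$OL; OH <- nodes$OH
    for (i in seq_len(n)) {
      s <- pmin(log(IL / OL[i]), log(OH[i] / IH))
      score[i, ] <- s
      ok <- s > 0
      ok[i] <- FALSE
      if (exclude_same_repressor) {
        ok <- ok & nodes$repressor_family != nodes$repressor_family[i]
      }
      compatible[i, ] <- as.integer(ok)
    }
  }
  edges <- which(compatible == 1L, arr.ind = TRUE)
  edges_df <- data.frame(source = labels[edges[, 1]], target = labels[edges[, 2]],
                         score = score[edges])
  edges_df <- edges_df[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(nodes = nodes, score = score, compatible = compatible,
                 n_compatible = sum(compatible),
                 exclude_same_repressor = exclude_same_repressor,
                 edges = edges_df),
            class = "compatibility_matrix")
}

#' @export
print.compatibility_matrix <- function(x, ...) {
  cat(sprintf("<compatibility_matrix> %d operational gate-contexts, %d compatible ordered pairs\n",
              nrow(x$nodes), x$n_compatible))
  invisible(x)
}

#' Discrete Frechet distance between two point sequences
#'
#' Classic dynamic program: the minimum over monotone couplings of the
#' maximum Euclidean distance between coupled points. Symmetric; zero iff
#' the sequences are identical.
#'
#' @param p,q Numeric matrices (n x 2 and m x 2) of 2D points.
#' @return The discrete Frechet distance.
#' @export
discrete_frechet <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) < 1 || nrow(q) < 1) stop("sequences must be non-empty", call. = FALSE)
  stopifnot(ncol(p) == 2, ncol(q) == 2)
  n <- nrow(p); m <- nrow(q)
  # pairwise Euclidean distances
  d <- sqrt(outer(p[, 1], q[, 1], "-")^2 + outer(p[, 2], q[, 2], "-")^2)
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(m)[-1]) {
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]), d[i, j])
    }
  }
  ca[n, m]
}

.normalize_curve <- function(pts, log_transform = TRUE) {
  m <- cbind(pts$input_rpu, pts$output_rpu)
  if (log_transform) {
    if (any(m <= 0)) stop("similarity requires strictly positive points",
                          call. = FALSE)
    m <- log(m)
  }
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) stop("degenerate curve: zero range on an axis", call. = FALSE)
  sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
}

#' Shape similarity between two characterizations
#'
#' Both curves are log-transformed and min-max normalized to [0,1] along
#' each axis — per curve by default, making this a pure comparison of
#' shape, insensitive to each curve's own location and scale — and the
#' similarity is 1 minus their discrete Frechet distance. Identical shapes
#' score 1; since normalized curves live in the unit square, the score is
#' bounded below by 1 - sqrt(2).
#'
#' @param a,b `characterization`s with >= 2 strictly positive points.
#' @param joint_normalization Normalize both curves with shared min/max
#'   instead of per curve (then location/scale differences do count).
#' @param log_transform Log both axes first (default TRUE).
#' @return List with `frechet`, `similarity`, and the two curve labels.
#' @export
curve_similarity <- function(a, b, joint_normalization = FALSE,
                             log_transform = TRUE) {
  stopifnot(nrow(a$points) >= 2, nrow(b$points) >= 2)
  if (joint_normalization) {
    na <- nrow(a$points)
    m <- rbind(cbind(a$points$input_rpu, a$points$output_rpu),
               cbind(b$points$input_rpu, b$points$output_rpu))
    if (log_transform) {
      if (any(m <= 0)) stop("similarity requires strictly positive points",
                            call. = FALSE)
      m <- log(m)
    }
    rng <- apply(m, 2, range)
    span <- rng[2, ] - rng[1, ]
    if (any(span == 0)) stop("degenerate curves: zero range on an axis",
                             call. = FALSE)
    m <- sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
    pa <- m[seq_len(na), , drop = FALSE]
    pb <- m[-seq_len(na), , drop = FALSE]
  } else {
    pa <- .normalize_curve(a$points, log_transform)
    pb <- .normalize_curve(b$points, log_transform)
  }
  dF <- discrete_frechet(pa, pb)
  list(curve_a = a$gate_context$label, curve_b = b$gate_context$label,
       frechet = dF, similarity = 1 - dF)
}

#' Similarity matrix across a set of characterizations
#'
#' The typical use is one gate across its contexts (the similarity heatmap
#' of context impact): darker off-diagonal entries mean a context change
#' reshaped the transfer function more.
#'
#' @param chrs List of `characterization`s.
#' @param labels Optional names; defaults to context labels.
#' @param ... Passed to [curve_similarity()].
#' @return Symmetric numeric matrix of similarity scores (diagonal 1).
#' @export
similarity_matrix <- function(chrs, labels = NULL, ...) {
  n <- length(chrs)
  if (is.null(labels)) {
    labels <- vapply(chrs, function(ch)
      paste(ch$gate_context$backbone, ch$gate_context$host, sep = ":"), "")
  }
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- curve_similarity(chrs[[i]], chrs[[j]], ...)$similarity
        m[i, j] <- m[j, i] <- s
      }
    }
  }
  m
}
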