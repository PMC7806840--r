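# Cross-context prediction: optimal affine transformation between one
# gate's characterizations in two contexts, applied to other gates.

log_points <- function(chr) {
  m <- cbind(chr$points$input_rpu, chr$points$output_rpu)
  if (any(m <= 0)) stop("log-space mapping requires strictly positive points",
                        call. = FALSE)
  log(m)
}

#' Fit the optimal affine map between two characterizations
#'
#' Characterizations of the same (reference) gate in a source and target
#' context are paired point-by-point on the shared inducer ladder and
#' mapped to (log input, log output). The six parameters of a 2D affine
#' transformation (2x2 matrix plus translation; pure axis translations and
#' general linear maps are special cases) are optimized to minimize the L1
#' loss \eqn{\sum_i \|M p_i + t - q_i\|_1}. Starts include the exact
#' least-squares affine solution, the identity, and the centroid-aligning
#' translation; L1 polishing is by Nelder-Mead, deterministic.
#'
#' @param source,target `characterization`s at the same inducer levels,
#'   >= 3 points, strictly positive.
#' @param linear_only Drop the translation (pure linear map; 4 parameters).
#' @return An `affine_map`: `matrix` (2x2), `translation` (length 2),
#'   `loss` (achieved L1 objective), `degenerate` flag.
#' @export
fit_affine <- function(source, target, linear_only = FALSE) {
  P <- log_points(source)
  Q <- log_points(target)
  if (nrow(P) != nrow(Q)) stop("source and target must have the same number of points",
                               call. = FALSE)
  if (nrow(P) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (!isTRUE(all.equal(source$points$iptg_uM, target$points$iptg_uM))) {
    stop("source and target must be sampled at the same inducer levels",
         call. = FALSE)
  }

  X <- cbind(1, P)
  if (qr(X)$rank < 3) {
    t0 <- colMeans(Q) - colMeans(P)
    warning("degenerate source characterization; returning centroid translation")
    map <- structure(list(matrix = diag(2), translation = t0,
                          loss = sum(abs(sweep(Q - P, 2, t0))), degenerate = TRUE),
                     class = "affine_map")
    return(map)
  }

  # exact least-squares affine solution as the primary start
  beta <- qr.solve(X, Q)                        # 3 x 2: row 1 translation, rows 2:3 = t(M)
  ls_par <- c(as.numeric(beta[2:3, ]), beta[1, ])  # (M row-major, t)

  unpack <- function(par) {
    list(M = matrix(par[1:4], 2, 2, byrow = TRUE),
         t = if (linear_only) c(0, 0) else par[5:6])
  }
  obj <- function(par) {
    u <- unpack(par)
    sum(abs(P %*% t(u$M) + rep(u$t, each = nrow(P)) - Q))
  }
  npar <- if (linear_only) 4L else 6L
  starts <- list(
    ls_par[seq_len(npar)],
    c(1, 0, 0, 1, 0, 0)[seq_len(npar)],
    c(1, 0, 0, 1, colMeans(Q) - colMeans(P))[seq_len(npar)]
  )
  best <- NULL
  for (s in starts) {
    res <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || res$value < best$value) best <- res
  }
  u <- unpack(best$par)
  structure(list(matrix = u$M, translation = u$t, loss = best$value,
                 degenerate = FALSE),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat("<affine_map> log-log space; L1 loss", format(x$loss, digits = 4), "\n")
  cat(sprintf("  M = [%7.4f %7.4f; %7.4f %7.4f], t = (%.4f, %.4f)\n",
              x$matrix[1, 1], x$matrix[1, 2], x$matrix[2, 1], x$matrix[2, 2],
              x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply an affine map to predict a gate in the target context
#'
#' Transforms the gate's source-context characterization in log space and
#' exponentiates back to RPU. If the transformed inputs are no longer
#' increasing the points are re-sorted with a warning.
#'
#' @param map An `affine_map`.
#' @param gate_source `characterization` of the gate in the source context.
#' @return Predicted `characterization` in the target context.
#' @export
predict_characterization <- function(map, gate_source) {
  P <- log_points(gate_source)
  Z <- P %*% t(map$matrix) + rep(map$translation, each = nrow(P))
  out <- exp(Z)
  if (is.unsorted(out[, 1], strictly = FALSE)) {
    warning("transformed inputs not increasing; re-sorting predicted points")
  }
  characterization(gate_source$gate_context, input_rpu = out[, 1],
                   output_rpu = out[, 2], iptg_uM = gate_source$points$iptg_uM)
}

#' Per-gate prediction error
#'
#' Mean absolute deviation in log space between predicted and measured
#' points (L1 norm per paired point, averaged): a pure output offset of
#' delta in log units scores exactly delta.
#'
#' @param predicted,measured `characterization`s with paired points.
#' @return Mean absolute log deviation (dimensionless).
#' @export
prediction_error <- function(predicted, measured) {
  P <- log_points(predicted)
  Q <- log_points(measured)
  if (nrow(P) != nrow(Q)) stop("predicted and measured lengths differ", call. = FALSE)
  mean(rowSums(abs(P - Q)))  # L1 per point, averaged over points
}

#' Cross-context prediction over a library
#'
#' Fits the affine map on a single reference gate's source/target pair and
#' applies it to every other gate characterized in both contexts.
#'
#' @param chrs_source,chrs_target Named lists of `characterization`s
#'   (names = gate names) in the source and target context.
#' @param reference Reference gate name; default the first operational-gate
#'   name alphabetically present in both lists.
#' @return List with `map`, `reference`, and `errors`: data.frame of gate,
#'   prediction error, and whether it is the reference.
#' @export
predict_library <- function(chrs_source, chrs_target, reference = NULL) {
  common <- sort(intersect(names(chrs_source), names(chrs_target)))
  if (length(common) < 2) stop("need at least two gates in both contexts", call. = FALSE)
  if (is.null(reference)) reference <- common[1]
  if (!reference %in% common) stop("reference gate not present in both contexts",
                                   call. = FALSE)
  map <- fit_affine(chrs_source[[reference]], chrs_target[[reference]])
  errs <- vapply(common, function(g) {
    pred <- suppressWarnings(predict_characterization(map, chrs_source[[g]]))
    prediction_error(pred, chrs_target[[g]])
  }, 0)
  list(map = map, reference = reference,
       errors = data.frame(gate = common, error = unname(errs),
                           is_reference = common == reference))
}
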