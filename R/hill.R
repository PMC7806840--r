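# Four-parameter repressive Hill model: fitting with logarithmic residuals,
# input/output thresholds, and the operational criterion.

#' Evaluate the repressive Hill transfer function
#'
#' \deqn{h(x) = y_{min} + (y_{max} - y_{min}) \frac{k^n}{k^n + x^n}}
#'
#' Strictly decreasing in x whenever `ymax > ymin`; h(0) = ymax and
#' h(k) = (ymin + ymax) / 2.
#'
#' @param fit A `hill_fit`, or any list with `ymin`, `ymax`, `k`, `n`.
#' @param x Input activity (RPU), non-negative. Vectorized.
#' @return Output activity (RPU).
#' @export
hill_eval <- function(fit, x) {
  stopifnot(all(x >= 0))
  kn <- fit$k^fit$n
  fit$ymin + (fit$ymax - fit$ymin) * kn / (kn + x^fit$n)
}

#' Fit the Hill model to a characterization
#'
#' `ymin` and `ymax` are pinned to the minimum and maximum of the corrected
#' data; `k` and `n` are then fitted by least squares on logarithmic
#' residuals, \eqn{\sum_i (\log h(x_i) - \log y_i)^2}, via deterministic
#' multi-start optimization (log-spaced k grid across the input range
#' crossed with n in {0.5, 1, 2, 4}). Outputs at or below zero (clipped
#' during standardization) are replaced by a floor before taking logs.
#'
#' @param chr A `characterization` (or a data.frame with `input_rpu` and
#'   `output_rpu` columns).
#' @param floor Positivity floor for log residuals; default
#'   `max(1e-4, smallest positive output / 10)`.
#' @return A `hill_fit`: `ymin`, `ymax`, `k`, `n`, `residual` (sum of
#'   squared log residuals), `converged`, and the source `gate_context`
#'   when available.
#' @export
fit_hill <- function(chr, floor = NULL) {
  pts <- if (inherits(chr, "characterization")) chr$points else chr
  x <- pts$input_rpu
  y <- pts$output_rpu
  stopifnot(length(x) == length(y), length(x) >= 2)

  if (all(y <= 0)) stop("all outputs non-positive; cannot fit in log space",
                        call. = FALSE)
  if (is.null(floor)) floor <- max(1e-4, min(y[y > 0]) / 10)
  y <- pmax(y, floor)

  ymin <- min(y)
  ymax <- max(y)
  out <- list(ymin = ymin, ymax = ymax,
              gate_context = if (inherits(chr, "characterization")) chr$gate_context else NULL)

  if (ymax - ymin < .Machine$double.eps * ymax) {
    # flat response: any (k, n) reproduces the data; report midpoint k
    out$ymax <- out$ymin
    out$k <- stats::median(x[x > 0])
    out$n <- 1
    out$residual <- sum((log(pmax(y, floor)) - log(ymin))^2)
    out$converged <- TRUE
    class(out) <- "hill_fit"
    return(out)
  }

  logy <- log(y)
  obj <- function(par) {
    k <- exp(par[1]); n <- exp(par[2])
    kn <- k^n
    h <- ymin + (ymax - ymin) * kn / (kn + x^n)
    sum((log(h) - logy)^2)
  }

  xpos <- x[x > 0]
  k_grid <- if (length(xpos) >= 2) {
    exp(seq(log(min(xpos)), log(max(xpos)), length.out = 8))
  } else max(x, 1)
  starts <- expand.grid(logk = log(k_grid), logn = log(c(0.5, 1, 2, 4)))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    out$k <- NA_real_; out$n <- NA_real_
    out$residual <- NA_real_; out$converged <- FALSE
    class(out) <- "hill_fit"
    return(out)
  }
  out$k <- exp(best$par[1])
  out$n <- exp(best$par[2])
  out$residual <- best$value
  out$converged <- best$convergence == 0
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> ymin=%.4g ymax=%.4g k=%.4g n=%.3g residual=%.3g%s\n",
              x$ymin, x$ymax, x$k, x$n, x$residual,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Input/output thresholds and the operational criterion
#'
#' Output thresholds are `OL = 2 ymin` (output low) and `OH = ymax / 2`
#' (output high). Input thresholds are the closed forms
#' \deqn{IL = \left(\frac{k^n y_{max}}{y_{max} - 2 y_{min}}\right)^{1/n}, \quad
#'       IH = \left(\frac{k^n (y_{max} - 2 y_{min})}{y_{min}}\right)^{1/n},}
#' which satisfy h(IL) = OH and h(IH) = OL: inputs below IL guarantee a high
#' output, inputs above IH guarantee a low one. A gate is operational iff
#' OH > OL and IH > IL; when `ymax <= 2 ymin` the input thresholds are
#' undefined (returned as NA) and the gate is non-operational.
#'
#' @param fit A `hill_fit` (or list with ymin, ymax, k, n).
#' @return A `thresholds` object: `OL`, `OH`, `IL`, `IH`, `operational`.
#' @export
thresholds <- function(fit) {
  ymin <- fit$ymin; ymax <- fit$ymax; k <- fit$k; n <- fit$n
  OL <- 2 * ymin
  OH <- ymax / 2
  if (is.na(k) || is.na(n) || ymin <= 0 || ymax <= 2 * ymin) {
    t <- list(OL = OL, OH = OH, IL = NA_real_, IH = NA_real_,
              operational = FALSE, gate_context = fit$gate_context)
    class(t) <- "thresholds"
    return(t)
  }
  kn <- k^n
  IL <- (kn * ymax / (ymax - 2 * ymin))^(1 / n)
  IH <- (kn * (ymax - 2 * ymin) / ymin)^(1 / n)
  converged <- if (is.null(fit$converged)) TRUE else isTRUE(fit$converged)
  t <- list(OL = OL, OH = OH, IL = IL, IH = IH,
            operational = (OH > OL) && (IH > IL) && converged,
            gate_context = fit$gate_context)
  class(t) <- "thresholds"
  t
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("<thresholds> OL=%.4g OH=%.4g IL=%.4g IH=%.4g operational=%s\n",
              x$OL, x$OH, x$IL, x$IH, x$operational))
  invisible(x)
}

#' Is a gate operational?
#'
#' TRUE iff the gate's output-high band exceeds its output-low band
#' (OH > OL) and its input thresholds are properly ordered (IH > IL); gates
#' with undefined thresholds or non-converged fits are excluded. For
#' positive ymin this is algebraically equivalent to `ymax > 4 ymin`.
#'
#' @param t A `thresholds` object.
#' @return Logical.
#' @export
is_operational <- function(t) {
  isTRUE(t$operational)
}

#' Fit and threshold a whole set of characterizations
#'
#' @param chrs List of `characterization`s.
#' @return data.frame with one row per gate-context: identity columns,
#'   fitted parameters, residual, convergence flag, thresholds and the
#'   operational flag (the usual supplementary-style parameter table).
#' @export
fit_library <- function(chrs) {
  rows <- lapply(chrs, function(ch) {
    f <- fit_hill(ch)
    t <- thresholds(f)
    gc <- ch$gate_context
    data.frame(gate = gc$gate_name, repressor_family = gc$repressor_family,
               backbone = gc$backbone, host = gc$host,
               ymin = f$ymin, ymax = f$ymax, k = f$k, n = f$n,
               residual = f$residual, converged = f$converged,
               OL = t$OL, OH = t$OH, IL = t$IL, IH = t$IH,
               operational = t$operational)
  })
  do.call(rbind, rows)
}
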