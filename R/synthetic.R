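# Synthetic gate libraries and event-level cytometry emulation.
#
# Every downstream stage (gating, medians, RPU, Hill fits, compatibility,
# chains, prediction) is exercised against data generated here with known
# ground truth, so the whole pipeline is testable without any download.

#' Ground-truth parameters of one genetic inverter
#'
#' A NOT gate is a repressor + cognate promoter pair whose steady-state
#' transfer function is a decreasing four-parameter Hill curve
#' \eqn{h(x) = ymin + (ymax - ymin) k^n / (k^n + x^n)} in RPU.
#'
#' @param gate_name Gate identifier, e.g. "PhlF-P1". The repressor family is
#'   the prefix before the first dash unless given explicitly.
#' @param ymin,ymax Floor and ceiling of the response (RPU); `ymax > ymin > 0`.
#' @param k Half-repression input (RPU); positive.
#' @param n Hill coefficient (cooperativity); positive.
#' @param repressor_family Repressor family name; defaults to the gate-name
#'   prefix so variants such as PhlF-P1 / PhlF-P2 share a family.
#' @param functional If `FALSE` the generator emits a flat response at `ymin`.
#' @return A `gate_truth` object.
#' @export
gate_truth <- function(gate_name, ymin, ymax, k, n,
                       repressor_family = NULL, functional = TRUE) {
  if (is.null(repressor_family)) {
    repressor_family <- sub("-.*$", "", gate_name)
  }
  stopifnot(is.character(gate_name), length(gate_name) == 1L)
  if (!(ymax > ymin && ymin > 0)) {
    stop("gate_truth requires ymax > ymin > 0", call. = FALSE)
  }
  if (!(k > 0 && n > 0)) {
    stop("gate_truth requires k > 0 and n > 0", call. = FALSE)
  }
  structure(
    list(gate_name = gate_name, repressor_family = repressor_family,
         ymin = ymin, ymax = ymax, k = k, n = n,
         functional = isTRUE(functional)),
    class = "gate_truth"
  )
}

#' @export
print.gate_truth <- function(x, ...) {
  cat(sprintf("<gate_truth> %s (%s)%s\n", x$gate_name, x$repressor_family,
              if (x$functional) "" else " [non-functional]"))
  cat(sprintf("  ymin=%.4g ymax=%.4g k=%.4g n=%.3g\n",
              x$ymin, x$ymax, x$k, x$n))
  invisible(x)
}

.BACKBONES <- c("pAN", "pSEVA221", "pSEVA231", "pSEVA251")
.HOSTS <- c("EcDH5a", "EcCC118lpir", "PpKT2440")

#' One molecular context: plasmid backbone x host strain
#'
#' Context effects are phenomenological: multiplicative on `ymin`, `ymax`
#' and `k`, additive on `n`. Applying all-unit factors reproduces the base
#' gate exactly.
#'
#' @param backbone One of pAN, pSEVA221, pSEVA231, pSEVA251.
#' @param host One of EcDH5a, EcCC118lpir, PpKT2440.
#' @param ymax_factor,ymin_factor,k_factor Positive multipliers.
#' @param n_shift Additive change to the Hill coefficient.
#' @param viable Whether constructs can be characterized in this context at
#'   all (non-viable gate-context combinations are dropped, not flattened).
#' @return A `context_spec` object.
#' @export
context_spec <- function(backbone, host, ymax_factor = 1, ymin_factor = 1,
                         k_factor = 1, n_shift = 0, viable = TRUE) {
  backbone <- match.arg(backbone, .BACKBONES)
  host <- match.arg(host, .HOSTS)
  if (any(c(ymax_factor, ymin_factor, k_factor) <= 0)) {
    stop("context factors must be positive", call. = FALSE)
  }
  structure(
    list(backbone = backbone, host = host,
         ymax_factor = ymax_factor, ymin_factor = ymin_factor,
         k_factor = k_factor, n_shift = n_shift, viable = isTRUE(viable),
         label = paste(backbone, host, sep = ":")),
    class = "context_spec"
  )
}

#' Default seven-context panel
#'
#' The study conditions emulated: pAN in E. coli DH5a; pSEVA221 in all three
#' hosts; pSEVA231 in CC118lpir and KT2440; pSEVA251 in KT2440. Effects are
#' chosen so that E. coli contexts retain inverter logic with shifted
#' dynamic ranges, while P. putida KT2440 flattens responses enough that a
#' subset of gates loses NOT logic (becomes non-operational downstream).
#'
#' @return List of 7 `context_spec` objects.
#' @export
default_contexts <- function() {
  list(
    context_spec("pAN",      "EcDH5a"),
    context_spec("pSEVA221", "EcDH5a",      0.60, 0.70, 0.90,  0.30),
    context_spec("pSEVA221", "EcCC118lpir", 0.50, 0.50, 1.10,  0.10),
    context_spec("pSEVA231", "EcCC118lpir", 0.80, 0.80, 1.20,  0.10),
    context_spec("pSEVA221", "PpKT2440",    0.30, 1.40, 2.00, -1.00),
    context_spec("pSEVA231", "PpKT2440",    0.35, 1.30, 2.20, -0.80),
    context_spec("pSEVA251", "PpKT2440",    0.40, 1.20, 1.80, -0.90)
  )
}

#' Inducer-to-input map of the sensor module
#'
#' Maps IPTG concentration (uM) applied to the pTac/LacI input module onto
#' input promoter activity in RPU. The two vectors must have equal length
#' and input RPU must increase strictly with IPTG.
#'
#' @param iptg_uM Ordered inducer concentrations (uM).
#' @param input_rpu Matching input activities (RPU), strictly increasing.
#' @return A `sensor_map` object.
#' @export
sensor_map <- function(iptg_uM, input_rpu) {
  stopifnot(length(iptg_uM) == length(input_rpu))
  if (any(input_rpu < 0)) stop("input RPU must be non-negative", call. = FALSE)
  if (any(diff(order(iptg_uM)) != 1) || any(diff(iptg_uM) <= 0)) {
    stop("iptg_uM must be strictly increasing", call. = FALSE)
  }
  if (any(diff(input_rpu) <= 0)) {
    stop("input_rpu must be strictly increasing with iptg", call. = FALSE)
  }
  structure(list(iptg_uM = as.numeric(iptg_uM),
                 input_rpu = as.numeric(input_rpu)),
            class = "sensor_map")
}

#' Standard inducer ladder
#' @return Numeric vector of the 13 IPTG concentrations (uM) used throughout.
#' @export
iptg_ladder <- function() c(0, 5, 10, 20, 30, 40, 50, 70, 100, 150, 200, 500, 1000)

#' Default sensor map: activating Hill response of the input module
#'
#' Input activity `smin + smax * iptg^m / (K^m + iptg^m)` evaluated at the
#' standard 13-level IPTG ladder. Defaults span roughly 0.003-3.3 RPU,
#' comparable to published pTac input ranges, so gate transitions (k around
#' 0.1-0.3 RPU) sit inside the sampled input window.
#'
#' @param smin Basal input activity (RPU) at 0 uM IPTG.
#' @param smax Asymptotic induced activity increment (RPU).
#' @param K Half-activation IPTG concentration (uM).
#' @param m Sensor Hill coefficient.
#' @param iptg_uM Inducer levels (uM).
#' @return A `sensor_map`.
#' @export
default_sensor <- function(smin = 0.002, smax = 4.5, K = 300, m = 0.8,
                           iptg_uM = iptg_ladder()) {
  sensor_map(iptg_uM, smin + smax * iptg_uM^m / (K^m + iptg_uM^m))
}

#' Look up input RPU for an inducer level
#' @param sensor A `sensor_map`.
#' @param iptg Concentration (uM); must be a member of the map's ladder.
#' @return Input activity (RPU).
#' @export
sensor_input_rpu <- function(sensor, iptg) {
  idx <- match(iptg, sensor$iptg_uM)
  if (anyNA(idx)) {
    stop("iptg level ", paste(iptg[is.na(idx)], collapse = ", "),
         " uM is not in the sensor map", call. = FALSE)
  }
  sensor$input_rpu[idx]
}

#' Event-level noise and instrument model
#'
#' Fluorescence per event is additive autofluorescence plus the construct
#' signal (Hill output in RPU times `brightness` a.u./RPU), scaled by a
#' cell-size coupling `(FSC / scatter_norm)^size_coupling` and multiplied by
#' log-normal cell-to-cell noise `exp(sigma_lognormal * Z)`. Forward scatter
#' is log-normal around `scatter_mean`. With `sigma_lognormal = 0`,
#' `scatter_sigma = 0` and `size_coupling = 0` every event takes the
#' deterministic value `autofluorescence_mean + signal * brightness`.
#'
#' @param sigma_lognormal Log-sd of the multiplicative construct noise.
#' @param autofluorescence_mean Background fluorescence (a.u.).
#' @param scatter_mean Median forward scatter (a.u.).
#' @param scatter_sigma Log-sd of the scatter distribution.
#' @param size_coupling Exponent linking scatter to construct fluorescence.
#' @param brightness Fluorescence units per RPU of promoter activity.
#' @param scatter_norm Fixed scatter normalization for the coupling term, so
#'   that samples whose cells run larger genuinely read brighter.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma_lognormal = 0.25, autofluorescence_mean = 150,
                        scatter_mean = 5e4, scatter_sigma = 0.35,
                        size_coupling = 1, brightness = 1000,
                        scatter_norm = 5e4) {
  stopifnot(sigma_lognormal >= 0, scatter_sigma >= 0, scatter_mean > 0,
            brightness > 0, scatter_norm > 0)
  structure(
    list(sigma_lognormal = sigma_lognormal,
         autofluorescence_mean = autofluorescence_mean,
         scatter_mean = scatter_mean, scatter_sigma = scatter_sigma,
         size_coupling = size_coupling, brightness = brightness,
         scatter_norm = scatter_norm),
    class = "noise_model"
  )
}

#' Zero-noise variant of a noise model (for exact-recovery checks)
#' @param noise A `noise_model`.
#' @return The same model with all stochastic terms and coupling off.
#' @export
noise_off <- function(noise = noise_model()) {
  noise$sigma_lognormal <- 0
  noise$scatter_sigma <- 0
  noise$size_coupling <- 0
  noise
}

# Evaluate code with a local RNG state; never disturbs the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.REPRESSOR_FAMILIES <- c("AmtR", "AmeR", "BM3R1", "BetI", "HlyIIR", "IcaRA",
                         "LitR", "LmrA", "PhlF", "PsrA", "QacR", "SrpR")

#' Generate a gate library across contexts with known ground truth
#'
#' Samples base Hill parameters for `n_gates` inverters (12 distinct
#' repressor families; further gates are variants sharing a family, named
#' with suffixes as in PhlF-P1 / PhlF-P2) and applies each context's
#' multiplicative/additive effects, optionally with per-gate heterogeneity
#' so that the same context change affects different gates differently
#' (the nonlinear-context regime). Deterministic under a fixed seed.
#'
#' @param n_gates Number of inverters (>= 1).
#' @param contexts List of `context_spec`s.
#' @param seed RNG seed.
#' @param n_nonviable Number of gates flagged non-viable in
#'   `nonviable_backbone` contexts (emulating constructs that could not be
#'   characterized in one backbone). Default 0.
#' @param nonviable_backbone Backbone in which those gates are non-viable.
#' @param heterogeneity Log-sd of per-gate jitter applied to each context's
#'   ymin/ymax/k factors (and sd of jitter on the n shift). 0 gives perfectly
#'   homogeneous context effects, under which context change is a single
#'   affine map in log space.
#' @param ymin_range,ymax_range,k_range Log-uniform sampling ranges (RPU).
#' @param n_range Uniform sampling range for the Hill coefficient.
#' @return A `gate_library`: list with `gates` (base `gate_truth`s),
#'   `contexts`, and `truths`, a list of per-gate-context entries each
#'   holding the context-adjusted `gate_truth`, backbone, host and `viable`.
#' @export
make_library <- function(n_gates, contexts = default_contexts(), seed = 1,
                         n_nonviable = 0, nonviable_backbone = "pSEVA251",
                         heterogeneity = 0,
                         ymin_range = c(0.10, 0.35),
                         ymax_range = c(1.5, 4),
                         k_range = c(0.05, 0.13),
                         n_range = c(2.6, 3.5)) {
  if (!is.numeric(n_gates) || n_gates < 1) {
    stop("n_gates must be >= 1", call. = FALSE)
  }
  if (length(contexts) < 1) stop("need at least one context", call. = FALSE)
  n_gates <- as.integer(n_gates)

  with_seed(seed, {
    fam <- rep(.REPRESSOR_FAMILIES, length.out = n_gates)
    # suffix naming: first member of a family is <Fam>-<X>1, variants -<X>2...
    idx_in_fam <- stats::ave(seq_len(n_gates), fam, FUN = seq_along)
    names_g <- paste0(fam, "-", substr(fam, 1, 1), idx_in_fam)

    runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
    ymin <- runif_log(n_gates, ymin_range)
    ymax <- runif_log(n_gates, ymax_range)
    k    <- runif_log(n_gates, k_range)
    nn   <- stats::runif(n_gates, n_range[1], n_range[2])

    gates <- lapply(seq_len(n_gates), function(i) {
      gate_truth(names_g[i], ymin = ymin[i], ymax = ymax[i],
                 k = k[i], n = nn[i], repressor_family = fam[i])
    })

    nonviable_gates <- if (n_nonviable > 0) names_g[seq_len(min(n_nonviable, n_gates))] else character(0)

    truths <- list()
    for (ctx in contexts) {
      for (g in gates) {
        jf <- if (heterogeneity > 0) exp(stats::rnorm(3, 0, heterogeneity)) else c(1, 1, 1)
        jn <- if (heterogeneity > 0) stats::rnorm(1, 0, heterogeneity) else 0
        ymin_c <- g$ymin * ctx$ymin_factor * jf[1]
        ymax_c <- g$ymax * ctx$ymax_factor * jf[2]
        k_c    <- g$k    * ctx$k_factor    * jf[3]
        n_c    <- max(g$n + ctx$n_shift + jn, 0.2)
        # a context can push the ceiling below the floor; such a device is a
        # flat (non-functional) response pinned near the floor level
        functional <- ymax_c > ymin_c
        if (!functional) ymax_c <- ymin_c * 1.0001
        viable <- ctx$viable &&
          !(ctx$backbone == nonviable_backbone && g$gate_name %in% nonviable_gates)
        truths[[length(truths) + 1L]] <- list(
          truth = gate_truth(g$gate_name, ymin = ymin_c, ymax = ymax_c,
                             k = k_c, n = n_c,
                             repressor_family = g$repressor_family,
                             functional = functional),
          backbone = ctx$backbone, host = ctx$host,
          context_label = ctx$label, viable = viable
        )
      }
    }
    structure(list(gates = gates, contexts = contexts, truths = truths),
              class = "gate_library")
  })
}

#' @export
print.gate_library <- function(x, ...) {
  nv <- sum(!vapply(x$truths, `[[`, TRUE, "viable"))
  cat(sprintf("<gate_library> %d gates x %d contexts = %d gate-contexts (%d non-viable, %d characterizable)\n",
              length(x$gates), length(x$contexts), length(x$truths), nv,
              length(x$truths) - nv))
  invisible(x)
}

#' Characterizable gate-context entries of a library
#' @param lib A `gate_library`.
#' @return The subset of `lib$truths` flagged viable.
#' @export
viable_truths <- function(lib) {
  Filter(function(tr) tr$viable, lib$truths)
}

.make_event_table <- function(FSC, SSC, FL1, role, gate = NA_character_,
                              context_label = NA_character_, iptg_uM = NA_real_) {
  df <- data.frame(FSC = FSC, SSC = SSC, FL1 = FL1)
  attr(df, "role") <- role
  attr(df, "gate") <- gate
  attr(df, "context_label") <- context_label
  attr(df, "iptg_uM") <- iptg_uM
  class(df) <- c("event_table", "data.frame")
  df
}

# shared event machinery: scatter draw + fluorescence for a given signal (RPU)
.simulate_signal_events <- function(signal_rpu, n_events, noise) {
  z_fsc <- stats::rnorm(n_events)
  FSC <- noise$scatter_mean * exp(noise$scatter_sigma * z_fsc)
  # side scatter tracks forward scatter with extra spread
  SSC <- 0.6 * noise$scatter_mean *
    exp(0.8 * noise$scatter_sigma * z_fsc +
          0.3 * noise$scatter_sigma * stats::rnorm(n_events))
  coupling <- (FSC / noise$scatter_norm)^noise$size_coupling
  cell_noise <- exp(noise$sigma_lognormal * stats::rnorm(n_events))
  FL1 <- noise$autofluorescence_mean +
    coupling * signal_rpu * noise$brightness * cell_noise
  list(FSC = FSC, SSC = SSC, FL1 = FL1)
}

#' Simulate one cytometry sample of a gate at one inducer level
#'
#' @param truth A `gate_truth` (possibly context-adjusted).
#' @param sensor A `sensor_map`; `iptg` must be one of its levels.
#' @param iptg Inducer concentration (uM).
#' @param n_events Number of events (>= 1).
#' @param noise A `noise_model`.
#' @param seed RNG seed.
#' @param context_label Metadata label carried on the table.
#' @return An `event_table` with columns FSC, SSC, FL1.
#' @export
simulate_events <- function(truth, sensor, iptg, n_events = 30000,
                            noise = noise_model(), seed = 1,
                            context_label = NA_character_) {
  stopifnot(inherits(truth, "gate_truth"), n_events >= 1)
  x <- sensor_input_rpu(sensor, iptg)
  signal <- if (truth$functional) {
    truth$ymin + (truth$ymax - truth$ymin) * truth$k^truth$n /
      (truth$k^truth$n + x^truth$n)
  } else truth$ymin
  with_seed(seed, {
    ch <- .simulate_signal_events(signal, n_events, noise)
    .make_event_table(ch$FSC, ch$SSC, ch$FL1, role = "gate",
                      gate = truth$gate_name, context_label = context_label,
                      iptg_uM = iptg)
  })
}

#' Simulate control samples for one context
#'
#' The autofluorescence control carries no construct (signal 0 RPU); the
#' reference-standard control expresses constitutively at exactly 1 RPU, so
#' that after standardization the autofluorescence sample reads 0 and the
#' standard reads 1 by construction.
#'
#' @param context A `context_spec` (controls are per-context).
#' @param n_events Events per control sample.
#' @param noise A `noise_model`.
#' @param seed RNG seed.
#' @return List with elements `auto` and `standard`, both `event_table`s.
#' @export
simulate_controls <- function(context, n_events = 30000,
                              noise = noise_model(), seed = 1) {
  stopifnot(n_events >= 1)
  with_seed(seed, {
    a <- .simulate_signal_events(0, n_events, noise)
    s <- .simulate_signal_events(1, n_events, noise)
    list(
      auto = .make_event_table(a$FSC, a$SSC, a$FL1, role = "auto",
                               context_label = context$label),
      standard = .make_event_table(s$FSC, s$SSC, s$FL1, role = "standard",
                                   context_label = context$label)
    )
  })
}
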