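# End-to-end orchestration: synthetic library -> events -> medians -> RPU ->
# Hill fits -> thresholds -> compatibility -> similarity -> chains ->
# prediction, with a serializable configuration and a reproduction helper.

#' Default pipeline configuration
#'
#' Every stage parameter with its default; the list round-trips through
#' JSON unchanged (contexts/noise/sensor are stored as plain fields).
#'
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param n_events Events per simulated sample.
#' @param sigma_lognormal Event-noise log-sd.
#' @param heterogeneity Per-gate context-effect jitter (see [make_library()]).
#' @param ... Overrides for any other field.
#' @return A named list (`run_config`).
#' @export
default_config <- function(seed = 1, n_events = 2000, sigma_lognormal = 0.25,
                           heterogeneity = 0.15, ...) {
  cfg <- list(
    n_gates = 20,
    n_nonviable = 5,
    nonviable_backbone = "pSEVA251",
    heterogeneity = heterogeneity,
    n_events = n_events,
    sigma_lognormal = sigma_lognormal,
    size_coupling = 1,
    gating_coverage = 0.5,
    window_halfwidth = Inf,       # plain-median fallback; finite value turns
                                  # on size conditioning around the pooled mode
    min_window_events = 100,
    exclude_same_repressor = TRUE,
    reference_gate = "AmtR-A1",
    seed = seed,
    outdir = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

# derive a bounded per-sample seed from the master seed and a sample index
derive_seed <- function(seed, index) {
  (seed * 10007L + index * 7919L) %% 2147483647L
}

#' Run the full synthetic characterization pipeline
#'
#' Generates the gate library, simulates event-level samples and controls,
#' preprocesses (density gating, optional size-conditioned medians),
#' standardizes to RPU, fits Hill models, derives thresholds, scores
#' compatibility under three nested context policies (single backbone+host,
#' any backbone within one host, all contexts), computes one gate's
#' cross-context similarity matrix, searches maximum chain depth per
#' policy, and runs the cross-context prediction. Deterministic for a
#' fixed config.
#'
#' @param config A config list from [default_config()].
#' @return An analysis bundle: list with `library`, `characterizations`,
#'   `fits`, `policy_report`, `similarity`, `prediction`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  noise <- noise_model(sigma_lognormal = config$sigma_lognormal,
                       size_coupling = config$size_coupling)
  sensor <- default_sensor()
  lib <- make_library(config$n_gates, seed = config$seed,
                      n_nonviable = config$n_nonviable,
                      nonviable_backbone = config$nonviable_backbone,
                      heterogeneity = config$heterogeneity)

  contexts <- lib$contexts
  names(contexts) <- vapply(contexts, `[[`, "", "label")

  # per-context controls through the same preprocessing as the samples
  control_medians <- list()
  for (ci in seq_along(contexts)) {
    ctx <- contexts[[ci]]
    ctl <- simulate_controls(ctx, n_events = config$n_events, noise = noise,
                             seed = derive_seed(config$seed, 100000L + ci))
    if (is.null(ctl$auto)) stop("missing controls for context ", ctx$label,
                                call. = FALSE)
    control_medians[[ctx$label]] <- list(
      auto = summarize_sample(ctl$auto, coverage = config$gating_coverage,
                              min_events = 1),
      std = summarize_sample(ctl$standard, coverage = config$gating_coverage,
                             min_events = 1)
    )
  }

  vt <- viable_truths(lib)
  chrs <- vector("list", length(vt))
  for (i in seq_along(vt)) {
    tr <- vt[[i]]
    summaries <- lapply(seq_along(sensor$iptg_uM), function(j) {
      ev <- simulate_events(tr$truth, sensor, sensor$iptg_uM[j],
                            n_events = config$n_events, noise = noise,
                            seed = derive_seed(config$seed, i * 100L + j),
                            context_label = tr$context_label)
      summarize_sample(ev, coverage = config$gating_coverage,
                       window_halfwidth = config$window_halfwidth,
                       min_events = config$min_window_events)
    })
    gc <- gate_context(tr$truth$gate_name, tr$backbone, tr$host,
                       tr$truth$repressor_family)
    chrs[[i]] <- suppressWarnings(build_characterization(
      summaries, control_medians[[tr$context_label]], sensor, gc))
  }

  fits <- fit_library(chrs)

  policies <- nested_policies()
  policy_report <- reproduce_counts(fits, policies,
                                    exclude_same_repressor = config$exclude_same_repressor)

  # similarity of the first gate across every context where it is viable
  g1 <- lib$gates[[1]]$gate_name
  g1_chrs <- Filter(function(ch) ch$gate_context$gate_name == g1, chrs)
  sim <- if (length(g1_chrs) >= 2) similarity_matrix(g1_chrs) else NULL

  # prediction: source context pSEVA221:EcCC118lpir -> target pSEVA221:EcDH5a
  pick_ctx <- function(label) {
    sel <- Filter(function(ch)
      paste(ch$gate_context$backbone, ch$gate_context$host, sep = ":") == label, chrs)
    stats::setNames(sel, vapply(sel, function(ch) ch$gate_context$gate_name, ""))
  }
  src <- pick_ctx("pSEVA221:EcCC118lpir")
  tgt <- pick_ctx("pSEVA221:EcDH5a")
  ref <- if (config$reference_gate %in% intersect(names(src), names(tgt)))
    config$reference_gate else NULL
  pred <- if (length(intersect(names(src), names(tgt))) >= 2)
    predict_library(src, tgt, reference = ref) else NULL

  bundle <- list(library = lib, characterizations = chrs, fits = fits,
                 policy_report = policy_report, similarity = sim,
                 prediction = pred, config = config)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

#' The three nested context policies of the headline analysis
#'
#' Single backbone within one host; any backbone within that host; all
#' contexts. Each policy's set of admissible gate-contexts contains the
#' previous one (pAN/DH5a stands apart, so the single-backbone policy uses
#' pSEVA221 in its host to keep the chain nested).
#'
#' @param backbone Backbone of the strictest policy.
#' @param host Host of the two restricted policies.
#' @return Named list of predicates on fit rows.
#' @export
nested_policies <- function(backbone = "pSEVA221", host = "EcCC118lpir") {
  list(
    single_backbone = function(row) row$backbone == backbone && row$host == host,
    single_host = function(row) row$host == host,
    all_contexts = NULL
  )
}

#' Compatible-pair counts and maximum depths per context policy
#'
#' The reproduction table behind the headline analysis: one row per policy
#' with the number of compatible ordered pairs and the maximum
#' repressor-distinct chain depth. Works on any fits/thresholds table,
#' including ones derived from external (deposited) data.
#'
#' @param fits Fits data.frame ([fit_library()] layout).
#' @param policies Named list of row predicates (NULL entry = all rows).
#' @param ... Passed to [compatibility_matrix()].
#' @return data.frame: policy, n_nodes, n_compatible, max_depth.
#' @export
reproduce_counts <- function(fits, policies = nested_policies(), ...) {
  depth_by_context_policy(fits, policies, ...)
}

#' Write an analysis bundle to disk
#'
#' CSV tables plus a JSON manifest with md5 content hashes and the full
#' configuration in effect.
#'
#' @param bundle Result of [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(characterizations = file.path(outdir, "characterizations.csv"),
             fits = file.path(outdir, "fits.csv"),
             policy_report = file.path(outdir, "policy_report.csv"))
  utils::write.csv(characterizations_to_df(bundle$characterizations),
                   paths["characterizations"], row.names = FALSE)
  utils::write.csv(bundle$fits, paths["fits"], row.names = FALSE)
  utils::write.csv(bundle$policy_report, paths["policy_report"], row.names = FALSE)
  if (!is.null(bundle$similarity)) {
    paths <- c(paths, similarity = file.path(outdir, "similarity.csv"))
    utils::write.csv(bundle$similarity, paths["similarity"], row.names = TRUE)
  }
  if (!is.null(bundle$prediction)) {
    paths <- c(paths, prediction = file.path(outdir, "prediction_errors.csv"))
    utils::write.csv(bundle$prediction$errors, paths["prediction"], row.names = FALSE)
  }
  manifest <- list(
    files = lapply(stats::setNames(as.list(paths), names(paths)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    config = bundle$config[!vapply(bundle$config, is.null, TRUE)]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
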