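# Relative promoter units (RPU) and assembly of transfer-function
# characterizations from per-sample medians.

#' Convert median fluorescence to relative promoter units
#'
#' \deqn{RPU = (yfp - yfp_{auto}) / (yfp_{std} - yfp_{auto})}
#'
#' so that the autofluorescence control reads 0 and the constitutive
#' reference-standard construct reads 1. The ratio is invariant under any
#' affine rescaling applied to all three inputs, which is what makes RPU
#' comparable across instruments and gain settings.
#'
#' @param yfp Median fluorescence of the sample (a.u.). Vectorized.
#' @param yfp_auto Median fluorescence of the autofluorescence control.
#' @param yfp_std Median fluorescence of the reference-standard control;
#'   must exceed `yfp_auto`.
#' @param clip_negative Clip negative results (sample dimmer than the
#'   autofluorescence control) to 0, with a warning.
#' @return RPU value(s).
#' @export
rpu <- function(yfp, yfp_auto, yfp_std, clip_negative = TRUE) {
  if (!(yfp_std > yfp_auto)) {
    stop("unusable standard: yfp_std must exceed yfp_auto", call. = FALSE)
  }
  val <- (yfp - yfp_auto) / (yfp_std - yfp_auto)
  if (clip_negative && any(val < 0)) {
    warning(sum(val < 0), " RPU value(s) below 0 clipped to 0")
    val <- pmax(val, 0)
  }
  val
}

#' Identity of one gate-in-context
#'
#' @param gate_name Gate identifier (e.g. "PhlF-P1").
#' @param backbone Plasmid backbone.
#' @param host Host strain.
#' @param repressor_family Defaults to the gate-name prefix before the dash,
#'   so variants of one repressor share a family.
#' @return A `gate_context` object.
#' @export
gate_context <- function(gate_name, backbone, host, repressor_family = NULL) {
  if (is.null(repressor_family)) repressor_family <- sub("-.*$", "", gate_name)
  structure(list(gate_name = gate_name, repressor_family = repressor_family,
                 backbone = backbone, host = host,
                 label = paste(gate_name, backbone, host, sep = "|")),
            class = "gate_context")
}

#' Assemble a transfer-function characterization
#'
#' Combines per-inducer-level sample medians with matched per-context
#' controls into ordered (input RPU, output RPU) points. At least 6 inducer
#' levels are required for a usable characterization.
#'
#' @param summaries Either a list of `sample_summary` objects (one per
#'   inducer level, each carrying its `iptg_uM`) or a data.frame with
#'   columns `iptg_uM` and `median_fluorescence`.
#' @param controls List with `auto` and `std`: each a `sample_summary` or a
#'   bare median fluorescence value, from the same context as the samples.
#' @param sensor A `sensor_map` providing input RPU per inducer level.
#' @param gc A `gate_context` identifying the device.
#' @param min_levels Minimum number of inducer levels (default 6).
#' @param clip_negative Passed to [rpu()].
#' @return A `characterization`: `gate_context` plus a data.frame `points`
#'   with columns `iptg_uM`, `input_rpu`, `output_rpu`, sorted by input.
#' @export
build_characterization <- function(summaries, controls, sensor, gc,
                                   min_levels = 6, clip_negative = TRUE) {
  if (is.data.frame(summaries)) {
    iptg <- summaries$iptg_uM
    med <- summaries$median_fluorescence
  } else {
    iptg <- vapply(summaries, function(s) as.numeric(s$iptg_uM), 0)
    med <- vapply(summaries, function(s) s$median_fluorescence, 0)
  }
  if (anyNA(iptg)) stop("summaries lack iptg_uM metadata", call. = FALSE)
  if (anyDuplicated(iptg)) {
    stop("duplicate inducer level(s): ",
         paste(unique(iptg[duplicated(iptg)]), collapse = ", "), call. = FALSE)
  }
  if (length(iptg) < min_levels) {
    stop("characterization needs at least ", min_levels,
         " inducer levels, got ", length(iptg), call. = FALSE)
  }
  ctrl_value <- function(ctl, what) {
    if (is.null(ctl)) stop("missing ", what, " control", call. = FALSE)
    if (inherits(ctl, "sample_summary")) ctl$median_fluorescence else as.numeric(ctl)
  }
  auto <- ctrl_value(controls$auto, "autofluorescence")
  std <- ctrl_value(controls$std, "standardization")
  out_rpu <- rpu(med, auto, std, clip_negative = clip_negative)
  in_rpu <- sensor_input_rpu(sensor, iptg)
  ord <- order(in_rpu)
  structure(
    list(gate_context = gc,
         points = data.frame(iptg_uM = iptg[ord], input_rpu = in_rpu[ord],
                             output_rpu = out_rpu[ord])),
    class = "characterization"
  )
}

#' Build a characterization directly from known points (no cytometry stage)
#'
#' Useful for pre-computed characterization tables and for fixtures.
#'
#' @param gc A `gate_context`.
#' @param input_rpu,output_rpu Paired coordinates (RPU).
#' @param iptg_uM Optional inducer levels per point.
#' @return A `characterization`.
#' @export
characterization <- function(gc, input_rpu, output_rpu, iptg_uM = NA_real_) {
  stopifnot(length(input_rpu) == length(output_rpu))
  ord <- order(input_rpu)
  structure(
    list(gate_context = gc,
         points = data.frame(iptg_uM = rep_len(iptg_uM, length(input_rpu))[ord],
                             input_rpu = input_rpu[ord],
                             output_rpu = output_rpu[ord])),
    class = "characterization"
  )
}

#' @export
print.characterization <- function(x, ...) {
  gc <- x$gate_context
  cat(sprintf("<characterization> %s [%s, %s], %d points, input %.3g-%.3g RPU\n",
              gc$gate_name, gc$backbone, gc$host, nrow(x$points),
              min(x$points$input_rpu), max(x$points$input_rpu)))
  invisible(x)
}

#' Rebuild characterization objects from a long-format table
#'
#' Inverse of [characterizations_to_df()]; also accepts externally produced
#' tables of pre-computed (input RPU, output RPU) points.
#'
#' @param df data.frame with columns gate, backbone, host, input_rpu,
#'   output_rpu and optionally repressor_family and iptg_uM.
#' @return List of `characterization`s.
#' @export
df_to_characterizations <- function(df) {
  key <- paste(df$gate, df$backbone, df$host, sep = "|")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    fam <- if ("repressor_family" %in% names(d)) d$repressor_family[1] else NULL
    gc <- gate_context(d$gate[1], d$backbone[1], d$host[1], fam)
    iptg <- if ("iptg_uM" %in% names(d)) d$iptg_uM else NA_real_
    characterization(gc, d$input_rpu, d$output_rpu, iptg)
  })
}

#' Serialize characterizations to a long-format data.frame
#' @param chrs List of `characterization`s.
#' @return data.frame with gate, repressor_family, backbone, host, iptg_uM,
#'   input_rpu, output_rpu.
#' @export
characterizations_to_df <- function(chrs) {
  do.call(rbind, lapply(chrs, function(ch) {
    gc <- ch$gate_context
    cbind(data.frame(gate = gc$gate_name,
                     repressor_family = gc$repressor_family,
                     backbone = gc$backbone, host = gc$host),
          ch$points)
  }))
}
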