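#!/usr/bin/env Rscript
# Stage 4: cross-context prediction. Fit the optimal affine map (L1 loss,
# log-log space) between the reference gate's characterizations in a source
# and a target context, apply it to every other gate, and measure per-gate
# prediction error. Large errors on non-reference gates are the signature
# of gate-specific (nonlinear) context effects.

suppressPackageStartupMessages(library(gatecontext))

chars <- read.csv("results/pipeline/characterizations.csv")
chrs <- df_to_characterizations(chars)

pick <- function(backbone, host) {
  sel <- Filter(function(ch)
    ch$gate_context$backbone == backbone && ch$gate_context$host == host, chrs)
  setNames(sel, vapply(sel, function(ch) ch$gate_context$gate_name, ""))
}
src <- pick("pSEVA221", "EcCC118lpir")
tgt <- pick("pSEVA221", "EcDH5a")

res <- predict_library(src, tgt, reference = "AmtR-A1")
print(res$map)
err <- res$errors[order(res$errors$error), ]
print(err, row.names = FALSE)
write.csv(err, "results/prediction_errors.csv", row.names = FALSE)

ref_err <- err$error[err$is_reference]
cat(sprintf("\nReference gate (%s) error: %.3f log units; worst gate: %.3f (%.1fx).\n",
            res$reference, ref_err, max(err$error), max(err$error) / ref_err))
cat("A single linear transformation transfers poorly to other gates:\n")
cat("context effects are gate-specific, so portability cannot be corrected\n")
cat("by one global calibration.\n")
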