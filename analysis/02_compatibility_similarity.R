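#!/usr/bin/env Rscript
# Stage 2: score every ordered pair of operational gate-contexts for
# compatibility under the three nested context policies, and quantify how
# much each context reshapes one gate's transfer function (discrete-Frechet
# shape similarity).

suppressPackageStartupMessages(library(gatecontext))

fits <- read.csv("results/pipeline/fits.csv")
chars <- read.csv("results/pipeline/characterizations.csv")

policies <- nested_policies()
for (nm in names(policies)) {
  cm <- compatibility_matrix(fits, context_filter = policies[[nm]])
  cat(sprintf("%-16s %3d operational nodes, %4d compatible ordered pairs\n",
              nm, nrow(cm$nodes), cm$n_compatible))
  write.csv(cm$edges, sprintf("results/compatibility_edges_%s.csv", nm),
            row.names = FALSE)
  write.csv(cm$compatible, sprintf("results/compatibility_table_%s.csv", nm))
}

# similarity of each gate to itself across contexts: per-gate heatmap data
chrs <- df_to_characterizations(chars)
gates <- unique(chars$gate)
sim_long <- do.call(rbind, lapply(gates, function(g) {
  own <- Filter(function(ch) ch$gate_context$gate_name == g, chrs)
  if (length(own) < 2) return(NULL)
  m <- similarity_matrix(own)
  data.frame(gate = g,
             context_a = rep(rownames(m), ncol(m)),
             context_b = rep(colnames(m), each = nrow(m)),
             similarity = as.vector(m))
}))
write.csv(sim_long, "results/similarity_by_gate.csv", row.names = FALSE)

rng <- range(sim_long$similarity[sim_long$context_a != sim_long$context_b])
cat(sprintf("Cross-context similarity spans %.3f-%.3f over %d gates:\n",
            rng[1], rng[2], length(gates)))
cat("contexts reshape transfer functions to very different degrees.\n")
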