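# gatecontext

Quantitative characterization of genetic NOT gates (inverters) across
plasmid-backbone × host-strain contexts, in R.

A genetic inverter — a repressor and its cognate promoter — is the basic
unit of genetic logic circuits, but its measured behaviour depends on the
molecular context carrying it: the plasmid backbone (whose origin of
replication sets copy number) and the host strain. This package implements
the full analysis pipeline for studying those effects, for synthetic
biologists and modellers working with gate libraries:

* **Event-level preprocessing** — density gating on forward/side scatter and
  (optionally) cell-size-conditioned median fluorescence.
* **RPU standardization** — `RPU = (⟨YFP⟩ − ⟨YFP⟩_auto) / (⟨YFP⟩_std − ⟨YFP⟩_auto)`,
  so an autofluorescence control reads 0 and a constitutive reference reads 1.
* **Hill characterization** — the repressive four-parameter model
  `h(x) = ymin + (ymax − ymin)·kⁿ/(kⁿ + xⁿ)` fitted by least squares on
  logarithmic residuals with `ymin`/`ymax` pinned to the data extremes.
* **Thresholds and the operational criterion** — `OL = 2·ymin`,
  `OH = ymax/2`, closed-form `IL`/`IH` satisfying `h(IL) = OH`,
  `h(IH) = OL`; a gate is operational iff `OH > OL` and `IH > IL`.
* **Compatibility scoring** — an ordered pair A→B scores
  `min(ln(IL_B/OL_A), ln(OH_A/IH_B))`, positive iff A can drive B.
* **Shape similarity** — 1 minus the discrete Fréchet distance between
  log-transformed, min-max-normalized curves.
* **Circuit depth** — longest repressor-distinct paths in the compatibility
  graph, per context policy.
* **Cross-context prediction** — the optimal 2D affine map (L1 loss,
  log-log space) fitted on one reference gate and transferred to the rest.
* **Synthetic data** — an event-level cytometry generator with known ground
  truth (20 gates × 7 contexts, 135 characterizable devices by default), so
  every stage is testable end-to-end without external data.

## Worked example

```r
library(gatecontext)

bundle <- run_pipeline(default_config(seed = 1))
bundle$library
#> <gate_library> 20 gates x 7 contexts = 140 gate-contexts (5 non-viable, 135 characterizable)

bundle$policy_report
#>            policy n_nodes n_compatible max_depth
#> 1 single_backbone      20           17         4
#> 2     single_host      40           62         5
#> 3    all_contexts     101          556         6
```

Reading: restricted to a single backbone and host, the library offers 17
composable ordered gate pairs and circuits at most 4 inverters deep; freeing
the backbone raises that to 62 pairs and depth 5; freeing backbone *and*
host raises it to 556 pairs and depth 6. Context relaxation monotonically
enlarges the design space — the package's central, property-tested result.

```r
pred <- bundle$prediction
pred$reference
#> [1] "AmtR-A1"
range(pred$errors$error)
#> [1] 0.154 0.810
```

The affine map fitted on the reference gate transfers poorly to other gates
(errors in mean absolute log-RPU per point): context effects are
gate-specific, so a single linear correction cannot port a whole library
between contexts.

The `analysis/` directory runs the same stages as a narrated sequence
(`01_simulate_and_characterize.R` → `04_prediction.R`), writing tables under
`results/`.

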