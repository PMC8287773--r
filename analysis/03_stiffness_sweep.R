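#!/usr/bin/env Rscript
# Step 3 — strain-stiffness characteristic of the default joint model.
#
# Runs the ten-value soft-tissue stiffness sweep (1-50 MPa, 400 N in
# five substeps, large deflection below 5 MPa, adaptive mesh
# convergence at 5%) on the default congruent condyle geometry, then
# fits the power law eps = a * E^b. Stiffness values whose solve does
# not converge are reported as absent rows — at 1 MPa the refined mesh
# typically fails exactly as the softest cases did in the original
# commercial-solver study.

suppressPackageStartupMessages(library(tfjstiff))
dir.create("results", showWarnings = FALSE)

sweep <- suppressWarnings(
  run_stiffness_sweep(geometry_model(), load_case(400, 5),
                      unloaded_gap_mm = 6, base_size = 1.2,
                      progress = TRUE))
write_sweep_table(sweep, "results/sweep.csv")

fit <- fit_power_law(sweep)
print(fit)
jsonlite::write_json(
  list(a = fit$a, b = fit$b, r_squared = fit$r_squared,
       se_a = fit$se[["a"]], se_b = fit$se[["b"]],
       converged_rows = fit$n,
       max_abs_convergence_error_pct =
         max(abs(sweep$convergence_error_pct), na.rm = TRUE)),
  "results/sweep_fit.json", auto_unbox = TRUE, digits = NA)
message("wrote results/sweep.csv and results/sweep_fit.json")
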