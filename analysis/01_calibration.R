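#!/usr/bin/env Rscript

# Equilibrium calibration of the nanotube H2O2 sensor: forward curve,
# refit from perturbed starts, limit-of-detection inversion and response
# time. Writes results/calibration/.

suppressPackageStartupMessages(library(ncckit))
out <- "results/calibration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

p0 <- default_calibration()
message("published-constant model: ", format(p0))
conc <- 10^seq(-6, 0)
curve <- data.frame(concentration_M = conc,
                    response_pct = response_at(conc, p0))
write_calibration_csv(curve, file.path(out, "response_curve.csv"))

# refit from a start perturbed by +/-50% on every parameter
start <- calibration_params(p0$alpha * 1.5, p0$beta * 0.5, p0$K_D * 1.5,
                            p0$n * 0.5)
fit <- fit_calibration(curve, start)
message(sprintf(
  "refit: alpha = %.2f %%, beta = %.2f %%, K_D = %.5f M, n = %.3f (R^2 = %.5f)",
  fit$params$alpha, fit$params$beta, fit$params$K_D, fit$params$n,
  fit$r_squared))
write_calibration_json(fit$params, file.path(out, "fitted_params.json"))

# limit of detection as a function of the (unpublished) blank noise level
blank_sds <- c(0.01, 0.05, 0.1, 0.5)
lods <- vapply(blank_sds, function(s)
  limit_of_detection(fit$params, blank_response = fit$params$beta,
                     blank_sd = s), 0)
lod_tab <- data.frame(blank_sd_pct = blank_sds, lod_M = lods,
                      lod_nM = lods * 1e9)
print(lod_tab, row.names = FALSE)
utils::write.csv(lod_tab, file.path(out, "lod_vs_blank_sd.csv"),
                 row.names = FALSE)
message("the detection limit scales with the blank standard deviation, ",
        "which is a property of each instrument run")

# response time at a low concentration (t90 ~ ln 10 / k_s)
kin <- default_kinetics(fit$params)
tt <- seq(0, 1200, by = 0.5)
tr <- intensity_trace(tt, intensity_forward(tt, 1e-6, kin, I0 = 1000))
message(sprintf("response time at 1 uM: t90 = %.0f s (~%.1f min)",
                response_time(tr), response_time(tr) / 60))
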