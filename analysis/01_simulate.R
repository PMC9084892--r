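#!/usr/bin/env Rscript
# Generate the synthetic study datasets for all five modalities and write
# them (plus machine-readable truth records) under results/data/. Every
# downstream analysis script reads only these files.

library(foldbind)
suppressMessages(library(jsonlite))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- urea denaturation: 4 constructs, 24 steps 0.135-6 M, FIR noise 0.005")
urea <- gen_urea_curves(noise_sd = 0.005, seed = seed)
write.csv(urea$table, file.path(out, "urea_curves.csv"), row.names = FALSE)
write_json(urea$truth, file.path(out, "urea_truth.json"),
           auto_unbox = TRUE, digits = NA)

message("-- thermal ramps: 30-85 C at 1 C/min; N-linker constructs protected from aggregation")
thermal_truth <- list(
  "A1 short"    = list(midpoints = c(50.7, 61.0), onset = 55),
  "A1+OGly+C"   = list(midpoints = c(49.9, 63.0), onset = 67),
  "A1+OGly+N"   = list(midpoints = c(53.3, 64.0), onset = NA),
  "A1+OGly+N+C" = list(midpoints = c(53.2, 63.0), onset = NA)
)
thermal_rows <- list()
for (lb in names(thermal_truth)) {
  tt <- thermal_truth[[lb]]
  g <- gen_thermal(construct = lb, midpoints = tt$midpoints,
                   aggregation_onset = tt$onset,
                   seed = seed + match(lb, names(thermal_truth)))
  thermal_rows[[lb]] <- data.frame(construct = lb, temp_C = g$curve$temp_c,
                                   fir = g$curve$fir,
                                   backscatter = g$curve$backscatter)
}
write.csv(do.call(rbind, thermal_rows), file.path(out, "thermal_ramps.csv"),
          row.names = FALSE)
write_json(thermal_truth, file.path(out, "thermal_truth.json"),
           auto_unbox = TRUE, digits = NA)

message("-- BLI: 4 constructs x {150, 10} mM NaCl, 5 concentrations each")
# on-rates at 150 mM span the panel's ~80-fold range; low salt raises kon
# by construct-specific factors averaging ~17-fold with off-rates untouched
bli_truth <- list(
  "A1 short"    = list(kon150 = 3.1e5, koff = 0.056, fold = 13.5),
  "A1+OGly+C"   = list(kon150 = 1.3e5, koff = 0.058, fold = 16.0),
  "A1+OGly+N"   = list(kon150 = 1.2e4, koff = 0.031, fold = 19.0),
  "A1+OGly+N+C" = list(kon150 = 3.9e3, koff = 0.036, fold = 20.0)
)
bli_rows <- list()
for (lb in names(bli_truth)) {
  bt <- bli_truth[[lb]]
  for (nacl in c(150, 10)) {
    kon <- if (nacl == 150) bt$kon150 else bt$kon150 * bt$fold
    tr <- one_site_kinetics(kon, bt$koff, rmax = 1)
    g <- gen_sensorgrams(tr, construct = lb, nacl = nacl, noise_sd = 0.01,
                         seed = seed + 100L + match(lb, names(bli_truth)) +
                           as.integer(nacl))
    for (i in seq_along(g$samples)) {
      for (role in c("sample", "internal_ref")) {
        s <- if (role == "sample") g$samples[[i]] else g$internal_refs[[i]]
        phase <- ifelse(s$time <= s$assoc_window[2L], "assoc", "dissoc")
        bli_rows[[length(bli_rows) + 1L]] <- data.frame(
          construct = lb, nacl_mM = nacl, conc_M = g$samples[[i]]$conc,
          time_s = s$time, response = s$response, phase = phase,
          well_role = role)
      }
    }
  }
}
write.csv(do.call(rbind, bli_rows), file.path(out, "bli_sensorgrams.csv"),
          row.names = FALSE)
write_json(bli_truth, file.path(out, "bli_truth.json"), auto_unbox = TRUE,
           digits = NA)

message("-- ITC: 7 constructs, endothermic panel with common dH/TdS rank order")
itc_truth <- list(
  "A1 short"    = list(kd = 1.8e-7, dh = 11.0),
  "A1+N"        = list(kd = 7.7e-7, dh = 9.5),
  "A1+C"        = list(kd = 4.5e-7, dh = 10.4),
  "A1+N+C"      = list(kd = 1.8e-6, dh = 8.6),
  "A1+OGly+N"   = list(kd = 7.6e-6, dh = 6.8),
  "A1+OGly+C"   = list(kd = 9.0e-7, dh = 10.0),
  "A1+OGly+N+C" = list(kd = 9.2e-6, dh = 6.5)
)
itc_rows <- list()
for (lb in names(itc_truth)) {
  it <- itc_truth[[lb]]
  th <- one_site_thermo(n = 1, ka = 1 / it$kd, dh = it$dh)
  g <- gen_itc(th, noise_frac = 0.02,
               seed = seed + 200L + match(lb, names(itc_truth)))
  itc_rows[[lb]] <- data.frame(construct = lb,
                               injection_index = seq_along(g$heats),
                               heat_kcal = g$heats)
}
write.csv(do.call(rbind, itc_rows), file.path(out, "itc_heats.csv"),
          row.names = FALSE)
write_json(itc_truth, file.path(out, "itc_truth.json"), auto_unbox = TRUE,
           digits = NA)

message("-- HDX: A1 short (reference) vs N-linker construct, 2 protected loops")
hdx <- gen_hdx(labels = c("A1 short", "A1+OGly+N"), seed = seed + 300L)
write.csv(rbind(hdx$reference$measurements, hdx$other$measurements),
          file.path(out, "hdx_uptake.csv"), row.names = FALSE)
write_json(hdx$truth[c("offset", "protected_regions", "timepoints",
                       "d2o_fraction", "back_exchange")],
           file.path(out, "hdx_truth.json"), auto_unbox = TRUE, digits = NA)

message("done: synthetic datasets written to ", out)
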