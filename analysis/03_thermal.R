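#!/usr/bin/env Rscript
# Melting temperatures from dFIR/dT and aggregation onsets from
# backscatter for each construct's thermal ramp.

library(foldbind)

bundle <- load_table("results/data/thermal_ramps.csv", "thermal")
tab <- bundle$table

rows <- list()
for (lb in unique(tab$construct)) {
  d <- tab[tab$construct == lb, ]
  curve <- thermal_ramp(lb, d$temp_C, d$fir, backscatter = d$backscatter)
  ma <- melting_analysis(curve)
  pk <- ma$transitions[ma$transitions$kind == "peak", ]
  pk <- pk[order(-pk$prominence), ]
  tm1 <- if (nrow(pk) >= 1) sort(pk$tm_c[1:min(2, nrow(pk))])[1] else NA
  tm2 <- if (nrow(pk) >= 2) sort(pk$tm_c[1:2])[2] else NA
  rows[[lb]] <- data.frame(construct = lb, tm1_C = tm1, tm2_C = tm2,
                           n_shoulders = sum(ma$transitions$kind == "shoulder"),
                           aggregation_onset_C = ma$aggregation_onset)
  message(sprintf(
    "%-14s Tm1 = %.1f C, Tm2 = %.1f C, aggregation onset = %s", lb, tm1,
    tm2, if (is.na(ma$aggregation_onset)) "none (protected up to 85 C)"
    else sprintf("%.1f C", ma$aggregation_onset)))
}
out <- do.call(rbind, rows)
rownames(out) <- NULL
write_report(out, "results/melting.csv")
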