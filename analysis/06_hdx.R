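#!/usr/bin/env Rscript
# Peptide-level deuterium uptake summaries, coverage/redundancy of the
# peptide map, and the construct difference map at the 0.7 Da threshold.

library(foldbind)

bundle <- load_table("results/data/hdx_uptake.csv", "hdx")
tab <- bundle$table
labels <- unique(tab$construct)
exps <- lapply(labels, function(lb) {
  hdx_experiment(lb, tab[tab$construct == lb, ])
})
names(exps) <- labels

ref <- exps[["A1 short"]]
peps <- ref$peptides
region <- range(c(vapply(peps, `[[`, numeric(1), "start"),
                  vapply(peps, `[[`, numeric(1), "end")))
cr <- coverage_and_redundancy(peps, region[1L], region[2L])
message(sprintf(
  "peptide map: %d peptides over residues %d-%d; %.1f%% coverage, %.2fx redundancy",
  length(peps), region[1L], region[2L], cr$coverage, cr$redundancy))

for (other in setdiff(labels, "A1 short")) {
  dm <- difference_map(ref, exps[[other]], threshold = 0.7)
  print(dm)
  sig <- dm$per_peptide[dm$per_peptide$any_significant, ]
  if (nrow(sig) > 0) {
    message(sprintf(
      "protected peptides (A1 short exchanges > 0.7 Da more than %s):",
      other))
    for (i in seq_len(nrow(sig))) {
      message(sprintf("  residues %d-%d (%d significant timepoints)",
                      sig$pep_start[i], sig$pep_end[i],
                      sig$n_significant[i]))
    }
  }
  safe <- gsub("[^A-Za-z0-9]+", "_", other)
  write_report(dm$entries, sprintf("results/hdx_diff_%s.csv", safe))
  write_report(dm$per_peptide, sprintf("results/hdx_diff_%s_by_peptide.csv",
                                       safe))
}
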