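#!/usr/bin/env Rscript
# Gene-set enrichment of the cumulative changed set against functional
# annotations, Fisher exact (upper tail) with Bonferroni correction and
# the array itself as the background universe. Annotations here are
# synthetic: one term built from the true event loci (expected to enrich)
# and several random terms (expected not to).

suppressPackageStartupMessages({library(nucshift); library(dplyr)})

profiles <- read_profiles("results/data/profiles.tsv")
truth <- read_truth("results/data/truth.tsv")
universe <- unique(profiles$locus_id)

calls <- call_all(profiles)
cum <- cumulative_changed(changed_sets(calls), universe)

set.seed(404)
event_loci <- unique(truth$locus_id[truth$changed])
annotations <- c(
  list(event_loci_synthetic = event_loci),
  setNames(lapply(1:5, function(i) sample(universe, 60)),
           sprintf("random_term_%d_synthetic", 1:5))
)

res <- enrich(cum$members, annotations, universe)
readr::write_tsv(res, "results/enrichment.tsv")
cat("enrichment of the cumulative changed set (fold, Bonferroni p):\n")
print(as.data.frame(res[, c("term", "k", "K", "fold", "adjusted_p")]),
      row.names = FALSE)
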