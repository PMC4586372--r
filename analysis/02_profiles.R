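#!/usr/bin/env Rscript
# Normalize the two channels per array, form per-probe log2
# (nucleosomal / genomic) ratios, and collapse them to per-locus occupancy
# profiles on the TSS-relative midpoint grid. Also records the
# replicate-consistency correlations (the scatterplot check).

suppressPackageStartupMessages(library(nucshift))

data_dir <- "results/data"
loci <- read_loci(file.path(data_dir, "loci.tsv"))
layout <- read_design(file.path(data_dir, "design.tsv"), loci)
signals <- read_signals(file.path(data_dir, "signals.tsv"))

profiles <- build_profiles(signals, layout, method = "median")
write_profiles(profiles, file.path(data_dir, "profiles.tsv"))

ratios <- log2_ratio(normalize_channels(signals))
cons <- replicate_consistency(ratios)
readr::write_tsv(cons, "results/replicate_consistency.tsv")

cat(sprintf("profiles: %d loci x %d positions per condition/replicate\n",
            length(unique(profiles$locus_id)),
            nrow(profiles) / length(unique(paste(profiles$condition,
                                                 profiles$replicate,
                                                 profiles$locus_id)))))
cat("replicate consistency (per condition):\n")
print(as.data.frame(cons), row.names = FALSE)
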