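#!/usr/bin/env Rscript
# Simulate the nicotine-like experiment: 858 TSS-centered 2-kb loci tiled
# with 60-mers (13-bp step, both strands), two biological replicates for a
# drug-naive control and three treatment time points, repositioning events
# injected at 25% of loci with partial restoration later in the course.
#
# Writes the raw two-channel intensities, the probe design, and the truth
# table under results/data/.

suppressPackageStartupMessages(library(nucshift))

seed <- 101L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
exp <- generate_experiment(cfg, seed)

write_loci(exp$loci, file.path(out, "loci.tsv"))
write_design(exp$layout, file.path(out, "design.tsv"))
write_signals(exp$signals, file.path(out, "signals.tsv"))
write_truth(exp$truth, file.path(out, "truth.tsv"))
Biostrings::writeXStringSet(synthetic_sequences(exp$loci, seed + 1L),
                            file.path(out, "sequences.fa"))

sm <- layout_summary(exp$layout)
cat(sprintf("simulated %d loci x %d probes (median spacing %.1f bp), %d arrays\n",
            nrow(exp$loci), sm$probe_count[1], sm$median_spacing[1],
            length(unique(paste(exp$signals$condition, exp$signals$replicate)))))
cat(sprintf("truly changed loci at first time point: %d\n",
            sum(exp$truth$changed[exp$truth$timepoint == cfg$timepoints[1]])))
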