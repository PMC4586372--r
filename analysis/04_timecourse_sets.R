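#!/usr/bin/env Rscript
# Set arithmetic over the time course: which changes are unique to a time
# point, which persist throughout, how many loci return to the basal state,
# and how the changed sets of two drugs overlap. The second drug is a
# cocaine-like course (four time points, stronger restoration) simulated on
# the same locus universe.

suppressPackageStartupMessages({library(nucshift); library(dplyr)})

profiles <- read_profiles("results/data/profiles.tsv")
calls <- call_all(profiles)
sets <- changed_sets(calls)
universe <- unique(profiles$locus_id)

vp <- venn_partition(sets)
write_partition(vp, "results/venn_partition.json", "results/venn_regions.tsv")
cat("time-point Venn regions (drug A):\n")
print(as.data.frame(vp$regions[, c("region", "count")]), row.names = FALSE)

cum <- cumulative_changed(sets, universe)
last_tp <- names(sets)[length(sets)]
restored <- restored_loci(cum$members, sets[[last_tp]])
cat(sprintf("cumulative changed: %d (%d%%); restored by %s: %d; still changed: %d\n",
            cum$count, cum$pct, last_tp, length(restored),
            length(sets[[last_tp]])))

# second drug on the same array design
cfgB <- sim_config(timepoints = c("5min", "20min", "40min", "60min"),
                   fraction_changed = 0.15, revert_fraction = 0.6)
expB <- generate_experiment(cfgB, seed = 202L)
callsB <- call_all(build_profiles(expB$signals, expB$layout))
setsB <- changed_sets(callsB)
cumB <- cumulative_changed(setsB, universe)

ov <- drug_overlap(cum$members, cumB$members, labels = c("drugA", "drugB"))
cat(sprintf("drug-specific changes: %d%% of drug A's, %d%% of drug B's; shared %d\n",
            ov$pct_A_only, ov$pct_B_only, length(ov$shared)))
jsonlite::write_json(
  list(drugA_union = cum$count, drugB_union = cumB$count,
       drugA_only_pct = ov$pct_A_only, drugB_only_pct = ov$pct_B_only,
       shared = length(ov$shared)),
  "results/drug_overlap.json", auto_unbox = TRUE, pretty = TRUE)
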