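#!/usr/bin/env Rscript
# Regulatory annotation of a changed promoter: occupancy states at the TSS
# and at annotated TF binding sites before and after treatment, the
# permissive/restrictive configuration verdict, NDR calls, and a
# figure-style profile plot for the most strongly repositioned locus.

suppressPackageStartupMessages({library(nucshift); library(dplyr)})

profiles <- read_profiles("results/data/profiles.tsv")
calls <- call_all(profiles)
first_tp <- setdiff(unique(profiles$condition), "control")[1]

top <- calls |>
  filter(condition == first_tp, changed) |>
  arrange(r_mean) |>
  slice(1)
cat(sprintf("most strongly repositioned locus at %s: %s (r = %.4f +/- %.4f)\n",
            first_tp, top$locus_id, top$r_mean, top$r_sd))

ctl <- average_replicates(profiles[profiles$condition == "control" &
                                     profiles$locus_id == top$locus_id, ])
trt <- average_replicates(profiles[profiles$condition == first_tp &
                                     profiles$locus_id == top$locus_id, ])

# illustrative annotation: two permissive sites upstream, two repressive
# sites downstream of the TSS
tfbs <- tibble::tibble(
  locus_id = top$locus_id,
  factor = c("FOS", "SRF", "CTCF", "EGR1"),
  start = c(-600, -350, 250, 500), end = c(-500, -250, 350, 600),
  regulatory_class = c("permissive", "permissive", "repressive", "repressive")
)

cl <- classify_configuration(ctl, trt, tss_interval = c(-100, 100), tfbs = tfbs)
cat(sprintf("configuration verdict: %s\n", cl$verdict))
print(as.data.frame(cl$sites[, c("factor", "regulatory_class", "transition")]),
      row.names = FALSE)

ndr_ctl <- call_ndrs(ctl); ndr_trt <- call_ndrs(trt)
cat(sprintf("NDRs (>=140 bp below baseline): %d basal, %d treated\n",
            nrow(ndr_ctl), nrow(ndr_trt)))
readr::write_tsv(dplyr::bind_rows(basal = ndr_ctl, treated = ndr_trt,
                                  .id = "state"),
                 "results/ndrs_top_locus.tsv")

p <- plot_profile(ctl, trt, tfbs = tfbs, smooth = 5,
                  title = sprintf("%s, control vs %s", top$locus_id, first_tp))
ggplot2::ggsave("results/top_locus_profile.png", p, width = 8, height = 4,
                dpi = 150)
cat("wrote results/top_locus_profile.png\n")
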