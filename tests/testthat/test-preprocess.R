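make_signals <- function(n = 50, conds = "c", reps = 1:2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(probe_id = sprintf("p%02d", 1:n), condition = conds,
                      replicate = reps, stringsAsFactors = FALSE)
  tibble::as_tibble(grid) |>
    dplyr::mutate(cy3 = stats::rlnorm(dplyr::n(), log(500), 0.4),
                  cy5 = stats::rlnorm(dplyr::n(), log(800), 0.4))
}

test_that("median normalization equalizes array medians and preserves ratios", {
  s <- make_signals()
  norm <- normalize_channels(s, "median")
  meds <- norm |>
    dplyr::group_by(condition, replicate) |>
    dplyr::summarise(m3 = median(cy3), m5 = median(cy5), .groups = "drop")
  expect_true(all(abs(meds$m3 - meds$m3[1]) < 1e-9))
  expect_equal(meds$m3, meds$m5)

  # scale invariance: doubling one channel leaves post-normalization ratios alone
  s2 <- dplyr::mutate(s, cy3 = 2 * cy3)
  r1 <- log2_ratio(normalize_channels(s, "median"))
  r2 <- log2_ratio(normalize_channels(s2, "median"))
  expect_equal(r1$value, r2$value)
})

test_that("two arrays with different medians are brought to a common reference", {
  s <- make_signals(conds = "c", reps = 1:2)
  s$cy3[s$replicate == 2] <- s$cy3[s$replicate == 2] * 4  # medians ~100 vs ~400
  norm <- normalize_channels(s, "median")
  m <- tapply(norm$cy3, norm$replicate, median)
  expect_equal(unname(m[1]), unname(m[2]))
})

test_that("method none is the identity and non-positive intensities are named", {
  s <- make_signals()
  expect_identical(normalize_channels(s, "none"), s)
  s$cy5[3] <- 0
  err <- expect_error(normalize_channels(s, "median"),
                      class = "nucshift_preprocess_error")
  expect_match(conditionMessage(err), s$probe_id[3])
})

test_that("quantile normalization equalizes array-channel distributions", {
  s <- make_signals(reps = 1:2)
  norm <- normalize_channels(s, "quantile")
  q1 <- sort(norm$cy3[norm$replicate == 1])
  q2 <- sort(norm$cy3[norm$replicate == 2])
  expect_equal(q1, q2, tolerance = 1e-8)
})

test_that("log2 ratios follow the definition", {
  s <- tibble::tibble(probe_id = c("a", "b", "c"), condition = "c",
                      replicate = 1L,
                      cy3 = c(10, 40, 100), cy5 = c(10, 10, 800))
  expect_equal(log2_ratio(s)$value, c(0, 2, -3))
})

test_that("co-located probes are averaged and distinct midpoints pass through", {
  loci <- tiny_loci(1)
  layout <- build_layout(loci, both_strands = TRUE, rev_offset = 0)
  # rev_offset 0: forward and reverse probes share midpoints
  p2 <- layout$probes[layout$probes$start == layout$probes$start[1], ]
  ratios <- tibble::tibble(probe_id = p2$probe_id, condition = "c",
                           replicate = 1L, value = c(1, 3))
  pr <- average_probes(ratios, layout)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$value, 2)

  layout6 <- build_layout(loci, both_strands = TRUE, rev_offset = 6)
  ratios6 <- tibble::tibble(probe_id = layout6$probes$probe_id,
                            condition = "c", replicate = 1L,
                            value = seq_len(nrow(layout6$probes)))
  pr6 <- average_probes(ratios6, layout6)
  expect_equal(nrow(pr6), nrow(layout6$probes))  # 299 distinct midpoints
  expect_true(all(diff(pr6$offset) > 0))
  expect_true(all(pr6$offset >= -1000 & pr6$offset < 1000))
})

test_that("probes missing from the layout are rejected", {
  loci <- tiny_loci(1)
  layout <- build_layout(loci)
  ratios <- tibble::tibble(probe_id = "nope", condition = "c",
                           replicate = 1L, value = 0)
  expect_error(average_probes(ratios, layout),
               class = "nucshift_preprocess_error")
})

test_that("minus-strand loci get a flipped, upstream-negative offset axis", {
  loci <- make_loci("M1", tss = 1000, strand = "-")
  layout <- build_layout(loci, both_strands = FALSE)
  ratios <- tibble::tibble(probe_id = layout$probes$probe_id, condition = "c",
                           replicate = 1L, value = 0)
  pr <- average_probes(ratios, layout)
  mids <- (layout$probes$start + layout$probes$end) %/% 2L
  expect_setequal(pr$offset, -(mids - 1000L))
})

test_that("replicate averaging is the position-wise mean and demands one grid", {
  p1 <- prof(1:10, rep(2, 10), replicate = "1")
  p2 <- prof(1:10, rep(-2, 10), replicate = "2")
  avg <- average_replicates(dplyr::bind_rows(p1, p2))
  expect_equal(avg$value, rep(0, 10))
  expect_equal(unique(avg$replicate), "averaged")

  same <- average_replicates(dplyr::bind_rows(p1, p1 |> dplyr::mutate(replicate = "2")))
  expect_equal(same$value, p1$value)

  set.seed(8)
  three <- dplyr::bind_rows(lapply(1:3, function(r)
    prof(1:20, rnorm(20), replicate = as.character(r))))
  avg3 <- average_replicates(three)
  oracle <- sapply(1:20, function(i) mean(three$value[three$offset == i]))
  expect_equal(avg3$value, oracle)

  bad <- dplyr::bind_rows(p1, prof(2:11, rep(1, 10), replicate = "2"))
  expect_error(average_replicates(bad), class = "nucshift_preprocess_error")
})

test_that("doubling both channels of every probe leaves profiles identical", {
  cfg <- sim_config(n_loci = 4L)
  exp <- generate_experiment(cfg, seed = 2)
  pr1 <- build_profiles(exp$signals, exp$layout)
  doubled <- dplyr::mutate(exp$signals, cy3 = 2 * cy3, cy5 = 2 * cy5)
  pr2 <- build_profiles(doubled, exp$layout)
  expect_equal(pr1, pr2, tolerance = 1e-12)
})

test_that("bin averaging conserves the grand mean for equally occupied bins", {
  loci <- tiny_loci(1)
  layout <- build_layout(loci, both_strands = TRUE, rev_offset = 0)
  set.seed(4)
  ratios <- tibble::tibble(probe_id = layout$probes$probe_id, condition = "c",
                           replicate = 1L, value = rnorm(nrow(layout$probes)))
  pr <- average_probes(ratios, layout)
  expect_equal(mean(pr$value), mean(ratios$value))
})

test_that("zero-noise profiles reproduce the protection track up to the affine map", {
  loci <- tiny_loci(1)
  cfg <- quiet_cfg(n_loci = 1L)
  layout <- build_layout(loci)
  set.seed(10)
  map <- sample_basal_map(loci[1, ], cfg)
  track <- protection_track(map, c(loci$window_start, loci$window_end))
  s <- simulate_intensities(list(L1 = track), layout, cfg, "c", 1)
  pr <- build_profiles(s, layout, method = "none")

  # oracle: per-probe mean protection computed by direct looping
  pbar <- sapply(seq_len(nrow(layout$probes)), function(i) {
    a <- layout$probes$start[i] - loci$window_start + 1L
    b <- layout$probes$end[i] - loci$window_start
    mean(track[a:b])
  })
  mids <- (layout$probes$start + layout$probes$end) %/% 2L - loci$tss
  oracle <- cfg$background_log2 + cfg$dynamic_range * pbar[order(mids)]
  expect_equal(pr$value, oracle, tolerance = 1e-10)
})

test_that("profiles round-trip through TSV", {
  p <- dplyr::bind_rows(prof(1:5, rnorm(5)), prof(1:5, rnorm(5), replicate = "2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(p, path)
  expect_equal(read_profiles(path), p)
})
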