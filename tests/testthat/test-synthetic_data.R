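test_that("basal maps are deterministic under a fixed seed and respect the window", {
  loci <- tiny_loci(1)
  cfg <- sim_config()
  set.seed(42); a <- sample_basal_map(loci[1, ], cfg)
  set.seed(42); b <- sample_basal_map(loci[1, ], cfg)
  expect_identical(a, b)
  expect_true(all(a$start >= loci$window_start))
  expect_true(all(a$end <= loci$window_end))
  expect_true(all(a$end - a$start == cfg$nuc_len))
  expect_true(all(diff(a$start) > 0))
  expect_true(all(utils::head(a$end, -1) <= utils::tail(a$start, -1)))
})

test_that("mean basal footprint count matches the renewal-process expectation", {
  loci <- tiny_loci(1)
  cfg <- sim_config(linker_mean = 50)
  set.seed(1)
  counts <- replicate(400, nrow(sample_basal_map(loci[1, ], cfg)))
  # expectation approx window / (nuc_len + linker_mean) = 2000/197 ~ 10
  expect_lt(abs(mean(counts) - 2000 / 197), 1)
})

test_that("a footprint longer than the window is an error", {
  loci <- tiny_loci(1)
  cfg <- sim_config(nuc_len = 2001L)
  expect_error(sample_basal_map(loci[1, ], cfg),
               class = "nucshift_sim_error")
})

test_that("eviction removes exactly the overlapping footprints", {
  loci <- tiny_loci(1)
  map <- tibble::tibble(locus_id = "L1",
                        start = c(200L, 600L, 1200L),
                        end = c(347L, 747L, 1347L), fuzz = 0)
  ev <- tibble::tibble(kind = "evict", target_start = -500L, target_end = -200L,
                       magnitude = NA_integer_)
  res <- apply_event(map, ev, loci[1, ])   # tss = 1000 -> target [500, 800)
  expect_true(res$realized)
  expect_equal(res$map$start, c(200L, 1200L))
})

test_that("shift translates an isolated footprint exactly", {
  loci <- tiny_loci(1)   # tss = 1000
  map <- tibble::tibble(locus_id = "L1", start = 800L, end = 947L, fuzz = 0)
  ev <- tibble::tibble(kind = "shift", target_start = -250L, target_end = -20L,
                       magnitude = 40L)
  res <- apply_event(map, ev, loci[1, ])
  expect_true(res$realized)
  expect_equal(res$map$start, 840L)
  expect_equal(res$map$end, 987L)
})

test_that("gain into a saturated window is unrealized, not an error", {
  loci <- make_loci("L1", tss = 1000, window_width = 600)
  # fully tile the window with footprints: no room anywhere
  starts <- seq(loci$window_start, loci$window_end - 147L, by = 147L)
  map <- tibble::tibble(locus_id = "L1", start = starts,
                        end = starts + 147L, fuzz = 0)
  ev <- tibble::tibble(kind = "gain", target_start = -100L, target_end = 100L,
                       magnitude = NA_integer_)
  res <- apply_event(map, ev, loci[1, ])
  expect_false(res$realized)
  expect_identical(res$map, map)
})

test_that("footprints stay non-overlapping under random event streams", {
  loci <- tiny_loci(1)
  cfg <- sim_config()
  set.seed(99)
  for (rep in 1:20) {
    map <- sample_basal_map(loci[1, ], cfg)
    for (k in 1:10) {
      ev <- tibble::tibble(
        kind = sample(c("evict", "gain", "shift"), 1),
        target_start = sample(-900:500, 1),
        magnitude = sample(c(-120:-40, 40:120), 1)
      )
      ev$target_end <- ev$target_start + sample(100:400, 1)
      map <- apply_event(map, ev, loci[1, ])$map
      if (nrow(map) > 1) {
        expect_true(all(diff(map$start) > 0))
        expect_true(all(utils::head(map$end, -1) <= utils::tail(map$start, -1)))
      }
      expect_true(all(map$start >= loci$window_start & map$end <= loci$window_end))
    }
  }
})

test_that("protection tracks are indicators at zero fuzz and conserve mass when fuzzy", {
  win <- c(0L, 1000L)
  empty <- tibble::tibble(locus_id = character(0), start = integer(0),
                          end = integer(0), fuzz = numeric(0))
  expect_equal(protection_track(empty, win), rep(0, 1000))

  map <- tibble::tibble(locus_id = "L1", start = 300L, end = 447L, fuzz = 0)
  tr <- protection_track(map, win)
  expect_equal(tr, as.numeric(seq(0, 999) >= 300 & seq(0, 999) < 447))

  map$fuzz <- 20
  tr <- protection_track(map, win)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_lt(abs(sum(tr) - 147), 1)   # numeric integration ~ nuc_len
})

test_that("noise-free intensities give the configured affine log-ratio", {
  loci <- tiny_loci(1)
  cfg <- quiet_cfg(n_loci = 1L)
  layout <- build_layout(loci)
  zero <- list(L1 = rep(0, 2000))
  full <- list(L1 = rep(1, 2000))
  s0 <- simulate_intensities(zero, layout, cfg, "c", 1)
  s1 <- simulate_intensities(full, layout, cfg, "c", 1)
  expect_equal(log2(s0$cy3 / s0$cy5), rep(cfg$background_log2, nrow(s0)))
  expect_equal(log2(s1$cy3 / s1$cy5) - log2(s0$cy3 / s0$cy5),
               rep(cfg$dynamic_range, nrow(s0)))
})

test_that("log-ratio noise matches the closed form for two log-normal channels", {
  loci <- make_loci("L1", tss = 5000, window_width = 9000)
  cfg <- sim_config(sigma_channel = 0.2, sigma_replicate = 0)
  layout <- build_layout(loci, both_strands = FALSE)  # ~680 probes
  tracks <- list(L1 = rep(0, 9000))
  set.seed(3)
  s <- simulate_intensities(tracks, layout, cfg, "c", 1)
  emp <- sd(log2(s$cy3 / s$cy5))
  expect_lt(abs(emp - sqrt(2) * 0.2 / log(2)) / (sqrt(2) * 0.2 / log(2)), 0.1)
})

test_that("expected log ratio is monotone in probe protection", {
  loci <- tiny_loci(1)
  cfg <- quiet_cfg(n_loci = 1L)
  layout <- build_layout(loci)
  for (p in list(c(0, 0.3), c(0.3, 0.9), c(0.9, 1))) {
    lo <- simulate_intensities(list(L1 = rep(p[1], 2000)), layout, cfg, "c", 1)
    hi <- simulate_intensities(list(L1 = rep(p[2], 2000)), layout, cfg, "c", 1)
    expect_true(all(log2(hi$cy3 / hi$cy5) > log2(lo$cy3 / lo$cy5)))
  }
})

test_that("generate_experiment honors fraction_changed and the seed", {
  cfg0 <- sim_config(n_loci = 20L, fraction_changed = 0)
  exp0 <- generate_experiment(cfg0, seed = 5)
  expect_false(any(exp0$truth$changed))
  expect_equal(nrow(exp0$events), 0L)

  cfg <- sim_config(n_loci = 200L, fraction_changed = 0.25,
                    revert_fraction = 0)
  exp1 <- generate_experiment(cfg, seed = 6)
  n_changed <- sum(exp1$truth$changed[exp1$truth$timepoint == "10min"])
  # binomial(200, 0.25): 3.5 sd ~ 21
  expect_lt(abs(n_changed - 50), 22)

  exp2 <- generate_experiment(cfg, seed = 6)
  expect_identical(exp1$signals, exp2$signals)
  expect_identical(exp1$truth, exp2$truth)
})

test_that("sim configs round-trip through YAML with defaults for absent keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_loci: 10", "sigma_channel: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_loci, 10)
  expect_equal(cfg$sigma_channel, 0.2)
  expect_equal(cfg$nuc_len, 147L)
  writeLines("not_a_key: 1", path)
  expect_error(read_sim_config(path), class = "nucshift_sim_error")
})
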