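revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("the intrinsic score is exactly strand-symmetric", {
  polyA <- strrep("A", 400)
  sA <- intrinsic_score(polyA)
  sT <- intrinsic_score(revcomp(polyA))
  expect_equal(sA$score, sT$score)

  for (seed in 1:3) {
    s <- rand_seq(500, seed)
    fwd <- intrinsic_score(s)$score
    rev <- intrinsic_score(revcomp(s))$score
    expect_equal(rev, rev(fwd), tolerance = 1e-12)
  }
})

test_that("10-bp-phased WW dinucleotides outscore the same bases permuted", {
  set.seed(51)
  # build a 500-bp G/C background with AA planted every 10 bp
  bg <- sample(c("G", "C"), 500, replace = TRUE)
  phased <- bg
  at <- seq(1, 499, by = 10)
  phased[at] <- "A"; phased[at + 1] <- "A"
  permuted <- sample(phased)                 # same composition, no phasing
  sp <- intrinsic_score(paste(phased, collapse = ""))
  # compare raw means of the in-phase term via the unnormalized difference:
  # same base composition, so the GC term cancels in expectation
  sr <- intrinsic_score(paste(permuted, collapse = ""))
  # the phased sequence must concentrate WW in one phase class
  raw_gap <- function(chars) {
    ww <- chars[-length(chars)] %in% c("A", "T") & chars[-1] %in% c("A", "T")
    ph <- ((seq_along(ww) - 1) %% 10)
    max(table(factor(ph[ww], levels = 0:9))) / max(sum(ww), 1)
  }
  expect_gt(raw_gap(phased), raw_gap(permuted))
  # and the z-track of the phased sequence must have structure where planted
  expect_gt(sd(sp$score), 0)
  expect_gt(sd(sr$score), 0)
})

test_that("degenerate sequences yield a flagged constant track", {
  sN <- intrinsic_score(strrep("N", 300))
  expect_true(attr(sN, "degenerate"))
  expect_true(all(sN$score == 0))
  expect_error(intrinsic_score("ACGT"), class = "nucshift_model_error")
})

test_that("model tracks are z-normalized on the profile grid", {
  loci <- tiny_loci(2)
  seqs <- synthetic_sequences(loci, seed = 52)
  grid <- seq(-950L, 950L, by = 10L)
  mt <- model_track_from_sequences(seqs, loci, grid)
  per <- split(mt$score, mt$locus_id)
  for (s in per) {
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(sd(s), 1, tolerance = 1e-12)
  }
  expect_setequal(unique(mt$offset), grid)
})

test_that("external tracks load from TSV, resample, and reject constants and gaps", {
  loci <- tiny_loci(2)
  grid <- seq(-900L, 900L, by = 20L)
  dense <- expand.grid(locus_id = loci$locus_id,
                       offset = seq(-1000L, 999L, by = 10L),
                       stringsAsFactors = FALSE)
  set.seed(53)
  dense$score <- rnorm(nrow(dense))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dense, path)
  mt <- load_model_track(path, loci, grid)
  expect_setequal(unique(mt$offset), grid)
  # values at shared positions survive resampling (up to the z-rescale)
  one <- dense[dense$locus_id == "L1" & dense$offset %in% grid, ]
  got <- mt[mt$locus_id == "L1", ]
  expect_equal(cor(got$score[match(one$offset, got$offset)], one$score), 1,
               tolerance = 1e-12)

  const <- dense; const$score <- 1
  readr::write_tsv(const, path)
  expect_error(load_model_track(path, loci, grid),
               class = "nucshift_model_error")

  gap <- dense[dense$locus_id == "L1", ]
  readr::write_tsv(gap, path)
  err <- expect_error(load_model_track(path, loci, grid),
                      class = "nucshift_model_error")
  expect_match(conditionMessage(err), "L2")
})

test_that("a profile equal to the model correlates at 1 and scores directed", {
  set.seed(54)
  grid <- seq(-500L, 500L, by = 10L)
  z <- as.numeric(scale(rnorm(length(grid))))
  model <- tibble::tibble(locus_id = "L1", offset = grid, score = z)
  treated <- prof(grid, z)
  control <- prof(grid, rnorm(length(grid)))
  sc <- score_locus(control, treated, model)
  expect_equal(sc$r_treated_model, 1.0)
  expect_equal(sc$difference_score, 1 - sc$r_control_model)
  expect_true(sc$dna_directed)
})

test_that("model scoring is invariant to affine rescaling of the inputs", {
  set.seed(55)
  grid <- seq(-500L, 500L, by = 10L)
  model <- tibble::tibble(locus_id = "L1", offset = grid,
                          score = as.numeric(scale(rnorm(length(grid)))))
  control <- prof(grid, rnorm(length(grid)))
  treated <- prof(grid, rnorm(length(grid)))
  a <- score_locus(control, treated, model)
  b <- score_locus(dplyr::mutate(control, value = 3 * value + 7),
                   dplyr::mutate(treated, value = 0.2 * value - 1), model)
  expect_equal(a$r_control_model, b$r_control_model, tolerance = 1e-12)
  expect_equal(a$r_treated_model, b$r_treated_model, tolerance = 1e-12)
})

test_that("the HDAC1/CXCL6-style threshold logic separates directed from independent", {
  grid <- seq(-500L, 500L, by = 10L)
  set.seed(56)
  z <- as.numeric(scale(rnorm(length(grid))))
  model <- tibble::tibble(locus_id = "L1", offset = grid, score = z)
  control <- prof(grid, rnorm(length(grid)))

  # treated profile correlating ~0.82 with the model: directed
  hi <- z + rnorm(length(grid), sd = sqrt(1 / 0.82^2 - 1))
  sc_hi <- score_locus(control, prof(grid, hi), model)
  expect_gte(sc_hi$r_treated_model, 0.7)
  expect_true(sc_hi$dna_directed)

  # treated profile correlating ~0.62: below the directed threshold
  lo <- z + rnorm(length(grid), sd = sqrt(1 / 0.62^2 - 1) * 1.3)
  sc_lo <- score_locus(control, prof(grid, lo), model)
  expect_false(sc_lo$dna_directed)
})

test_that("directed_fraction handles empty and indeterminate sets", {
  scores <- tibble::tibble(locus_id = c("a", "b", "c"),
                           dna_directed = c(TRUE, FALSE, NA))
  expect_true(is.na(directed_fraction(scores, character(0))))
  expect_equal(directed_fraction(scores, c("a", "b", "c")), 0.5)
})

test_that("model-directed events are recovered and orthogonal ones are not", {
  mc <- simulate_model_comparison(sim_config(), seed = 57, n_loci = 20L)
  m <- dplyr::inner_join(mc$scores, mc$truth, by = "locus_id")
  expect_gte(mean(m$dna_directed[m$directed], na.rm = TRUE), 0.8)
  expect_lte(mean(m$dna_directed[!m$directed], na.rm = TRUE), 0.2)
})
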