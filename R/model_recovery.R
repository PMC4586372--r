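#' Profile position grid of a layout
#'
#' The sorted unique TSS-relative probe-midpoint offsets — the grid on
#' which profiles and model tracks live.
#'
#' @param layout A `probe_layout`.
#' @return Sorted integer vector of offsets.
#' @export
profile_grid <- function(layout) {
  p <- layout$probes
  li <- match(p$locus_id, layout$loci$locus_id)
  off <- probe_midpoint(p) - layout$loci$tss[li]
  off <- ifelse(layout$loci$strand[li] == "-", -off, off)
  sort(unique(as.integer(off)))
}

# Per-base occupancy in [0,1] obtained by relaxing toward a z-scaled
# sequence score: logistic link, so high-scoring DNA is occupied.
occupancy_from_score <- function(z) stats::plogis(z)

# Per-base intrinsic-score track across a full locus window (edges padded).
intrinsic_track_per_base <- function(seq, window_width, ...) {
  sc <- intrinsic_score(seq, ...)
  x <- seq_len(window_width)
  approx(sc$pos, sc$score, xout = x, rule = 2)$y
}

#' Simulate a model-directed versus model-orthogonal comparison
#'
#' Generates loci with synthetic window sequences and a basal (random)
#' nucleosome map as the control state. Half of the loci relax toward
#' their own intrinsic sequence score in the treated state (model-directed
#' repositioning); the other half relax toward the score of an unrelated
#' decoy sequence (model-orthogonal repositioning). Intensities are
#' simulated for both states, profiles rebuilt, and every locus scored
#' against its model track — the ground truth for validating the
#' DNA-directed classification.
#'
#' @param cfg A `sim_config` (noise and design parameters are used;
#'   `n_loci` is overridden by `n_loci` here).
#' @param seed Integer seed.
#' @param n_loci Number of loci (default 60).
#' @return List with `scores` (per-locus [score_locus()] rows),
#'   `truth` (tibble `locus_id`, `directed`), `profiles`, `model`.
#' @export
simulate_model_comparison <- function(cfg = sim_config(), seed,
                                      n_loci = 60L) {
  set.seed(as.integer(seed))
  loci <- make_loci(sprintf("M%03d", seq_len(n_loci)),
                    tss = 2000L + (seq_len(n_loci) - 1L) * 5000L,
                    window_width = cfg$window_width)
  layout <- build_layout(loci, cfg$probe_len, cfg$overlap,
                         cfg$both_strands, cfg$rev_offset)
  seqs <- synthetic_sequences(loci, seed)
  decoys <- synthetic_sequences(loci, seed + 1000L)
  grid <- profile_grid(layout)
  model <- model_track_from_sequences(seqs, loci, grid)

  directed <- rep(c(TRUE, FALSE), length.out = n_loci)
  w <- cfg$window_width

  control_tracks <- lapply(seq_len(n_loci), function(i) {
    m <- sample_basal_map(loci[i, ], cfg, ndr = FALSE)
    protection_track(m, c(loci$window_start[i], loci$window_end[i]))
  })
  names(control_tracks) <- loci$locus_id

  treated_tracks <- lapply(seq_len(n_loci), function(i) {
    src <- if (directed[i]) seqs[[i]] else decoys[[i]]
    occupancy_from_score(intrinsic_track_per_base(as.character(src), w))
  })
  names(treated_tracks) <- loci$locus_id

  signals <- dplyr::bind_rows(
    lapply(seq_len(cfg$replicates), function(r)
      simulate_intensities(control_tracks, layout, cfg, "control", r)),
    lapply(seq_len(cfg$replicates), function(r)
      simulate_intensities(treated_tracks, layout, cfg, "treated", r))
  )
  profiles <- build_profiles(signals, layout)
  scores <- score_all(profiles, model, condition = "treated")

  list(scores = scores,
       truth = tibble::tibble(locus_id = loci$locus_id, directed = directed),
       profiles = profiles, model = model)
}
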