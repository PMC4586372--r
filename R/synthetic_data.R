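#' Simulation configuration
#'
#' Bundles every parameter of the synthetic two-channel experiment. The
#' defaults emulate the study design this pipeline targets: 858 loci on
#' 2-kb TSS-centered windows, 60-mer probes tiled at a 13-bp step on both
#' strands, nucleosome footprints of 147 bp, two biological replicates, a
#' drug-naive control plus three treatment time points, and repositioning
#' events injected at a quarter of the loci.
#'
#' Intensity model per probe: the genomic channel (Cy5) has expectation
#' `baseline`; the nucleosomal channel (Cy3) has expectation
#' `baseline * 2^(background_log2 + dynamic_range * p)` where `p` is the
#' mean MNase-protection over the probe interval. Both channels carry
#' independent multiplicative log-normal noise (`sigma_channel`, sd on the
#' natural-log scale) and a shared per-array log-normal batch effect
#' (`sigma_replicate`). The expected log2 ratio is therefore affine and
#' monotone in `p`, crossing zero mid-protection so that occupied DNA sits
#' above the zero line and naked linker below it.
#'
#' @param n_loci Number of loci.
#' @param window_width Window width bp.
#' @param probe_len,overlap,both_strands,rev_offset Probe tiling, see
#'   [build_layout()].
#' @param nuc_len Nucleosome footprint length bp (147).
#' @param linker_mean Mean linker (exponential) between footprints, bp.
#' @param fuzz_sd Positional fuzziness s.d. per footprint, bp.
#' @param ndr_fraction Fraction of loci given a nucleosome-depleted region
#'   over the TSS in the basal state.
#' @param ndr_interval NDR interval relative to the TSS, bp.
#' @param baseline Genomic-channel expected intensity.
#' @param background_log2 Expected log2 ratio of a fully naked probe.
#' @param dynamic_range Log2-ratio gain from naked to fully protected.
#' @param sigma_channel Per-channel log-normal noise sd (natural log).
#' @param sigma_replicate Per-array batch-effect log-normal sd.
#' @param replicates Biological replicates per condition.
#' @param timepoints Ordered treatment time-point labels.
#' @param fraction_changed Fraction of loci receiving repositioning events.
#' @param event_mix Named probabilities for event kinds
#'   (`shift`, `evict`, `gain`).
#' @param shift_range Range (bp) from which shift magnitudes are drawn.
#' @param evict_interval Eviction target interval relative to TSS.
#' @param revert_fraction Fraction of event loci whose events revert
#'   (offset) at a later time point, restoring the basal state.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 858L,
                       window_width = 2000L,
                       probe_len = 60L, overlap = 47L,
                       both_strands = TRUE, rev_offset = 6L,
                       nuc_len = 147L,
                       linker_mean = 50,
                       fuzz_sd = 10,
                       ndr_fraction = 0.6,
                       ndr_interval = c(-150L, 50L),
                       baseline = 1000,
                       background_log2 = -1.5,
                       dynamic_range = 3,
                       sigma_channel = 0.15,
                       sigma_replicate = 0.05,
                       replicates = 2L,
                       timepoints = c("10min", "60min", "90min"),
                       fraction_changed = 0.25,
                       event_mix = c(shift = 0.5, evict = 0.3, gain = 0.2),
                       shift_range = c(80L, 140L),
                       evict_interval = c(-500L, 500L),
                       revert_fraction = 0.2) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$fraction_changed >= 0, cfg$fraction_changed <= 1,
    cfg$ndr_fraction >= 0, cfg$ndr_fraction <= 1,
    cfg$revert_fraction >= 0, cfg$revert_fraction <= 1,
    cfg$sigma_channel >= 0, cfg$sigma_replicate >= 0,
    cfg$replicates >= 1, cfg$nuc_len > 0, cfg$linker_mean >= 0
  )
  if (abs(sum(cfg$event_mix) - 1) > 1e-8 || any(cfg$event_mix < 0)) {
    nucshift_abort("event_mix must be non-negative and sum to 1",
                   "nucshift_sim_error")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys absent from the file keep their [sim_config()] defaults.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    nucshift_abort(paste("unknown sim_config keys:", paste(bad, collapse = ", ")),
                   "nucshift_sim_error")
  }
  if (!is.null(vals$event_mix)) vals$event_mix <- unlist(vals$event_mix)
  do.call(sim_config, vals)
}

# ---- nucleosome maps -------------------------------------------------------

#' Sample a basal (drug-naive) nucleosome map for one locus
#'
#' Footprints of `nuc_len` bp are laid down left to right with exponential
#' linkers of mean `linker_mean`, giving a stationary placement with mean
#' period `nuc_len + linker_mean`. With `ndr = TRUE`, footprints overlapping
#' the configured TSS-relative NDR interval are removed afterwards,
#' emulating the nucleosome-depleted region of an accessible promoter.
#'
#' @param locus One-row locus tibble.
#' @param cfg A `sim_config`.
#' @param ndr Force a nucleosome-depleted region over the TSS?
#' @return A nucleosome map: tibble with `locus_id`, `start`, `end`, `fuzz`,
#'   footprints sorted and non-overlapping.
#' @export
sample_basal_map <- function(locus, cfg, ndr = FALSE) {
  ws <- locus$window_start; we <- locus$window_end
  if (cfg$nuc_len > we - ws) {
    nucshift_abort("nuc_len exceeds the locus window", "nucshift_sim_error")
  }
  starts <- integer(0)
  pos <- ws
  repeat {
    gap <- if (cfg$linker_mean > 0) stats::rexp(1, 1 / cfg$linker_mean) else 0
    s <- as.integer(round(pos + gap))
    if (s + cfg$nuc_len > we) break
    starts <- c(starts, s)
    pos <- s + cfg$nuc_len
  }
  map <- tibble::tibble(
    locus_id = locus$locus_id,
    start = starts,
    end = starts + as.integer(cfg$nuc_len),
    fuzz = rep(cfg$fuzz_sd, length(starts))
  )
  if (ndr && nrow(map)) {
    a <- locus$tss + cfg$ndr_interval[1]
    b <- locus$tss + cfg$ndr_interval[2]
    map <- map[!(map$start < b & map$end > a), ]
  }
  map
}

#' Apply a repositioning event to a nucleosome map
#'
#' Three event kinds are supported, all targeting a TSS-relative interval:
#' `evict` removes footprints overlapping the target; `gain` inserts one
#' footprint centered in the target if space permits; `shift` translates the
#' footprints overlapping the target by `magnitude` bp, dropping any shifted
#' footprint that would collide with a stationary one or leave the window.
#' An event that cannot alter the map (nothing to evict or shift, no room to
#' gain) is recorded as unrealized, not an error.
#'
#' @param map Nucleosome map tibble.
#' @param event One-row event tibble with `kind`, `target_start`,
#'   `target_end` (TSS-relative), `magnitude`.
#' @param locus One-row locus tibble (for TSS and window bounds).
#' @return List with `map` (invariants preserved) and `realized` (logical).
#' @export
apply_event <- function(map, event, locus) {
  a <- locus$tss + event$target_start
  b <- locus$tss + event$target_end
  hit <- map$start < b & map$end > a
  nuc_len <- if (nrow(map)) map$end[1] - map$start[1] else 147L

  if (event$kind == "evict") {
    out <- map[!hit, ]
    return(list(map = out, realized = any(hit)))
  }

  if (event$kind == "gain") {
    center <- (a + b) %/% 2L
    s <- as.integer(center - nuc_len %/% 2L)
    e <- s + as.integer(nuc_len)
    room <- s >= locus$window_start && e <= locus$window_end &&
      !any(map$start < e & map$end > s)
    if (!room) return(list(map = map, realized = FALSE))
    new <- tibble::tibble(locus_id = locus$locus_id, start = s, end = e,
                          fuzz = if (nrow(map)) map$fuzz[1] else 0)
    out <- dplyr::arrange(dplyr::bind_rows(map, new), .data$start)
    return(list(map = out, realized = TRUE))
  }

  if (event$kind == "shift") {
    if (!any(hit)) return(list(map = map, realized = FALSE))
    moved <- map[hit, ]
    moved$start <- moved$start + as.integer(event$magnitude)
    moved$end <- moved$end + as.integer(event$magnitude)
    keep <- moved$start >= locus$window_start & moved$end <= locus$window_end
    still <- map[!hit, ]
    if (nrow(still)) {
      for (i in seq_len(nrow(moved))) {
        if (keep[i] && any(still$start < moved$end[i] & still$end > moved$start[i])) {
          keep[i] <- FALSE
        }
      }
    }
    out <- dplyr::arrange(dplyr::bind_rows(still, moved[keep, ]), .data$start)
    return(list(map = out, realized = TRUE))
  }

  nucshift_abort(paste("unknown event kind:", event$kind), "nucshift_sim_error")
}

#' Per-base MNase-protection track of a nucleosome map
#'
#' The expected protection is 1 under a footprint core and 0 in naked
#' linker; positional fuzziness smooths each footprint edge with a Gaussian
#' kernel of the footprint's `fuzz` s.d., so the track still integrates to
#' approximately `nuc_len` per footprint.
#'
#' @param map Nucleosome map tibble (possibly empty).
#' @param window Integer pair `c(start, end)`, half-open.
#' @return Numeric vector of length `end - start`, values in \[0, 1\].
#' @export
protection_track <- function(map, window) {
  n <- window[2] - window[1]
  x <- seq.int(window[1], window[2] - 1L) + 0.5
  track <- numeric(n)
  for (i in seq_len(nrow(map))) {
    s <- map$start[i]; e <- map$end[i]; f <- map$fuzz[i]
    if (is.na(f) || f <= 0) {
      track <- track + as.numeric(x > s & x < e)
    } else {
      track <- track + (pnorm((x - s) / f) - pnorm((x - e) / f))
    }
  }
  pmin(track, 1)
}

# Mean protection over each probe interval, for all probes of the layout.
# `tracks` is a named list: locus_id -> per-base track over the locus window.
probe_protection <- function(tracks, layout) {
  p <- layout$probes
  loci <- layout$loci
  out <- numeric(nrow(p))
  for (lid in names(tracks)) {
    idx <- which(p$locus_id == lid)
    if (!length(idx)) next
    ws <- loci$window_start[loci$locus_id == lid]
    cs <- c(0, cumsum(tracks[[lid]]))
    s <- p$start[idx] - ws
    e <- p$end[idx] - ws
    out[idx] <- (cs[e + 1L] - cs[s + 1L]) / (e - s)
  }
  out
}

# ---- intensities -----------------------------------------------------------

#' Simulate one two-channel array from protection tracks
#'
#' @param tracks Named list `locus_id -> per-base protection track`.
#' @param layout A `probe_layout`.
#' @param cfg A `sim_config`.
#' @param condition,replicate Labels stamped on the output rows.
#' @return Tibble `probe_id`, `condition`, `replicate`, `cy3`, `cy5`
#'   (one row per probe; all intensities positive).
#' @export
simulate_intensities <- function(tracks, layout, cfg, condition, replicate) {
  pbar <- probe_protection(tracks, layout)
  n <- length(pbar)
  mu3 <- cfg$baseline * 2^(cfg$background_log2 + cfg$dynamic_range * pbar)
  mu5 <- rep(cfg$baseline, n)
  batch3 <- rlnorm(1, 0, cfg$sigma_replicate)
  batch5 <- rlnorm(1, 0, cfg$sigma_replicate)
  tibble::tibble(
    probe_id = layout$probes$probe_id,
    condition = condition,
    replicate = as.integer(replicate),
    cy3 = mu3 * batch3 * rlnorm(n, 0, cfg$sigma_channel),
    cy5 = mu5 * batch5 * rlnorm(n, 0, cfg$sigma_channel)
  )
}

# ---- full experiment -------------------------------------------------------

#' Generate a complete synthetic drug time-course experiment
#'
#' Builds the locus table and probe layout, samples a basal nucleosome map
#' per locus, injects repositioning events at `fraction_changed` of the loci
#' (onset at the first time point; a `revert_fraction` of event loci revert
#' to the basal state at a random later time point), derives per-condition
#' protection tracks, and simulates `replicates` arrays for the control and
#' every time point. The truth table marks a locus as changed at a time
#' point iff at least one realized event is active then.
#'
#' @param cfg A `sim_config`.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return List with `loci`, `layout`, `signals` (all arrays, long tibble),
#'   `truth` (`locus_id`, `timepoint`, `changed`), `events`, `maps` (named
#'   list of per-condition nucleosome maps), `tracks`, `cfg`, `seed`.
#' @export
generate_experiment <- function(cfg, seed) {
  set.seed(as.integer(seed))
  n <- cfg$n_loci
  loci <- make_loci(sprintf("L%04d", seq_len(n)),
                    tss = 2000L + (seq_len(n) - 1L) * 5000L,
                    window_width = cfg$window_width)
  layout <- build_layout(loci, cfg$probe_len, cfg$overlap,
                         cfg$both_strands, cfg$rev_offset)

  ndr <- runif(n) < cfg$ndr_fraction
  basal <- lapply(seq_len(n), function(i)
    sample_basal_map(loci[i, ], cfg, ndr = ndr[i]))
  names(basal) <- loci$locus_id

  events <- sample_events(loci, cfg)

  conditions <- c("control", cfg$timepoints)
  maps <- list(control = basal)
  realized <- list()
  for (tp in cfg$timepoints) {
    st <- apply_active_events(basal, events, loci, tp, cfg$timepoints)
    maps[[tp]] <- st$maps
    realized[[tp]] <- st$realized
  }

  truth <- truth_table(loci, events, realized, cfg$timepoints)

  tracks <- lapply(maps, function(mm) {
    tr <- lapply(seq_len(n), function(i)
      protection_track(mm[[i]], c(loci$window_start[i], loci$window_end[i])))
    names(tr) <- loci$locus_id
    tr
  })

  signals <- dplyr::bind_rows(lapply(conditions, function(cond) {
    dplyr::bind_rows(lapply(seq_len(cfg$replicates), function(r)
      simulate_intensities(tracks[[cond]], layout, cfg, cond, r)))
  }))

  list(loci = loci, layout = layout, signals = signals, truth = truth,
       events = events, maps = maps, tracks = tracks, cfg = cfg,
       seed = as.integer(seed))
}

# Draw the event table: one shift or evict event, or a trio of gain events,
# per selected locus. Shift direction is random; magnitudes span roughly a
# half nucleosomal repeat so treated profiles decorrelate from the basal one.
sample_events <- function(loci, cfg) {
  changed <- runif(nrow(loci)) < cfg$fraction_changed
  rows <- list()
  tps <- cfg$timepoints
  for (i in which(changed)) {
    kind <- sample(names(cfg$event_mix), 1, prob = cfg$event_mix)
    onset <- tps[1]
    offset <- NA_character_
    if (length(tps) > 1 && runif(1) < cfg$revert_fraction) {
      offset <- sample(tps[-1], 1)
    }
    half <- cfg$window_width %/% 2L
    if (kind == "shift") {
      mag <- sample(seq(cfg$shift_range[1], cfg$shift_range[2]), 1) *
        sample(c(-1L, 1L), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[i], kind = "shift",
        target_start = -half, target_end = half,
        magnitude = mag, onset = onset, offset = offset)
    } else if (kind == "evict") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[i], kind = "evict",
        target_start = cfg$evict_interval[1], target_end = cfg$evict_interval[2],
        magnitude = NA_integer_, onset = onset, offset = offset)
    } else {
      centers <- c(-600L, -150L, 300L) + sample(-50:50, 3, replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[i], kind = "gain",
        target_start = centers - cfg$nuc_len %/% 2L,
        target_end = centers + cfg$nuc_len %/% 2L,
        magnitude = NA_integer_, onset = onset, offset = offset)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(locus_id = character(), kind = character(),
                          target_start = integer(), target_end = integer(),
                          magnitude = integer(), onset = character(),
                          offset = character()))
  }
  dplyr::bind_rows(rows)
}

event_active <- function(events, tp, timepoints) {
  ti <- match(tp, timepoints)
  on <- match(events$onset, timepoints)
  off <- match(events$offset, timepoints)
  on <= ti & (is.na(off) | off > ti)
}

# Apply every active event (in table order) to each locus's basal map.
apply_active_events <- function(basal, events, loci, tp, timepoints) {
  maps <- basal
  realized <- logical(nrow(events))
  if (nrow(events)) {
    active <- event_active(events, tp, timepoints)
    for (j in which(active)) {
      lid <- events$locus_id[j]
      locus <- loci[loci$locus_id == lid, ]
      res <- apply_event(maps[[lid]], events[j, ], locus)
      maps[[lid]] <- res$map
      realized[j] <- res$realized
    }
  }
  list(maps = maps, realized = realized)
}

truth_table <- function(loci, events, realized, timepoints) {
  out <- expand.grid(locus_id = loci$locus_id, timepoint = timepoints,
                     stringsAsFactors = FALSE)
  out$changed <- FALSE
  for (tp in timepoints) {
    if (!nrow(events)) next
    act <- event_active(events, tp, timepoints) & realized[[tp]]
    ch <- unique(events$locus_id[act])
    out$changed[out$timepoint == tp & out$locus_id %in% ch] <- TRUE
  }
  tibble::as_tibble(out[order(out$timepoint, out$locus_id), ])
}

# ---- synthetic sequence ----------------------------------------------------

#' Generate synthetic locus-window DNA sequences
#'
#' Random sequence at a given GC content, with a configurable fraction of
#' each window carrying 10-bp-phased AA/TT dinucleotides so the intrinsic
#' sequence score has genuine structure to find. One record per locus,
#' record ID = locus_id, window-length sequences.
#'
#' @param loci Locus table.
#' @param seed Integer seed.
#' @param gc GC content of the random background.
#' @param phased_fraction Fraction of each window length covered by one
#'   contiguous phased-WW block (0 disables).
#' @return A [Biostrings::DNAStringSet] named by locus_id.
#' @export
synthetic_sequences <- function(loci, seed, gc = 0.41, phased_fraction = 0.3) {
  set.seed(as.integer(seed))
  seqs <- vapply(seq_len(nrow(loci)), function(i) {
    w <- loci$window_end[i] - loci$window_start[i]
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- sample(names(p), w, replace = TRUE, prob = p)
    if (phased_fraction > 0) {
      block <- as.integer(round(w * phased_fraction))
      at <- sample.int(w - block, 1)
      idx <- seq.int(at, at + block - 1L)
      # plant WW dinucleotides every 10 bp within the block
      ww_at <- idx[seq(1, length(idx) - 1L, by = 10L)]
      s[ww_at] <- sample(c("A", "T"), length(ww_at), replace = TRUE)
      s[ww_at + 1L] <- sample(c("A", "T"), length(ww_at), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, loci$locus_id))
}

#' Write and read experiment tables
#'
#' Intensities are stored as TSV (`probe_id`, `condition`, `replicate`,
#' `cy3`, `cy5`), the truth table as TSV (`locus_id`, `timepoint`,
#' `changed`).
#'
#' @param signals,truth Tibbles as produced by [generate_experiment()].
#' @param path Output file.
#' @return The path, invisibly (writers); a tibble (readers).
#' @export
write_signals <- function(signals, path) {
  readr::write_tsv(signals, path)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(probe_id = "c", condition = "c",
                                          replicate = "i", cy3 = "d", cy5 = "d"))
}

#' @rdname write_signals
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(locus_id = "c", timepoint = "c",
                                          changed = "l"))
}
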