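#' Intrinsic (sequence-directed) nucleosome occupancy score
#'
#' A deliberately simple, strand-symmetric stand-in for published
#' sequence-based occupancy models: for every position at which a full
#' `nuc_len` window fits, the score combines (i) the in-phase fraction of
#' WW (AA/AT/TA/TT) dinucleotides at a 10-bp period within the window —
#' the rotational-positioning signal — and (ii) the window G+C fraction,
#' with weights `w1` and `w2`. Scores are z-normalized over the sequence.
#' Bases `N` contribute to neither term. The score is exactly
#' strand-symmetric: a sequence and its reverse complement give the same
#' (mirrored) track. Any externally computed per-base occupancy track can
#' be used instead via [load_model_track()].
#'
#' @param seq A single DNA string (character or [Biostrings::DNAString]),
#'   alphabet `A`, `C`, `G`, `T`, `N`; length >= `nuc_len`.
#' @param nuc_len Window length (147).
#' @param period Dinucleotide phasing period, bp (10).
#' @param w1,w2 Weights of the phasing and GC terms.
#' @return Tibble `pos` (1-based center position), `score` (z-scaled).
#'   If the raw score is constant the track is degenerate: scores are all
#'   zero and the attribute `degenerate` is `TRUE`.
#' @export
intrinsic_score <- function(seq, nuc_len = 147L, period = 10L,
                            w1 = 1, w2 = 0.5) {
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  if (L < nuc_len) {
    nucshift_abort("sequence shorter than nuc_len", "nucshift_model_error")
  }
  half <- nuc_len %/% 2L
  is_w <- chars %in% c("A", "T")
  is_gc <- chars %in% c("G", "C")
  ww <- is_w[-L] & is_w[-1L]          # dinucleotide starts 1..L-1

  # windowed counts via cumsums; center c covers bases (c-half)..(c+half),
  # dinucleotide starts (c-half)..(c+half-1)
  centers <- seq.int(half + 1L, L - half)
  cgc <- c(0, cumsum(is_gc))
  gc_frac <- (cgc[centers + half + 1L] - cgc[centers - half]) / nuc_len

  # per-phase WW counts within each window (phase of absolute start mod period)
  phase <- (seq_len(L - 1L) - 1L) %% period
  cnt <- matrix(0, nrow = length(centers), ncol = period)
  for (p in seq_len(period) - 1L) {
    wp <- c(0, cumsum(ww & phase == p))
    cnt[, p + 1L] <- wp[centers + half] - wp[centers - half]
  }
  cww <- c(0, cumsum(ww))
  tot <- cww[centers + half] - cww[centers - half]
  in_phase <- apply(cnt, 1L, max) / pmax(tot, 1L)

  raw <- w1 * in_phase + w2 * gc_frac
  sdr <- sd(raw)
  if (is.na(sdr) || sdr == 0) {
    out <- tibble::tibble(pos = centers, score = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- tibble::tibble(pos = centers, score = (raw - mean(raw)) / sdr)
  attr(out, "degenerate") <- FALSE
  out
}

#' Model track over the profile grid for a set of loci
#'
#' Scores each locus-window sequence with [intrinsic_score()] and resamples
#' the per-base track onto the occupancy-profile position grid by linear
#' interpolation, then re-z-normalizes per locus on that grid.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or named character vector),
#'   one window sequence per locus, names = locus ids. Each sequence must
#'   span its locus window.
#' @param loci Locus table.
#' @param grid Integer vector of TSS-relative profile offsets on which to
#'   evaluate the model (e.g. `sort(unique(profiles$offset))`).
#' @param ... Passed to [intrinsic_score()].
#' @return Model track tibble: `locus_id`, `offset`, `score`.
#' @export
model_track_from_sequences <- function(seqs, loci, grid, ...) {
  ids <- names(seqs)
  if (is.null(ids) || !all(loci$locus_id %in% ids)) {
    nucshift_abort("sequences must be named and cover every locus",
                   "nucshift_model_error")
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    lid <- loci$locus_id[i]
    sc <- intrinsic_score(as.character(seqs[[match(lid, ids)]]), ...)
    # pos is 1-based within the window; convert to TSS-relative offsets
    off <- sc$pos - 1L + loci$window_start[i] - loci$tss[i]
    if (loci$strand[i] == "-") off <- -off
    ord <- order(off)
    tibble::tibble(locus_id = lid,
                   offset = as.integer(grid),
                   score = approx(off[ord], sc$score[ord], xout = grid,
                                  rule = 2)$y)
  })
  dplyr::bind_rows(out) |> znorm_track()
}

znorm_track <- function(track) {
  track |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::mutate(score = {
      s <- sd(.data$score)
      if (is.na(s) || s == 0)
        nucshift_abort(sprintf("constant model track at locus %s",
                               .data$locus_id[1]), "nucshift_model_error")
      (.data$score - mean(.data$score)) / s
    }) |>
    dplyr::ungroup()
}

#' Load an external per-base occupancy-model track
#'
#' Accepts a TSV (`locus_id`, `offset`, `score`; TSS-relative offsets) or a
#' wiggle file in genomic coordinates (resolved against the locus table).
#' The track is resampled onto the requested profile grid by linear
#' interpolation and z-normalized per locus. Loci whose windows are not
#' covered raise an error naming them.
#'
#' @param path Track file (`.wig` or TSV).
#' @param loci Locus table.
#' @param grid Integer vector of TSS-relative profile offsets.
#' @return Model track tibble: `locus_id`, `offset`, `score`.
#' @export
load_model_track <- function(path, loci, grid) {
  if (grepl("\\.wig$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import.wig(path)
    pos <- GenomicRanges::start(gr) - 1L   # back to 0-based
    val <- gr$score
    chr <- as.character(GenomicRanges::seqnames(gr))
    tab <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
      sel <- chr == loci$chrom[i] & pos >= loci$window_start[i] &
        pos < loci$window_end[i]
      off <- pos[sel] - loci$tss[i]
      if (loci$strand[i] == "-") off <- -off
      tibble::tibble(locus_id = loci$locus_id[i], offset = off,
                     score = val[sel])
    }))
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(locus_id = "c",
                                                   offset = "i", score = "d"))
  }
  missing <- setdiff(loci$locus_id, unique(tab$locus_id))
  covered <- tab |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(lo = min(.data$offset), hi = max(.data$offset),
                     .groups = "drop")
  gaps <- covered$locus_id[covered$lo > min(grid) | covered$hi < max(grid)]
  bad <- union(missing, gaps)
  if (length(bad)) {
    nucshift_abort(paste("model track does not cover loci:",
                         paste(sort(bad), collapse = ", ")),
                   "nucshift_model_error")
  }
  tab |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::reframe(score = approx(.data$offset, .data$score, xout = grid,
                                  rule = 2)$y,
                   offset = as.integer(grid)) |>
    dplyr::select("locus_id", "offset", "score") |>
    znorm_track()
}

#' Correlate control and treated profiles to the sequence model
#'
#' Computes the Pearson correlation of the control and treated profiles to
#' the model track on the shared grid, the treated-minus-control
#' difference score, and the DNA-directed verdict: the repositioned state
#' is called DNA-directed when it moved toward the model
#' (`difference_score > 0`) and resembles it strongly
#' (`r_treated_model >= directed_threshold`).
#'
#' @param control_profile,treated_profile Profile tibbles for one locus
#'   (typically replicate-averaged).
#' @param model Model track tibble for the same locus (`offset`, `score`).
#' @param directed_threshold Threshold on `r_treated_model` (default 0.7).
#' @param min_shared Minimum shared positions.
#' @return One-row tibble: `locus_id`, `r_control_model`,
#'   `r_treated_model`, `difference_score`, `dna_directed` (`NA` when any
#'   correlation is undefined).
#' @export
score_locus <- function(control_profile, treated_profile, model,
                        directed_threshold = 0.7, min_shared = 10L) {
  lid <- unique(c(control_profile$locus_id, treated_profile$locus_id))
  if (length(lid) != 1L) {
    nucshift_abort("score_locus expects profiles of a single locus",
                   "nucshift_model_error")
  }
  shared <- Reduce(intersect, list(control_profile$offset,
                                   treated_profile$offset, model$offset))
  if (length(shared) < min_shared) {
    nucshift_abort("too few shared positions with the model track",
                   "nucshift_model_error")
  }
  m <- model$score[match(shared, model$offset)]
  rc <- safe_cor(control_profile$value[match(shared, control_profile$offset)],
                 m, min_shared)
  rt <- safe_cor(treated_profile$value[match(shared, treated_profile$offset)],
                 m, min_shared)
  diff <- rt - rc
  tibble::tibble(
    locus_id = lid,
    r_control_model = rc,
    r_treated_model = rt,
    difference_score = diff,
    dna_directed = if (is.na(rc) || is.na(rt)) NA else
      (diff > 0 && rt >= directed_threshold)
  )
}

#' Model scores for all loci of one condition
#'
#' Replicate-averages the control and treated profiles per locus and
#' applies [score_locus()].
#'
#' @param profiles Long profile tibble.
#' @param model Model track tibble over all loci.
#' @param condition Treated condition label.
#' @param control Control condition label.
#' @param directed_threshold See [score_locus()].
#' @return Tibble with one [score_locus()] row per locus, plus `condition`.
#' @export
score_all <- function(profiles, model, condition, control = "control",
                      directed_threshold = 0.7) {
  ctl <- average_replicates(profiles[profiles$condition == control, ])
  trt <- average_replicates(profiles[profiles$condition == condition, ])
  ctl_s <- split(ctl, ctl$locus_id)
  trt_s <- split(trt, trt$locus_id)
  mod_s <- split(model, model$locus_id)
  ids <- intersect(names(ctl_s), names(trt_s))
  out <- dplyr::bind_rows(lapply(ids, function(lid) {
    score_locus(ctl_s[[lid]], trt_s[[lid]], mod_s[[lid]],
                directed_threshold = directed_threshold)
  }))
  out$condition <- condition
  out
}

#' Fraction of changed loci consistent with the DNA-directed model
#'
#' @param scores Output of [score_all()].
#' @param changed Character vector of changed locus ids.
#' @return Fraction in \[0, 1\], or `NA` for an empty changed set.
#' @export
directed_fraction <- function(scores, changed) {
  sel <- scores[scores$locus_id %in% changed & !is.na(scores$dna_directed), ]
  if (length(changed) == 0L || nrow(sel) == 0L) return(NA_real_)
  mean(sel$dna_directed)
}
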