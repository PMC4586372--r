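#' Normalize two-channel intensities
#'
#' Normalization is per array (one condition x replicate hybridization).
#' `"median"` rescales each channel of each array so that its median equals
#' a common reference (the grand median of all intensities unless
#' `reference` is given) — a ratio-preserving, assumption-light default.
#' `"quantile"` applies quantile normalization across all array-channel
#' columns via [limma::normalizeQuantiles()]. `"none"` is the identity.
#'
#' @param signals Tibble `probe_id`, `condition`, `replicate`, `cy3`, `cy5`.
#' @param method `"median"`, `"quantile"` or `"none"`.
#' @param reference Target median for `"median"` (default: grand median).
#' @return Tibble of the same shape with rescaled intensities.
#' @export
normalize_channels <- function(signals,
                               method = c("median", "quantile", "none"),
                               reference = NULL) {
  method <- match.arg(method)
  check_positive(signals)
  if (method == "none") return(signals)

  if (method == "median") {
    ref <- if (is.null(reference)) median(c(signals$cy3, signals$cy5)) else reference
    signals |>
      dplyr::group_by(.data$condition, .data$replicate) |>
      dplyr::mutate(cy3 = .data$cy3 * ref / median(.data$cy3),
                    cy5 = .data$cy5 * ref / median(.data$cy5)) |>
      dplyr::ungroup()
  } else {
    arrays <- split(signals, interaction(signals$condition, signals$replicate,
                                         drop = TRUE))
    arrays <- lapply(arrays, function(a) a[order(a$probe_id), ])
    m <- cbind(
      do.call(cbind, lapply(arrays, `[[`, "cy3")),
      do.call(cbind, lapply(arrays, `[[`, "cy5"))
    )
    mq <- limma::normalizeQuantiles(log2(m))
    k <- length(arrays)
    out <- dplyr::bind_rows(lapply(seq_along(arrays), function(i) {
      a <- arrays[[i]]
      a$cy3 <- 2^mq[, i]
      a$cy5 <- 2^mq[, i + k]
      a
    }))
    out[order(match(paste(out$condition, out$replicate, out$probe_id),
                    paste(signals$condition, signals$replicate, signals$probe_id))), ]
  }
}

check_positive <- function(signals) {
  bad <- which(signals$cy3 <= 0 | signals$cy5 <= 0)
  if (length(bad)) {
    nucshift_abort(
      sprintf("non-positive intensity at probe %s (%s, rep %s)",
              signals$probe_id[bad[1]], signals$condition[bad[1]],
              signals$replicate[bad[1]]),
      "nucshift_preprocess_error"
    )
  }
  invisible(signals)
}

#' Per-probe log2 occupancy ratio
#'
#' The occupancy signal: log2(nucleosomally-protected Cy3 / bare genomic
#' Cy5) per probe.
#'
#' @param signals Normalized intensity tibble.
#' @return Tibble `probe_id`, `condition`, `replicate`, `value`.
#' @export
log2_ratio <- function(signals) {
  if (any(signals$cy5 == 0)) {
    nucshift_abort("cy5 intensity of zero: ratio undefined",
                   "nucshift_preprocess_error")
  }
  tibble::tibble(
    probe_id = signals$probe_id,
    condition = signals$condition,
    replicate = signals$replicate,
    value = log2(signals$cy3 / signals$cy5)
  )
}

#' Collapse probe ratios to per-locus occupancy profiles
#'
#' Probes are anchored at their midpoint and binned by the midpoint offset
#' from the TSS (1-bp bins, i.e. exact midpoints; for minus-strand loci the
#' offset axis is flipped so upstream is always negative). Replicate probes
#' falling in the same bin — forward/reverse co-located probes or duplicate
#' spots within one array — are arithmetic-mean averaged. Biological
#' replicates are kept separate.
#'
#' @param ratios Output of [log2_ratio()].
#' @param layout A `probe_layout`.
#' @return Profile tibble `locus_id`, `condition`, `replicate`, `offset`,
#'   `value`, offsets strictly ascending within each profile and contained
#'   in the TSS-relative window.
#' @export
average_probes <- function(ratios, layout) {
  p <- layout$probes
  idx <- match(ratios$probe_id, p$probe_id)
  if (anyNA(idx)) {
    nucshift_abort("ratio table contains probes absent from the layout",
                   "nucshift_preprocess_error")
  }
  loci <- layout$loci
  li <- match(p$locus_id[idx], loci$locus_id)
  mid <- probe_midpoint(p)[idx]
  if (any(mid < loci$window_start[li] | mid >= loci$window_end[li])) {
    nucshift_abort("probe outside its locus window", "nucshift_preprocess_error")
  }
  offset <- mid - loci$tss[li]
  offset <- as.integer(ifelse(loci$strand[li] == "-", -offset, offset))

  # bin-mean over millions of 1-bp bins: sort on integer codes, then
  # collapse runs — much faster than per-group summarise
  lid <- p$locus_id[idx]
  l_code <- match(lid, sort(unique(lid)))
  c_code <- match(ratios$condition, sort(unique(ratios$condition)))
  r_code <- match(as.character(ratios$replicate),
                  sort(unique(as.character(ratios$replicate))))
  o <- order(l_code, c_code, r_code, offset)
  lc <- l_code[o]; cc <- c_code[o]; rc <- r_code[o]; off <- offset[o]
  val <- ratios$value[o]
  new_grp <- c(TRUE, lc[-1] != lc[-length(lc)] | cc[-1] != cc[-length(cc)] |
                 rc[-1] != rc[-length(rc)] | off[-1] != off[-length(off)])
  starts <- which(new_grp)
  ends <- c(starts[-1] - 1L, length(val))
  cs <- cumsum(val)
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  tibble::tibble(
    locus_id = lid[o][starts],
    condition = ratios$condition[o][starts],
    replicate = as.character(ratios$replicate[o][starts]),
    offset = off[starts],
    value = sums / (ends - starts + 1L)
  )
}

#' Average biological-replicate profiles position-wise
#'
#' Used for display only; change calls always compare replicates
#' individually. All replicates of a locus x condition must share the same
#' position grid.
#'
#' @param profiles Profile tibble (possibly several loci and conditions).
#' @return Profile tibble with `replicate = "averaged"`.
#' @export
average_replicates <- function(profiles) {
  l_code <- match(profiles$locus_id, sort(unique(profiles$locus_id)))
  c_code <- match(profiles$condition, sort(unique(profiles$condition)))
  o <- order(l_code, c_code, profiles$offset)
  lc <- l_code[o]; cc <- c_code[o]; off <- profiles$offset[o]
  val <- profiles$value[o]
  new_grp <- c(TRUE, lc[-1] != lc[-length(lc)] | cc[-1] != cc[-length(cc)] |
                 off[-1] != off[-length(off)])
  starts <- which(new_grp)
  ends <- c(starts[-1] - 1L, length(val))
  cnt <- ends - starts + 1L
  # identical grids iff every position of a locus x condition occurs
  # exactly once per replicate
  lc_key <- paste(profiles$locus_id, profiles$condition, sep = "\r")
  n_reps <- vapply(split(profiles$replicate, lc_key),
                   function(r) length(unique(r)), integer(1))
  if (any(cnt != n_reps[lc_key[o][starts]])) {
    nucshift_abort("replicate profiles are on mismatched position grids",
                   "nucshift_preprocess_error")
  }
  cs <- cumsum(val)
  sums <- cs[ends] - c(0, cs[ends[-length(ends)]])
  tibble::tibble(
    locus_id = profiles$locus_id[o][starts],
    condition = profiles$condition[o][starts],
    replicate = "averaged",
    offset = off[starts],
    value = sums / cnt
  )
}

#' End-to-end: intensities to occupancy profiles
#'
#' @param signals Raw intensity tibble.
#' @param layout A `probe_layout`.
#' @param method Normalization method, see [normalize_channels()].
#' @return Profile tibble.
#' @export
build_profiles <- function(signals, layout, method = "median") {
  signals |>
    normalize_channels(method = method) |>
    log2_ratio() |>
    average_probes(layout)
}

# ---- profile I/O -----------------------------------------------------------

#' Read and write occupancy profiles
#'
#' TSV columns: `locus_id`, `condition`, `replicate`, `offset`, `value`.
#'
#' @param profiles Profile tibble.
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(locus_id = "c", condition = "c",
                                          replicate = "c", offset = "i",
                                          value = "d"))
}

#' Export one profile set as a wiggle track
#'
#' Writes the profiles of a single condition x replicate as a
#' variable-step wiggle track in genomic coordinates (1-based, per the
#' wiggle convention) for genome-browser viewing.
#'
#' @param profiles Profile tibble restricted to one condition x replicate.
#' @param loci Locus table (for chrom / TSS back-mapping).
#' @param path Output `.wig` path.
#' @export
write_profile_wig <- function(profiles, loci, path) {
  key <- unique(paste(profiles$condition, profiles$replicate))
  if (length(key) != 1L) {
    nucshift_abort("write_profile_wig expects a single condition x replicate",
                   "nucshift_io_error")
  }
  li <- match(profiles$locus_id, loci$locus_id)
  off <- ifelse(loci$strand[li] == "-", -profiles$offset, profiles$offset)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom[li],
    ranges = IRanges::IRanges(start = loci$tss[li] + off + 1L, width = 1L),
    score = profiles$value
  )
  gr <- GenomicRanges::sort(gr)
  rtracklayer::export.wig(gr, path)
  invisible(path)
}
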