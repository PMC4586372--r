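#' Build a locus table for TSS-centered tiling windows
#'
#' A locus is a gene promoter window of fixed width centered on the TSS.
#' Coordinates are 0-based, half-open throughout the package; BED export is
#' native and GFF-style 1-based coordinates are only produced on export.
#'
#' @param locus_id Character vector of unique locus identifiers.
#' @param tss Integer vector of TSS genomic coordinates (0-based).
#' @param chrom Chromosome name per locus (recycled if length 1).
#' @param strand `"+"` or `"-"` per locus (recycled if length 1).
#' @param gene_symbol Optional gene symbols; defaults to `locus_id`.
#' @param window_width Window width in bp centered on the TSS (default 2000).
#'
#' @return A tibble with columns `locus_id`, `gene_symbol`, `chrom`, `tss`,
#'   `strand`, `window_start`, `window_end` (half-open, width
#'   `window_width`, TSS at the midpoint).
#' @export
#' @examples
#' make_loci(c("L1", "L2"), tss = c(5000, 12000))
make_loci <- function(locus_id, tss, chrom = "chrSim", strand = "+",
                      gene_symbol = locus_id, window_width = 2000L) {
  if (anyDuplicated(locus_id)) {
    nucshift_abort("locus_id values must be unique", "nucshift_design_error")
  }
  if (window_width <= 0) {
    nucshift_abort("window_width must be positive", "nucshift_design_error")
  }
  half <- window_width %/% 2L
  tibble::tibble(
    locus_id = as.character(locus_id),
    gene_symbol = as.character(gene_symbol),
    chrom = rep_len(as.character(chrom), length(locus_id)),
    tss = as.integer(tss),
    strand = rep_len(as.character(strand), length(locus_id)),
    window_start = as.integer(tss) - half,
    window_end = as.integer(tss) - half + as.integer(window_width)
  )
}

#' Tile probes across locus windows
#'
#' Places fixed-length probes at a constant step `probe_len - overlap` along
#' each locus window, per strand. With `both_strands = TRUE` the reverse
#' strand is tiled as well, offset by `rev_offset` bp so that pooled probe
#' starts interleave (halving the effective spacing, as in designs that quote
#' a median spacing of half the per-strand step). A final placement that
#' would run past the window end is dropped, never truncated.
#'
#' @param loci Locus table from [make_loci()] or [read_loci()].
#' @param probe_len Probe length in bp (default 60).
#' @param overlap Overlap between successive probes on a strand, bp
#'   (default 47, i.e. a 13-bp step).
#' @param both_strands Tile the reverse strand as well (default TRUE).
#' @param rev_offset Start offset of the reverse-strand tiling relative to
#'   the forward tiling, bp (default 6).
#'
#' @return A `probe_layout`: a list with elements `loci`, `probes` (tibble:
#'   `probe_id`, `locus_id`, `chrom`, `start`, `end`, `strand`), `probe_len`,
#'   `step`.
#' @export
#' @examples
#' loci <- make_loci("L1", tss = 1000)
#' layout <- build_layout(loci)
#' layout_summary(layout)
build_layout <- function(loci, probe_len = 60L, overlap = 47L,
                         both_strands = TRUE, rev_offset = 6L) {
  probe_len <- as.integer(probe_len)
  overlap <- as.integer(overlap)
  if (overlap >= probe_len || overlap < 0L) {
    nucshift_abort(
      sprintf("invalid design: overlap (%d) must satisfy 0 <= overlap < probe_len (%d)",
              overlap, probe_len),
      "nucshift_design_error"
    )
  }
  if (any(loci$window_end - loci$window_start < probe_len)) {
    nucshift_abort("every locus window must be at least probe_len wide",
                   "nucshift_design_error")
  }
  step <- probe_len - overlap

  tile_one <- function(ws, we, offset) {
    first <- ws + offset
    last_ok <- we - probe_len
    if (first > last_ok) return(integer(0))
    seq.int(first, last_ok, by = step)
  }

  pieces <- lapply(seq_len(nrow(loci)), function(i) {
    ws <- loci$window_start[i]; we <- loci$window_end[i]
    fwd <- tile_one(ws, we, 0L)
    starts <- fwd
    strands <- rep("+", length(fwd))
    if (both_strands) {
      rev <- tile_one(ws, we, as.integer(rev_offset))
      starts <- c(starts, rev)
      strands <- c(strands, rep("-", length(rev)))
    }
    ord <- order(starts, strands)
    tibble::tibble(
      locus_id = loci$locus_id[i],
      chrom = loci$chrom[i],
      start = as.integer(starts[ord]),
      end = as.integer(starts[ord] + probe_len),
      strand = strands[ord]
    )
  })
  probes <- dplyr::bind_rows(pieces)
  probes$probe_id <- sprintf("%s_p%04d", probes$locus_id,
                             stats::ave(seq_len(nrow(probes)), probes$locus_id,
                                        FUN = seq_along))
  probes <- probes[, c("probe_id", "locus_id", "chrom", "start", "end", "strand")]

  structure(
    list(loci = loci, probes = tibble::as_tibble(probes),
         probe_len = probe_len, step = step),
    class = "probe_layout"
  )
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d loci, %d probes (%d-mers, step %d bp/strand)\n",
              nrow(x$loci), nrow(x$probes), x$probe_len, x$step))
  invisible(x)
}

#' Per-locus probe count and median spacing
#'
#' Spacing is computed over successive probe starts pooled across both
#' strands within a locus; a locus with fewer than two probes has missing
#' spacing.
#'
#' @param layout A `probe_layout`.
#' @return Tibble with `locus_id`, `probe_count`, `median_spacing`.
#' @export
layout_summary <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  if (nrow(layout$probes) == 0L) {
    nucshift_abort("empty layout", "nucshift_design_error")
  }
  layout$probes |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      probe_count = dplyr::n(),
      median_spacing = if (dplyr::n() < 2L) NA_real_ else
        stats::median(diff(sort(.data$start))),
      .groups = "drop"
    )
}

probe_midpoint <- function(probes) (probes$start + probes$end) %/% 2L

# ---- design / locus I/O ----------------------------------------------------

#' Read and write probe designs
#'
#' The native design format is a TSV with columns `probe_id`, `locus_id`,
#' `chrom`, `start`, `end`, `strand` (0-based half-open). BED6 is also
#' supported; the BED name field carries `probe_id|locus_id`. Reading a
#' design requires the matching locus table so window membership can be
#' validated.
#'
#' @param path File path.
#' @param loci Locus table the probes belong to.
#' @param format `"tsv"` or `"bed"` (default guessed from extension).
#' @return `read_design()` returns a `probe_layout`; `write_design()`
#'   returns `path` invisibly.
#' @export
write_design <- function(layout, path, format = guess_format(path)) {
  stopifnot(inherits(layout, "probe_layout"))
  p <- layout$probes
  if (format == "tsv") {
    readr::write_tsv(p, path)
  } else if (format == "bed") {
    bed <- data.frame(
      chrom = p$chrom, start = p$start, end = p$end,
      name = paste(p$probe_id, p$locus_id, sep = "|"),
      score = 0L, strand = p$strand
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  } else {
    nucshift_abort("unknown design format", "nucshift_io_error")
  }
  invisible(path)
}

#' @rdname write_design
#' @param layout A `probe_layout` (for `write_design`).
#' @export
read_design <- function(path, loci, format = guess_format(path)) {
  if (format == "tsv") {
    p <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           probe_id = "c", locus_id = "c", chrom = "c",
                           start = "i", end = "i", strand = "c"))
  } else if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                               "name", "score", "strand"),
                           show_col_types = FALSE,
                           col_types = "ciicic")
    ids <- strsplit(bed$name, "|", fixed = TRUE)
    p <- tibble::tibble(
      probe_id = vapply(ids, `[`, "", 1L),
      locus_id = vapply(ids, `[`, "", 2L),
      chrom = bed$chrom, start = bed$start, end = bed$end, strand = bed$strand
    )
  } else {
    nucshift_abort("unknown design format", "nucshift_io_error")
  }
  if (any(is.na(p$start)) || any(is.na(p$end)) || any(p$start >= p$end)) {
    nucshift_abort("malformed probe coordinates (need start < end)",
                   "nucshift_io_error")
  }
  if (!all(p$locus_id %in% loci$locus_id)) {
    nucshift_abort("design references loci absent from the locus table",
                   "nucshift_io_error")
  }
  w <- loci[match(p$locus_id, loci$locus_id), ]
  if (any(p$start < w$window_start | p$end > w$window_end)) {
    nucshift_abort("probe interval outside its locus window",
                   "nucshift_io_error")
  }
  probe_len <- unique(p$end - p$start)
  step <- if (nrow(p) > 1L) {
    d <- diff(sort(p$start[p$locus_id == p$locus_id[1] & p$strand == "+"]))
    if (length(d)) min(d) else NA_integer_
  } else NA_integer_
  structure(list(loci = loci, probes = p,
                 probe_len = probe_len[1], step = step),
            class = "probe_layout")
}

#' Read and write locus tables
#'
#' Native format is a TSV with the [make_loci()] columns. BED6 is also
#' supported on write: the BED interval is the window, the name the
#' locus_id, and the thickStart-style 7th column carries the TSS.
#'
#' @param loci Locus table.
#' @param path File path.
#' @return `read_loci()` returns a locus tibble.
#' @export
write_loci <- function(loci, path) {
  readr::write_tsv(loci, path)
  invisible(path)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  loci <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            locus_id = "c", gene_symbol = "c", chrom = "c",
                            tss = "i", strand = "c",
                            window_start = "i", window_end = "i"))
  if (anyDuplicated(loci$locus_id)) {
    nucshift_abort("duplicate locus_id in locus table", "nucshift_io_error")
  }
  if (any(loci$window_end - loci$window_start <= 0)) {
    nucshift_abort("malformed locus windows", "nucshift_io_error")
  }
  loci
}

guess_format <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
}
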