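#' Occupancy state of a profile interval
#'
#' The zero line of the log2 occupancy ratio is the baseline: mean signal
#' above zero over the interval means the interval is nucleosome-occupied,
#' below zero nucleosome-depleted. With `mode = "relative"` the state is
#' taken from the sign of the treated-minus-control delta instead (for
#' cases that gain or lose occupancy relative to the control without
#' crossing the baseline). At least three profile positions must fall in
#' the interval.
#'
#' @param profile Profile tibble for one locus (`offset`, `value`).
#' @param interval TSS-relative interval `c(start, end)`, half-open.
#' @param control Optional control profile for `delta_vs_control` /
#'   relative mode.
#' @param mode `"absolute"` (zero baseline) or `"relative"` (delta sign;
#'   requires `control`).
#' @return One-row tibble: `start`, `end`, `n_positions`, `mean_signal`,
#'   `delta_vs_control`, `state` (`"occupied"`, `"depleted"` or
#'   `"indeterminate"`).
#' @export
interval_state <- function(profile, interval, control = NULL,
                           mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  sel <- profile$offset >= interval[1] & profile$offset < interval[2]
  vals <- profile$value[sel]
  delta <- NA_real_
  if (!is.null(control)) {
    shared <- intersect(profile$offset[sel],
                        control$offset[control$offset >= interval[1] &
                                         control$offset < interval[2]])
    if (length(shared)) {
      delta <- mean(profile$value[match(shared, profile$offset)]) -
        mean(control$value[match(shared, control$offset)])
    }
  }
  if (length(vals) < 3L) {
    return(tibble::tibble(start = interval[1], end = interval[2],
                          n_positions = length(vals),
                          mean_signal = NA_real_, delta_vs_control = delta,
                          state = "indeterminate"))
  }
  basis <- if (mode == "absolute") mean(vals) else delta
  state <- if (is.na(basis)) "indeterminate"
           else if (basis > 0) "occupied" else "depleted"
  tibble::tibble(start = interval[1], end = interval[2],
                 n_positions = length(vals), mean_signal = mean(vals),
                 delta_vs_control = delta, state = state)
}

#' Classify a promoter's nucleosome configuration after treatment
#'
#' Scores the occupancy-state transition of the TSS interval and of every
#' annotated TFBS between the control and treated profiles, then issues a
#' locus verdict: `"permissive"` when the TSS or at least half of the
#' permissive TF sites become depleted (accessible to activators) while no
#' repressive site becomes depleted; `"restrictive"` for the mirror case
#' (TSS becomes occupied or at least half of the repressive sites become
#' depleted, while no permissive site becomes depleted); `"mixed"`
#' otherwise. With no TFBS supplied the verdict comes from the TSS
#' interval alone.
#'
#' @param control,treated Profile tibbles for one locus.
#' @param tss_interval TSS-relative interval scored as "the TSS" (default
#'   `c(-100, 100)`).
#' @param tfbs Tibble of binding sites for this locus: `factor`,
#'   `start`, `end` (TSS-relative), `regulatory_class`
#'   (`"permissive"`/`"repressive"`). May be `NULL` or empty.
#' @param mode Occupancy-state mode, see [interval_state()].
#' @return List with `verdict`, `tss` (transition row) and `sites`
#'   (per-site tibble with `state_control`, `state_treated`, `transition`).
#' @export
classify_configuration <- function(control, treated,
                                   tss_interval = c(-100L, 100L),
                                   tfbs = NULL,
                                   mode = "absolute") {
  trans_one <- function(interval) {
    s0 <- interval_state(control, interval, mode = "absolute")$state
    s1 <- interval_state(treated, interval, control = control, mode = mode)$state
    tibble::tibble(
      start = interval[1], end = interval[2],
      state_control = s0, state_treated = s1,
      transition = if (s0 == "indeterminate" || s1 == "indeterminate")
        "indeterminate" else if (s0 == s1) "unchanged" else paste0(s0, "->", s1)
    )
  }
  tss <- trans_one(tss_interval)

  sites <- NULL
  if (!is.null(tfbs) && nrow(tfbs)) {
    sites <- dplyr::bind_rows(lapply(seq_len(nrow(tfbs)), function(i)
      trans_one(c(tfbs$start[i], tfbs$end[i]))))
    sites <- dplyr::bind_cols(tfbs[, c("factor", "regulatory_class")], sites)
  }

  became_depleted <- function(tr) tr == "occupied->depleted"
  became_occupied <- function(tr) tr == "depleted->occupied"

  if (is.null(sites)) {
    verdict <- if (became_depleted(tss$transition)) "permissive"
               else if (became_occupied(tss$transition)) "restrictive"
               else "mixed"
  } else {
    perm <- sites[sites$regulatory_class == "permissive", ]
    repr <- sites[sites$regulatory_class == "repressive", ]
    perm_dep <- if (nrow(perm)) mean(became_depleted(perm$transition)) else 0
    repr_dep <- if (nrow(repr)) mean(became_depleted(repr$transition)) else 0
    permissive <- (became_depleted(tss$transition) || perm_dep >= 0.5) &&
      !any(became_depleted(repr$transition))
    restrictive <- (became_occupied(tss$transition) || repr_dep >= 0.5) &&
      !any(became_depleted(perm$transition))
    verdict <- if (permissive && !restrictive) "permissive"
               else if (restrictive && !permissive) "restrictive"
               else "mixed"
  }
  list(verdict = verdict, tss = tss, sites = sites)
}

#' Call nucleosome-depleted regions (NDRs) in a profile
#'
#' Maximal runs of consecutive grid positions with signal below zero
#' spanning at least `min_width` bp. The default width of 140 bp is
#' approximately one nucleosome: narrower dips are not interpretable as
#' depleted regions.
#'
#' @param profile Profile tibble for one locus.
#' @param min_width Minimum span, bp (default 140).
#' @return Tibble `start`, `end` (TSS-relative, half-open at the grid
#'   resolution), `width`, `mean_signal`; zero rows if none.
#' @export
call_ndrs <- function(profile, min_width = 140L) {
  ord <- order(profile$offset)
  off <- profile$offset[ord]
  val <- profile$value[ord]
  neg <- val < 0
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          width = integer(0), mean_signal = numeric(0))
  if (!any(neg)) return(empty)
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    width <- off[j] - off[i]
    if (width >= min_width) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = off[i], end = off[j], width = width,
        mean_signal = mean(val[i:j]))
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Read TFBS annotations from BED6+2
#'
#' BED columns: chrom, start, end (genomic, 0-based half-open), name
#' (factor), score, strand, plus two extra columns `locus_id` and
#' `regulatory_class`. Coordinates are converted to TSS-relative intervals
#' using the locus table.
#'
#' @param path BED6+2 file.
#' @param loci Locus table.
#' @return Tibble `locus_id`, `factor`, `start`, `end` (TSS-relative),
#'   `regulatory_class`.
#' @export
read_tfbs <- function(path, loci) {
  bed <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "name",
                                       "score", "strand", "locus_id",
                                       "regulatory_class"),
                         show_col_types = FALSE, col_types = "ciiciccc")
  if (!all(bed$regulatory_class %in% c("permissive", "repressive"))) {
    nucshift_abort("regulatory_class must be 'permissive' or 'repressive'",
                   "nucshift_io_error")
  }
  li <- match(bed$locus_id, loci$locus_id)
  if (anyNA(li)) {
    nucshift_abort("TFBS references unknown locus_id", "nucshift_io_error")
  }
  s <- bed$start - loci$tss[li]
  e <- bed$end - loci$tss[li]
  flip <- loci$strand[li] == "-"
  rs <- ifelse(flip, -e, s)
  re <- ifelse(flip, -s, e)
  tibble::tibble(locus_id = bed$locus_id, factor = bed$name,
                 start = as.integer(rs), end = as.integer(re),
                 regulatory_class = bed$regulatory_class)
}
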