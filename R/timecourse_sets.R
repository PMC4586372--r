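#' Integer percentage with round-half-away-from-zero
#'
#' The rounding convention used for every printed percentage in the
#' reports: `100 * count / total`, rounded half away from zero to an
#' integer.
#'
#' @param count,total Non-negative counts, `count <= total`, `total > 0`.
#' @return Integer percent.
#' @export
#' @examples
#' percent_of(611, 858) # 71
percent_of <- function(count, total) {
  if (any(total <= 0)) {
    nucshift_abort("total must be positive", "nucshift_sets_error")
  }
  if (any(count < 0) || any(count > total)) {
    nucshift_abort("need 0 <= count <= total", "nucshift_sets_error")
  }
  p <- 100 * count / total
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Venn partition of changed-locus sets
#'
#' Assigns every locus in the union to the exact subset of time points at
#' which it appears, and counts each non-empty region.
#'
#' @param changed_sets Named list of character vectors (locus sets per
#'   time point); at least two sets.
#' @return List with `regions` (tibble: `region` label `a+b`, `n_sets`,
#'   `count`, `members` list-column) and `union_count`.
#' @export
venn_partition <- function(changed_sets) {
  if (length(changed_sets) < 2L) {
    nucshift_abort("venn_partition needs at least two sets", "nucshift_sets_error")
  }
  labs <- names(changed_sets)
  all_loci <- unique(unlist(changed_sets))
  membership <- vapply(changed_sets, function(s) all_loci %in% s,
                       logical(length(all_loci)))
  if (length(all_loci) == 1L) membership <- matrix(membership, nrow = 1L)
  sig <- apply(membership, 1L, function(m) paste(labs[m], collapse = "+"))
  regions <- tibble::tibble(locus_id = all_loci, region = sig) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_sets = lengths(strsplit(.data$region[1], "+", fixed = TRUE)),
                     count = dplyr::n(),
                     members = list(sort(.data$locus_id)),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_sets), .data$region)
  list(regions = regions, union_count = length(all_loci))
}

#' Cumulative changed set across time points
#'
#' @param changed_sets Named list of locus sets.
#' @param universe Character vector of all loci on the design (for the
#'   percentage), or its size.
#' @return List with `members`, `count`, `pct` (integer percent of the
#'   universe).
#' @export
cumulative_changed <- function(changed_sets, universe) {
  u <- sort(unique(unlist(changed_sets)))
  total <- if (is.numeric(universe)) universe else length(universe)
  list(members = u, count = length(u), pct = percent_of(length(u), total))
}

#' Loci restored to the basal state
#'
#' Loci that changed at some point during the time course but are no
#' longer called changed at a given (late) time point.
#'
#' @param cumulative Character vector: union of changed loci across time.
#' @param still_changed_at_t Character vector: loci still changed at the
#'   time point of interest; must be a subset of `cumulative`.
#' @return Sorted character vector of restored loci.
#' @export
restored_loci <- function(cumulative, still_changed_at_t) {
  if (!all(still_changed_at_t %in% cumulative)) {
    nucshift_abort("still-changed set must be a subset of the cumulative set",
                   "nucshift_sets_error")
  }
  sort(setdiff(cumulative, still_changed_at_t))
}

#' Drug-specific versus shared repositioning
#'
#' Compares the cumulative changed sets of two drugs (unions over their
#' time courses). Percentages are relative to each drug's own union,
#' rounded with [percent_of()].
#'
#' @param changedA,changedB Character vectors: cumulative changed loci per
#'   drug.
#' @param labels Length-2 character vector naming the drugs.
#' @return List with `A_only`, `B_only`, `shared` (sorted sets),
#'   `pct_A_only`, `pct_B_only`, and `labels`.
#' @export
drug_overlap <- function(changedA, changedB, labels = c("A", "B")) {
  A <- unique(changedA); B <- unique(changedB)
  shared <- intersect(A, B)
  a_only <- setdiff(A, B)
  b_only <- setdiff(B, A)
  list(
    labels = labels,
    A_only = sort(a_only), B_only = sort(b_only), shared = sort(shared),
    pct_A_only = if (length(A)) percent_of(length(a_only), length(A)) else NA_integer_,
    pct_B_only = if (length(B)) percent_of(length(b_only), length(B)) else NA_integer_
  )
}

#' Write a Venn partition report
#'
#' JSON summary (region counts, union) plus a TSV listing each region's
#' member loci.
#'
#' @param partition Output of [venn_partition()].
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_partition <- function(partition, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(union_count = partition$union_count,
           regions = stats::setNames(as.list(partition$regions$count),
                                     partition$regions$region)),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  if (!is.null(tsv_path)) {
    long <- tidyr::unnest(partition$regions[, c("region", "members")],
                          "members")
    names(long) <- c("region", "locus_id")
    readr::write_tsv(long, tsv_path)
  }
  invisible(partition)
}
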