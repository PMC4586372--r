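#' Fold enrichment of a term within a hit set
#'
#' `(k/n) / (K/N)`: the proportion of term members among the hits relative
#' to their proportion in the universe.
#'
#' @param k Hits belonging to the term.
#' @param n Hit-set size.
#' @param K Term size within the universe.
#' @param N Universe size.
#' @return Fold enrichment (0 when `k = 0`).
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    nucshift_abort("n, K and N must be positive", "nucshift_enrichment_error")
  }
  if (any(k < 0) || any(k > pmin(n, K))) {
    nucshift_abort("need 0 <= k <= min(n, K)", "nucshift_enrichment_error")
  }
  (k / n) / (K / N)
}

#' Gene-set over-representation of a changed-locus set
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per term
#' against the array universe, with Bonferroni correction across the
#' terms tested. Term membership is intersected with the universe first;
#' the universe defaults to the full design rather than the genome, since
#' hit sets drawn from an array must be tested against the array
#' background.
#'
#' @param changed Character vector of changed locus ids (subset of
#'   `universe`).
#' @param annotations Named list of character vectors: term -> member
#'   locus ids. Optionally a two-element name convention
#'   `"TERMID|Term name"` is preserved as-is.
#' @param universe Character vector of all loci on the design.
#' @return Tibble sorted by fold enrichment (descending): `term`, `k`,
#'   `n`, `K`, `N`, `fold`, `raw_p`, `adjusted_p`. Empty (with a warning)
#'   for an empty changed set.
#' @export
enrich <- function(changed, annotations, universe) {
  changed <- unique(changed)
  universe <- unique(universe)
  if (!all(changed %in% universe)) {
    nucshift_abort("changed set must be a subset of the universe",
                   "nucshift_enrichment_error")
  }
  empty <- tibble::tibble(term = character(0), k = integer(0), n = integer(0),
                          K = integer(0), N = integer(0), fold = numeric(0),
                          raw_p = numeric(0), adjusted_p = numeric(0))
  if (!length(changed)) {
    warning("empty changed set: no enrichment computed")
    return(empty)
  }
  N <- length(universe)
  n <- length(changed)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(unique(annotations[[term]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(changed, members))
    tibble::tibble(
      term = term, k = k, n = n, K = K, N = N,
      fold = fold_enrichment(k, n, K, N),
      raw_p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty)
  out$adjusted_p <- p.adjust(out$raw_p, method = "bonferroni")
  dplyr::arrange(out, dplyr::desc(.data$fold), .data$raw_p)
}

#' Read gene-set annotations
#'
#' GMT files (one term per line: term, description, members...) are read
#' with `fgsea::gmtPathways()` when available, otherwise parsed directly;
#' two-column TSV (`term`, `locus_id`) is also supported.
#'
#' @param path GMT or TSV file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    if (requireNamespace("fgsea", quietly = TRUE)) {
      return(fgsea::gmtPathways(path))
    }
    lines <- strsplit(readLines(path), "\t")
    return(setNames(lapply(lines, function(x) x[-(1:2)]),
                    vapply(lines, `[`, "", 1L)))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(term = "c", locus_id = "c"))
  split(tab$locus_id, tab$term)
}
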