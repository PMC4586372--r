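#' Pearson correlation between two occupancy profiles
#'
#' Profiles are intersected on their position grids; at least `min_shared`
#' shared positions are required. A constant (zero-variance) profile has no
#' defined correlation and raises a `nucshift_zero_variance` error, which
#' [call_locus()] converts into an indeterminate verdict.
#'
#' @param a,b Profile tibbles (`offset`, `value`) for the same locus.
#' @param min_shared Minimum number of shared positions (default 10).
#' @return Pearson r in \[-1, 1\].
#' @export
profile_correlation <- function(a, b, min_shared = 10L) {
  if ("locus_id" %in% names(a) && "locus_id" %in% names(b)) {
    if (!identical(unique(a$locus_id), unique(b$locus_id))) {
      nucshift_abort("profiles belong to different loci",
                     "nucshift_correlation_error")
    }
  }
  shared <- intersect(a$offset, b$offset)
  if (length(shared) < min_shared) {
    nucshift_abort(
      sprintf("only %d shared positions (need >= %d)", length(shared), min_shared),
      "nucshift_correlation_error"
    )
  }
  x <- a$value[match(shared, a$offset)]
  y <- b$value[match(shared, b$offset)]
  if (sd(x) == 0 || sd(y) == 0) {
    nucshift_abort("constant profile: correlation undefined",
                   "nucshift_zero_variance")
  }
  cor(x, y)
}

# cor() that returns NA instead of erroring/warning on zero variance.
safe_cor <- function(x, y, min_shared = 10L) {
  if (length(x) < min_shared) return(NA_real_)
  sx <- sd(x); sy <- sd(y)
  if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}

#' Change verdict from a set of replicate-pair correlations
#'
#' A locus is significantly changed iff every treated-replicate x
#' control-replicate correlation falls strictly below the threshold
#' ("common among all comparisons"). Any undefined correlation makes the
#' verdict indeterminate (`NA`).
#'
#' @param r_values Numeric vector of pairwise correlations.
#' @param threshold Correlation threshold (default 0.7, strict `<`).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
decide_change <- function(r_values, threshold = 0.7) {
  if (any(is.na(r_values))) return(NA)
  all(r_values < threshold)
}

#' Call repositioning at one locus
#'
#' Correlates every treated replicate against every control replicate and
#' applies the intersection rule of [decide_change()]. The summary `r_mean
#' +/- r_sd` is the mean and standard deviation of r over the comparison
#' pairs.
#'
#' @param treated,control Profile tibbles for one locus with a `replicate`
#'   column (one profile per biological replicate).
#' @param threshold Correlation threshold.
#' @param min_shared Minimum shared positions per comparison.
#' @return One-row tibble: `locus_id`, `n_pairs`, `r_mean`, `r_sd`,
#'   `r_min`, `r_max`, `changed`, `threshold`, plus `r_values` as a
#'   list-column.
#' @export
call_locus <- function(treated, control, threshold = 0.7, min_shared = 10L) {
  lid <- unique(c(treated$locus_id, control$locus_id))
  if (length(lid) != 1L) {
    nucshift_abort("call_locus expects profiles of a single locus",
                   "nucshift_correlation_error")
  }
  tr <- split(treated, treated$replicate)
  ct <- split(control, control$replicate)
  if (!length(tr) || !length(ct)) {
    nucshift_abort("need at least one replicate on each side",
                   "nucshift_correlation_error")
  }
  rs <- numeric(0)
  for (t in tr) for (c0 in ct) {
    r <- tryCatch(profile_correlation(t, c0, min_shared = min_shared),
                  nucshift_zero_variance = function(e) NA_real_)
    rs <- c(rs, r)
  }
  tibble::tibble(
    locus_id = lid,
    n_pairs = length(rs),
    r_mean = mean(rs),
    r_sd = if (length(rs) > 1L) sd(rs) else NA_real_,
    r_min = suppressWarnings(min(rs)),
    r_max = suppressWarnings(max(rs)),
    changed = decide_change(rs, threshold),
    threshold = threshold,
    r_values = list(rs)
  )
}

#' Call repositioning across all loci and conditions
#'
#' For every non-control condition, every locus is correlated over all
#' treated x control replicate pairs (`comparison = "all_pairs"`, the
#' default; `"matched"` compares replicate i against control replicate i
#' only) and the strict intersection rule is applied. Indeterminate loci
#' (zero-variance profiles) are excluded from changed/unchanged counts and
#' reported with `changed = NA`.
#'
#' @param profiles Long profile tibble over all conditions and replicates.
#' @param control Label of the control condition (default `"control"`).
#' @param threshold Correlation threshold (default 0.7).
#' @param comparison `"all_pairs"` or `"matched"`.
#' @param min_shared Minimum shared positions per comparison.
#' @return Tibble: `locus_id`, `condition`, `n_pairs`, `r_mean`, `r_sd`,
#'   `r_min`, `r_max`, `changed`, `threshold`.
#' @export
call_all <- function(profiles, control = "control", threshold = 0.7,
                     comparison = c("all_pairs", "matched"),
                     min_shared = 10L) {
  comparison <- match.arg(comparison)
  conds <- setdiff(unique(profiles$condition), control)
  if (!control %in% profiles$condition) {
    nucshift_abort(sprintf("control condition '%s' not present", control),
                   "nucshift_correlation_error")
  }
  ctl <- profiles[profiles$condition == control, ]
  ctl_reps <- sort(unique(ctl$replicate))

  per_cond <- lapply(conds, function(cond) {
    tr <- profiles[profiles$condition == cond, ]
    tr_reps <- sort(unique(tr$replicate))
    pairs <- if (comparison == "all_pairs") {
      expand.grid(t = tr_reps, c = ctl_reps, stringsAsFactors = FALSE)
    } else {
      data.frame(t = tr_reps, c = ctl_reps[seq_along(tr_reps)])
    }
    rr <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
      a <- tr[tr$replicate == pairs$t[k], c("locus_id", "offset", "value")]
      b <- ctl[ctl$replicate == pairs$c[k], c("locus_id", "offset", "value")]
      j <- dplyr::inner_join(a, b, by = c("locus_id", "offset"),
                             suffix = c("_t", "_c"))
      j |>
        dplyr::group_by(.data$locus_id) |>
        dplyr::summarise(r = safe_cor(.data$value_t, .data$value_c,
                                      min_shared = min_shared),
                         .groups = "drop")
    }))
    rr |>
      dplyr::group_by(.data$locus_id) |>
      dplyr::summarise(
        condition = cond,
        n_pairs = dplyr::n(),
        r_mean = mean(.data$r),
        r_sd = sd(.data$r),
        r_min = suppressWarnings(min(.data$r)),
        r_max = suppressWarnings(max(.data$r)),
        changed = decide_change(.data$r, threshold),
        threshold = threshold,
        .groups = "drop"
      )
  })
  dplyr::bind_rows(per_cond) |>
    dplyr::select("locus_id", "condition", dplyr::everything()) |>
    dplyr::arrange(.data$condition, .data$locus_id)
}

#' Summarize change calls per condition
#'
#' @param calls Output of [call_all()].
#' @param universe_size Number of loci on the design (denominator for
#'   percentages).
#' @return Tibble: `condition`, `n_changed`, `n_unchanged`,
#'   `n_indeterminate`, `pct_changed` (integer percent of the universe).
#' @export
change_summary <- function(calls, universe_size) {
  calls |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_changed = sum(.data$changed, na.rm = TRUE),
      n_unchanged = sum(!.data$changed, na.rm = TRUE),
      n_indeterminate = sum(is.na(.data$changed)),
      pct_changed = percent_of(sum(.data$changed, na.rm = TRUE), universe_size),
      .groups = "drop"
    )
}

#' Changed-locus sets per condition
#'
#' @param calls Output of [call_all()].
#' @return Named list of character vectors (locus ids with
#'   `changed == TRUE`), one per condition.
#' @export
changed_sets <- function(calls) {
  conds <- unique(calls$condition)
  setNames(lapply(conds, function(cc)
    calls$locus_id[calls$condition == cc & !is.na(calls$changed) & calls$changed]),
    conds)
}

#' Global replicate-consistency correlations
#'
#' Correlates the full per-probe log2-ratio vectors of every pair of
#' biological replicates within each condition — the scatterplot
#' consistency check of a two-channel replicate design.
#'
#' @param ratios Output of [log2_ratio()].
#' @return Tibble: `condition`, `rep_a`, `rep_b`, `n_probes`, `r`.
#' @export
replicate_consistency <- function(ratios) {
  out <- list()
  for (cond in unique(ratios$condition)) {
    rc <- ratios[ratios$condition == cond, ]
    reps <- sort(unique(rc$replicate))
    if (length(reps) < 2L) next
    cmb <- utils::combn(reps, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- rc[rc$replicate == cmb[1, k], ]
      b <- rc[rc$replicate == cmb[2, k], ]
      j <- dplyr::inner_join(a, b, by = "probe_id", suffix = c("_a", "_b"))
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond,
        rep_a = cmb[1, k], rep_b = cmb[2, k],
        n_probes = nrow(j),
        r = safe_cor(j$value_a, j$value_b, min_shared = 2L)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Write a change-call table
#'
#' @param calls Output of [call_all()].
#' @param path Output TSV path.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}
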