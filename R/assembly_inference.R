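#' Classification thresholds for the five-process decision tree
#'
#' The canonical cutoffs: |betaNRI| = 2 separates selection from stochastic
#' processes, |RC_bray| = 0.95 separates dispersal from drift. All four
#' comparisons are strict, so boundary values fall to the stochastic side.
#'
#' @param beta_nri_low,beta_nri_high betaNRI cutoffs (defaults -2, +2).
#' @param rc_low,rc_high RC_bray cutoffs (defaults -0.95, +0.95).
#' @return A list of class `"classification_thresholds"`.
#' @export
classification_thresholds <- function(beta_nri_low = -2, beta_nri_high = 2,
                                      rc_low = -0.95, rc_high = 0.95) {
  if (!(beta_nri_low < beta_nri_high)) stop("beta_nri_low must be < beta_nri_high")
  if (!(rc_low < rc_high)) stop("rc_low must be < rc_high")
  structure(list(beta_nri_low = beta_nri_low, beta_nri_high = beta_nri_high,
                 rc_low = rc_low, rc_high = rc_high),
            class = "classification_thresholds")
}

#' Classify sample pairs into assembly processes
#'
#' The decision tree applied to each pair's (betaNRI, RC_bray):
#' betaNRI < -2 -> homogeneous selection; betaNRI > +2 -> heterogeneous
#' selection; otherwise RC_bray > 0.95 -> dispersal limitation;
#' RC_bray < -0.95 -> homogenizing dispersal; otherwise drift. Exactly one
#' label per finite input pair; `NA` inputs give `NA` (undefined-flagged).
#'
#' @param beta_nri,rc_bray Numeric vectors (recycled to common length).
#' @param thresholds A [classification_thresholds()] object.
#' @return Character vector of process labels (see [assembly_processes()]),
#'   `NA` where either statistic is missing.
#' @examples
#' classify_pair(c(-2.6, 0.4, -1.0, 0.1), c(0.1, 0.97, -0.99, 0.2))
#' @export
classify_pair <- function(beta_nri, rc_bray,
                          thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  n <- max(length(beta_nri), length(rc_bray))
  b <- rep_len(beta_nri, n)
  r <- rep_len(rc_bray, n)
  out <- rep(NA_character_, n)
  ok <- is.finite(b) & is.finite(r)
  out[ok & b < thresholds$beta_nri_low] <- "homogeneous_selection"
  out[ok & b > thresholds$beta_nri_high] <- "heterogeneous_selection"
  stoch <- ok & is.na(out)
  out[stoch & r > thresholds$rc_high] <- "dispersal_limitation"
  out[stoch & r < thresholds$rc_low] <- "homogenizing_dispersal"
  out[stoch & is.na(out)] <- "drift"
  out
}

#' Summarize process fractions overall or per group
#'
#' Counts and fractions of the five processes over classified pairs. With
#' `grouping = "month"` only pairs whose two samples share the same calendar
#' month are kept (pooled across years and stations), so each month's
#' fraction is independent of the others. Pairs with undefined statistics
#' are excluded from the denominators but reported in
#' `n_flagged_undefined`. Groups drawn from fewer than `min_samples` samples
#' are emitted with a small-n warning rather than suppressed.
#'
#' @param records data.frame with columns `sample_a`, `sample_b` and either
#'   a `process` column or `beta_nri` + `rc_bray` (classified on the fly).
#' @param metadata Metadata data.frame with `sample_id` and `month`
#'   (required for `grouping = "month"`).
#' @param grouping `"all"`, `"month"` or `"custom"`.
#' @param groups Named character vector `sample_id -> group label`, for
#'   `grouping = "custom"`; only within-group pairs are summarized.
#' @param thresholds A [classification_thresholds()] object.
#' @param min_samples Minimum distinct samples per group before the small-n
#'   warning (default 4).
#' @return data.frame, one row per group: `group_label`, `n_pairs`,
#'   `n_classified`, `n_flagged_undefined`, `n_samples`, `small_n`, one
#'   `count_*` and one `frac_*` column per process. Fractions over classified
#'   pairs sum to 1 (or are `NA` when nothing was classified).
#' @export
summarize_processes <- function(records, metadata = NULL,
                                grouping = c("all", "month", "custom"),
                                groups = NULL,
                                thresholds = classification_thresholds(),
                                min_samples = 4L) {
  grouping <- match.arg(grouping)
  if (!all(c("sample_a", "sample_b") %in% colnames(records))) {
    stop("records must have sample_a and sample_b columns")
  }
  if (!"process" %in% colnames(records)) {
    if (!all(c("beta_nri", "rc_bray") %in% colnames(records))) {
      stop("records need a 'process' column or beta_nri + rc_bray")
    }
    records$process <- classify_pair(records$beta_nri, records$rc_bray,
                                     thresholds)
  }
  if (grouping == "all") {
    grp_a <- grp_b <- rep("ALL", nrow(records))
  } else if (grouping == "month") {
    if (is.null(metadata) || !all(c("sample_id", "month") %in% colnames(metadata))) {
      stop("month grouping needs metadata with sample_id and month")
    }
    mo <- stats::setNames(metadata$month, metadata$sample_id)
    miss <- setdiff(unique(c(records$sample_a, records$sample_b)),
                    names(mo))
    if (length(miss)) stop("samples without metadata: ",
                           paste(miss, collapse = ", "))
    grp_a <- month.name[mo[records$sample_a]]
    grp_b <- month.name[mo[records$sample_b]]
  } else {
    if (is.null(groups)) stop("custom grouping needs a 'groups' vector")
    grp_a <- unname(groups[records$sample_a])
    grp_b <- unname(groups[records$sample_b])
  }
  keep <- !is.na(grp_a) & !is.na(grp_b) & grp_a == grp_b
  records <- records[keep, , drop = FALSE]
  grp <- grp_a[keep]
  procs <- assembly_processes()
  res <- lapply(unique(grp), function(g) {
    rec <- records[grp == g, , drop = FALSE]
    n_pairs <- nrow(rec)
    n_samp <- length(unique(c(rec$sample_a, rec$sample_b)))
    flagged <- sum(is.na(rec$process))
    counts <- vapply(procs, function(p) sum(rec$process == p, na.rm = TRUE),
                     integer(1))
    n_class <- sum(counts)
    fracs <- if (n_class > 0) counts / n_class else rep(NA_real_, length(procs))
    small <- n_samp < min_samples
    if (small) {
      warning("group '", g, "' has only ", n_samp,
              " samples; fractions may not be interpretable", call. = FALSE)
    }
    if (n_class == 0) {
      warning("group '", g, "' has no classified pairs", call. = FALSE)
    }
    row <- data.frame(group_label = g, n_pairs = n_pairs,
                      n_classified = n_class, n_flagged_undefined = flagged,
                      n_samples = n_samp, small_n = small,
                      stringsAsFactors = FALSE)
    row[paste0("count_", procs)] <- as.list(counts)
    row[paste0("frac_", procs)] <- as.list(fracs)
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
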