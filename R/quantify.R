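# ROI statistics, group comparison and test-retest reproducibility.

#' Summarise a GluCEST map over an ROI
#'
#' Mean and SD of the contrast over valid pixels inside the mask. Invalid
#' pixels are excluded, not zero-filled.
#'
#' @param map A `glucest_map` (or plain numeric matrix).
#' @param mask Logical / 0-1 matrix selecting the ROI.
#' @param subject_id,group,scan_index,roi Metadata carried into the row.
#' @return One-row data.frame: `subject_id`, `group`, `scan_index`, `roi`,
#'   `glucest_mean`, `glucest_sd`, `n_pixels`.
#' @export
roi_summary <- function(map, mask, subject_id = "s01", group = "control",
                        scan_index = 1L, roi = "striatum") {
  vals <- if (inherits(map, "glucest_map")) map$contrast_pct else map
  stopifnot(all(dim(mask) == dim(vals)))
  v <- vals[as.logical(mask) & is.finite(vals)]
  if (length(v) == 0) stop("ROI contains no valid pixels")
  data.frame(subject_id = subject_id, group = group,
             scan_index = as.integer(scan_index), roi = roi,
             glucest_mean = mean(v),
             glucest_sd = if (length(v) > 1) stats::sd(v) else 0,
             n_pixels = length(v))
}

#' Test-retest reproducibility coefficients of variation
#'
#' From repeated ROI measurements over subjects x sessions, computes
#' per-subject CVs (100*SD/mean across that subject's sessions; their mean
#' and SD are the intra-subject repeatability) and per-session CVs
#' (100*SD/mean across subjects within a session; their mean and SD are the
#' inter-subject variability). Subjects with fewer than two sessions and
#' sessions with fewer than two subjects are dropped with a warning.
#'
#' @param measurements data.frame with `subject_id`, `scan_index` and a
#'   value column.
#' @param value Name of the value column (default `glucest_mean`; falls back
#'   to `glucest_pct`).
#' @return A `reproducibility_report`: `intra_cv_mean`, `intra_cv_sd`,
#'   `inter_cv_mean`, `inter_cv_sd`, `per_subject_cv`, `per_session_cv`.
#' @examples
#' df <- data.frame(subject_id = "a", scan_index = 1:3,
#'                  glucest_mean = c(9, 10, 11))
#' reproducibility_cv(df)$per_subject_cv  # 10
#' @export
reproducibility_cv <- function(measurements, value = NULL) {
  if (is.null(value))
    value <- if ("glucest_mean" %in% names(measurements)) "glucest_mean"
             else "glucest_pct"
  stopifnot(all(c("subject_id", "scan_index", value) %in% names(measurements)))
  m <- measurements[is.finite(measurements[[value]]), ]
  cv <- function(v) if (mean(v) == 0) 0 else 100 * stats::sd(v) / mean(v)

  by_subj <- split(m[[value]], m$subject_id)
  short <- vapply(by_subj, length, 1L) < 2
  if (any(short)) {
    warning(sprintf("dropping %d subject(s) with < 2 sessions", sum(short)))
    by_subj <- by_subj[!short]
  }
  if (length(by_subj) == 0) stop("no subject has >= 2 sessions")
  per_subject <- vapply(by_subj, cv, numeric(1))

  by_sess <- split(m[[value]], m$scan_index)
  small <- vapply(by_sess, length, 1L) < 2
  if (any(small)) {
    warning(sprintf("dropping %d session(s) with < 2 subjects", sum(small)))
    by_sess <- by_sess[!small]
  }
  if (length(by_sess) == 0) stop("no session has >= 2 subjects")
  per_session <- vapply(by_sess, cv, numeric(1))

  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  structure(list(intra_cv_mean = mean(per_subject),
                 intra_cv_sd = sd0(per_subject),
                 inter_cv_mean = mean(per_session),
                 inter_cv_sd = sd0(per_session),
                 per_subject_cv = per_subject,
                 per_session_cv = per_session),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf("<reproducibility_report> intra-subject CV %.1f +/- %.1f %%; inter-subject CV %.1f +/- %.1f %%\n",
              x$intra_cv_mean, x$intra_cv_sd, x$inter_cv_mean, x$inter_cv_sd))
  invisible(x)
}

# per-subject aggregation over repeat scans
aggregate_subjects <- function(cohort, value = "glucest_pct") {
  agg <- stats::aggregate(cohort[[value]],
                          by = list(subject_id = cohort$subject_id,
                                    group = cohort$group),
                          FUN = mean)
  names(agg)[3] <- value
  nsc <- stats::aggregate(cohort[[value]],
                          by = list(subject_id = cohort$subject_id),
                          FUN = function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  agg$glucest_se <- nsc$x[match(agg$subject_id, nsc$subject_id)]
  if ("glu_mM" %in% names(cohort)) {
    g <- cohort[!duplicated(cohort$subject_id), c("subject_id", "glu_mM", "glu_sd_mM")]
    agg <- merge(agg, g, by = "subject_id", sort = FALSE)
  }
  agg[order(agg$group, agg$subject_id), ]
}

#' Two-group comparison of a cohort variable
#'
#' Welch's (unequal-variance) two-sample t-test of the per-subject means
#' between the two groups. Repeat scans are averaged per subject first.
#' Degenerate zero-variance groups are handled explicitly: identical constant
#' groups give p = 1, distinct constant groups p = 0.
#'
#' @param cohort A cohort table with `group` and the value column.
#' @param variable Column to compare (default `glucest_pct`).
#' @return List: `difference` (group2 - group1), `group_means`, `statistic`,
#'   `p_value`, `groups`, `n`.
#' @export
group_compare <- function(cohort, variable = "glucest_pct") {
  stopifnot(all(c("group", "subject_id", variable) %in% names(cohort)))
  agg <- aggregate_subjects(cohort, variable)
  gl <- unique(agg$group)
  if (length(gl) != 2) stop("exactly two groups required")
  v1 <- agg[[variable]][agg$group == gl[1]]
  v2 <- agg[[variable]][agg$group == gl[2]]
  if (length(v1) < 2 || length(v2) < 2) stop("each group needs n >= 2")
  diff <- mean(v2) - mean(v1)
  if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
    stat <- if (diff == 0) 0 else Inf
    p <- if (diff == 0) 1 else 0
  } else {
    tt <- stats::t.test(v2, v1, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(difference = diff,
       group_means = stats::setNames(c(mean(v1), mean(v2)), gl),
       statistic = stat, p_value = p, groups = gl,
       n = stats::setNames(c(length(v1), length(v2)), gl))
}
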