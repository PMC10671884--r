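# Left/right eye comparison of AVLR feature records: per-metric
# differences, log-ratios and a bounded asymmetry index, plus a paired
# nonparametric cohort test.

#' Compare AVLR records of a left and a right eye
#'
#' For each of the nine AVLR ratios, reports the right and left values,
#' their difference (right minus left), the log-ratio `log(right/left)`,
#' and the asymmetry index `|right - left| / ((right + left)/2)` (bounded
#' in `[0, 2]` for positive values, invariant to side order). Missing
#' ratios on either side propagate as `NA` with a `missing_side` flag.
#'
#' @param left,right `image_feature_record`s sharing `roi_name`.
#' @param subject_id optional subject identifier stored on the report.
#' @return an `eye_pair_report`: data frame with columns `metric`, `left`,
#'   `right`, `difference`, `log_ratio`, `asymmetry_index`,
#'   `missing_side`; attributes `subject_id` and `roi_name`.
#' @export
compare_eyes <- function(left, right, subject_id = NULL) {
  stopifnot(inherits(left, "image_feature_record"),
            inherits(right, "image_feature_record"))
  if (!identical(left$roi_name, right$roi_name))
    stop("left and right records have different roi_name (",
         left$roi_name, " vs ", right$roi_name, ")")
  lv <- left$ratios; rv <- right$ratios
  miss <- !is.finite(lv) | !is.finite(rv)
  rep <- data.frame(
    metric = names(lv),
    left = unname(lv), right = unname(rv),
    difference = unname(rv - lv),
    log_ratio = unname(ifelse(miss | lv <= 0 | rv <= 0, NA_real_,
                              log(rv / lv))),
    asymmetry_index = unname(ifelse(miss, NA_real_,
                                    abs(rv - lv) / ((rv + lv) / 2))),
    missing_side = miss)
  structure(rep, subject_id = subject_id, roi_name = left$roi_name,
            class = c("eye_pair_report", "data.frame"))
}

#' Cohort-level eye asymmetry test
#'
#' Paired Wilcoxon signed-rank test of left versus right values of one
#' AVLR metric across subjects. Zero differences are dropped (the
#' signed-rank convention); if every pair is tied the test is undefined
#' and a p-value of 1 is reported with a `degenerate` flag.
#'
#' @param pairs list of `eye_pair_report`s (see [compare_eyes()]).
#' @param metric one of the nine ratio names, e.g. `"avlr_dm"`.
#' @return list: `metric`, `n_pairs` (complete pairs used), `statistic`,
#'   `p_value`, `median_difference`, `degenerate`.
#' @export
cohort_asymmetry_test <- function(pairs, metric = "avlr_dm") {
  vals <- vapply(pairs, function(p) {
    i <- match(metric, p$metric)
    if (is.na(i)) c(NA_real_, NA_real_) else c(p$left[i], p$right[i])
  }, numeric(2))
  complete <- is.finite(vals[1, ]) & is.finite(vals[2, ])
  l <- vals[1, complete]; r <- vals[2, complete]
  if (length(l) < 2)
    stop("insufficient data: need >= 2 complete pairs, have ", length(l))
  d <- r - l
  if (all(d == 0)) {
    return(list(metric = metric, n_pairs = length(l), statistic = NA_real_,
                p_value = 1, median_difference = 0, degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(r, l, paired = TRUE))
  list(metric = metric, n_pairs = length(l),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       median_difference = median(d), degenerate = FALSE)
}
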