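# Image-level AVLR features: for each of the nine metrics, the unweighted
# mean over artery segments divided by the unweighted mean over vein
# segments, plus per-class summary statistics and per-segment ratio rows.

.usable <- function(metrics) {
  metrics$vessel_class %in% c("artery", "vein") & !metrics$too_short
}

#' Image-level AVLR feature record
#'
#' For each metric the record holds the arithmetic mean over usable artery
#' segments divided by the mean over usable vein segments (`avlr_*`), the
#' per-class per-metric summary statistics (count, mean, sd, min, max,
#' median), and the usable segment counts. Segments classed `unknown`
#' (crossings) and segments flagged `too_short` are excluded from all
#' averages. If either class has no usable segment, the nine ratios are
#' `NA` and the record is flagged `incomplete` (never a division error).
#'
#' @param metrics data frame from [metrics_table()] (needs `vessel_class`
#'   and the nine metric columns).
#' @param image_id,eye,roi_name identifiers stored on the record.
#' @return an `image_feature_record`: fields `image_id`, `eye`,
#'   `roi_name`, `n_artery_segments`, `n_vein_segments`, `incomplete`,
#'   `ratios` (named length-9 vector `avlr_chord` ... `avlr_cl`), `stats`
#'   (long data frame: metric, class, count, mean, sd, min, max, median).
#' @export
image_ratios <- function(metrics, image_id = "image", eye = "unknown",
                         roi_name = "full") {
  ok <- if (nrow(metrics)) .usable(metrics) else logical(0)
  m_a <- metrics[ok & metrics$vessel_class == "artery", , drop = FALSE]
  m_v <- metrics[ok & metrics$vessel_class == "vein", , drop = FALSE]
  incomplete <- nrow(m_a) == 0 || nrow(m_v) == 0
  ratios <- setNames(rep(NA_real_, length(METRIC_NAMES)),
                     paste0("avlr_", METRIC_NAMES))
  if (!incomplete) {
    for (m in METRIC_NAMES) {
      mu_a <- mean(m_a[[m]])
      mu_v <- mean(m_v[[m]])
      ratios[paste0("avlr_", m)] <-
        if (is.finite(mu_v) && mu_v != 0) mu_a / mu_v else NA_real_
    }
  }
  per_class <- list(artery = m_a, vein = m_v)
  stats <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
    do.call(rbind, lapply(names(per_class), function(cls) {
      x <- per_class[[cls]][[m]]
      x <- x[is.finite(x)]
      data.frame(metric = m,
                 class = cls,
                 count = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) sd(x) else NA_real_,
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 median = if (length(x)) median(x) else NA_real_)
    }))
  }))
  rownames(stats) <- NULL
  structure(list(image_id = image_id, eye = eye, roi_name = roi_name,
                 n_artery_segments = nrow(m_a), n_vein_segments = nrow(m_v),
                 incomplete = incomplete, ratios = ratios, stats = stats),
            class = "image_feature_record")
}

#' @export
print.image_feature_record <- function(x, ...) {
  cat(sprintf("<image_feature_record %s [%s, %s] A=%d V=%d%s>\n",
              x$image_id, x$eye, x$roi_name, x$n_artery_segments,
              x$n_vein_segments, if (x$incomplete) " INCOMPLETE" else ""))
  print(round(x$ratios, 4))
  invisible(x)
}

#' Flatten an image feature record to one wide row
#'
#' Columns: identifiers, counts, `incomplete`, the nine `avlr_*` ratios,
#' then `<class>_<metric>_<stat>` for both classes, all nine metrics and
#' the six summary statistics.
#'
#' @param x an `image_feature_record`.
#' @param ... unused.
#' @return one-row data frame.
#' @export
as.data.frame.image_feature_record <- function(x, ...) {
  row <- data.frame(image_id = x$image_id, eye = x$eye,
                    roi_name = x$roi_name,
                    n_artery_segments = x$n_artery_segments,
                    n_vein_segments = x$n_vein_segments,
                    incomplete = x$incomplete)
  row <- cbind(row, as.data.frame(as.list(x$ratios)))
  st <- x$stats
  for (i in seq_len(nrow(st))) {
    for (s in c("count", "mean", "sd", "min", "max", "median")) {
      row[[paste(st$class[i], st$metric[i], s, sep = "_")]] <- st[[s]][i]
    }
  }
  row
}

#' Per-segment AVLR ratio rows
#'
#' Each usable segment's metric divided by the image-level mean of that
#' metric over the opposite class; this is the segment-wise counterpart of
#' the image-level ratios (the mean of artery segment-wise ratios equals
#' the image-level ratio exactly). Segments with no usable opposite-class
#' segments get `NA` ratios and a `ratio_missing` flag.
#'
#' @inheritParams image_ratios
#' @return `metrics` with nine extra `ratio_*` columns and
#'   `ratio_missing`.
#' @export
segmentwise_ratios <- function(metrics) {
  out <- metrics
  for (m in METRIC_NAMES)
    out[[paste0("ratio_", m)]] <- rep(NA_real_, nrow(metrics))
  out$ratio_missing <- rep(TRUE, nrow(metrics))
  if (!nrow(metrics)) return(out)
  ok <- .usable(metrics)
  for (cls in c("artery", "vein")) {
    opp <- if (cls == "artery") "vein" else "artery"
    rows <- which(ok & metrics$vessel_class == cls)
    opp_rows <- which(ok & metrics$vessel_class == opp)
    if (!length(rows) || !length(opp_rows)) next
    for (m in METRIC_NAMES) {
      mu_opp <- mean(metrics[[m]][opp_rows])
      if (is.finite(mu_opp) && mu_opp != 0)
        out[[paste0("ratio_", m)]][rows] <- metrics[[m]][rows] / mu_opp
    }
    out$ratio_missing[rows] <- FALSE
  }
  out
}
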