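# Box plots of AVLR ratio columns, image-wise or segment-wise.

#' Box plots of AVLR ratio features
#'
#' Draws side-by-side box plots of the selected ratio columns of a feature
#' table (image rows with `avlr_*` columns, or segment rows with
#' `ratio_*` columns). Non-finite values are dropped per column.
#'
#' @param rows data frame of feature rows.
#' @param columns character vector of column names to plot; defaults to
#'   every `avlr_*` (or, failing that, `ratio_*`) column present.
#' @param main plot title.
#' @param ... passed to [graphics::boxplot()].
#' @return (invisibly) the list of plotted value vectors.
#' @export
avlr_boxplot <- function(rows, columns = NULL, main = "AVLR ratios", ...) {
  if (is.null(columns)) {
    columns <- grep("^avlr_", names(rows), value = TRUE)
    if (!length(columns))
      columns <- grep("^ratio_", names(rows), value = TRUE)
  }
  missing_cols <- setdiff(columns, names(rows))
  if (length(missing_cols))
    stop("columns not present: ", paste(missing_cols, collapse = ", "))
  vals <- lapply(columns, function(cn) {
    x <- rows[[cn]]
    x[is.finite(x)]
  })
  names(vals) <- sub("^(avlr|ratio)_", "", columns)
  graphics::boxplot(vals, main = main, las = 2, ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(vals)
}
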