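#' Distribution of nuclei counts per cell
#'
#' Percentage of the population at each nuclei count, pooled over all
#' supplied cells (when multiple timepoints are given, pass their counts
#' concatenated to pool them). Counts above 8 are reported in an `"8+"`
#' display class but kept exact in the returned `count` column.
#'
#' @param counts integer vector of nuclei per cell (all >= 1).
#' @return data.frame with columns `count`, `n`, `pct` and
#'   `display_class` (`"1"`, `"2"`, ..., `"8+"`); attributes `n_cells` and
#'   `asynchrony_pct` (see [asynchronyFraction()]; `NA` when no cell has
#'   two or more nuclei).
#' @examples
#' nucleiCountDistribution(c(2, 2, 4, 4))
#' @export
nucleiCountDistribution <- function(counts) {
  counts <- as.integer(counts)
  stopIfNot(length(counts) >= 1, "at least one cell is required")
  if (any(is.na(counts) | counts < 1))
    stop(errorCondition("nuclei counts must be positive integers",
         class = c("cellsizer_format_error", "error", "condition")))
  tab <- table(counts)
  out <- data.frame(count = as.integer(names(tab)),
                    n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(counts))
  out$display_class <- ifelse(out$count >= 8, "8+", as.character(out$count))
  attr(out, "n_cells") <- length(counts)
  attr(out, "asynchrony_pct") <- asynchronyFraction(counts)
  out
}

#' Fraction of cells with asynchronous nuclear divisions
#'
#' Percentage of cells whose nuclei count falls outside the synchronous
#' power-of-two series, among cells with two or more nuclei:
#' `100 * |count in {3, 5, 6, 7}| / |count >= 2|`. Cells with a single
#' nucleus are excluded from the denominator; if no cell has two or more
#' nuclei the fraction is undefined and `NA` is returned (not 0).
#'
#' @param counts integer vector of nuclei per cell (all >= 1).
#' @param asynchronous_set counts treated as asynchronous.
#' @return percentage in \[0, 100\], or `NA_real_` for an empty
#'   denominator.
#' @examples
#' asynchronyFraction(c(2, 3, 4, 8))  # 25
#' @export
asynchronyFraction <- function(counts, asynchronous_set = c(3, 5, 6, 7)) {
  counts <- as.integer(counts)
  if (any(is.na(counts) | counts < 1))
    stop(errorCondition("nuclei counts must be positive integers",
         class = c("cellsizer_format_error", "error", "condition")))
  denom <- sum(counts >= 2)
  if (denom == 0) return(NA_real_)
  100 * sum(counts %in% asynchronous_set) / denom
}

#' Per-cell coefficient of variation of nuclear intensities
#'
#' For each cell, the CV (sample SD / mean, in percent) of its per-nucleus
#' fluorescence intensities, plus the group mean of the per-cell CVs. The
#' per-cell CV is invariant to multiplying all of a cell's intensities by a
#' positive constant, so exposure differences between cells do not affect
#' it. Non-positive intensities are floored at a small positive value and
#' flagged.
#'
#' @param intensities either a list of numeric vectors (one per cell, each
#'   with >= 2 nuclei) or a long data.frame with columns `cell_id` and
#'   `intensity_au` (as written by [simulateNuclearIntensities()]).
#' @return data.frame with columns `cell_id`, `n_nuclei`,
#'   `mean_intensity_au`, `cv_pct`; attributes `mean_cv_pct` (group mean of
#'   per-cell CVs) and `n_floored`.
#' @examples
#' perCellIntensityCV(list(c(90, 100, 110, 100)))  # CV 8.165%
#' @export
perCellIntensityCV <- function(intensities) {
  if (is.data.frame(intensities)) {
    for (col in c("cell_id", "intensity_au")) {
      if (!col %in% names(intensities))
        stop(errorCondition(sprintf("missing required column '%s'", col),
             class = c("cellsizer_format_error", "error", "condition")))
    }
    sets <- split(as.numeric(intensities$intensity_au),
                  intensities$cell_id)
  } else {
    stopIfNot(is.list(intensities), "supply a list or a long data.frame")
    sets <- lapply(intensities, as.numeric)
    if (is.null(names(sets))) names(sets) <- seq_along(sets)
  }
  n_floored <- 0L
  rows <- lapply(names(sets), function(id) {
    v <- sets[[id]]
    stopIfNot(length(v) >= 2, "each cell needs >= 2 nuclei")
    bad <- v <= 0
    if (any(bad)) {
      n_floored <<- n_floored + sum(bad)
      floor_val <- 1e-6 * max(abs(v), 1)
      v[bad] <- floor_val
    }
    data.frame(cell_id = id, n_nuclei = length(v),
               mean_intensity_au = mean(v), cv_pct = cvPct(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_cv_pct") <- mean(out$cv_pct)
  attr(out, "n_floored") <- n_floored
  out
}
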