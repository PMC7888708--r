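#' Compute per-cycle length extension
#'
#' Adds (or recomputes) `extension_um = division_length_um -
#' birth_length_um`. Records with negative extension are flagged and
#' retained: excluding them would bias the BL/E regression.
#'
#' @param records data.frame with `birth_length_um` and
#'   `division_length_um` columns.
#' @return `records` with an `extension_um` column and a
#'   `neg_extension` logical column; attribute `n_negative_extension` gives
#'   the flagged count.
#' @export
computeExtension <- function(records) {
  for (col in c("birth_length_um", "division_length_um")) {
    if (!col %in% names(records))
      stop(errorCondition(sprintf("missing required column '%s'", col),
           class = c("cellsizer_format_error", "error", "condition")))
  }
  records$extension_um <- records$division_length_um -
    records$birth_length_um
  records$neg_extension <- records$extension_um < 0
  attr(records, "n_negative_extension") <- sum(records$neg_extension)
  records
}

#' Group cells into birth-length cohorts
#'
#' Bins records into half-open birth-length intervals
#' `[k*width, (k+1)*width)` anchored at 0 (default width 0.5 um) and reports
#' per-cohort n, mean birth length, mean extension and SD of extension.
#' Cohorts are a display device; the homeostasis regression is fitted on the
#' raw records.
#'
#' @param records data.frame with `birth_length_um`; `extension_um` is
#'   computed if absent.
#' @param width bin width in um (> 0).
#' @param min_count cohorts with fewer records are flagged `low_n` (they are
#'   still reported).
#' @return data.frame with columns `bin_start`, `bin_end`, `n`, `mean_bl`,
#'   `mean_e`, `sd_e`, `low_n`.
#' @examples
#' recs <- data.frame(birth_length_um = c(6.1, 6.4, 6.9),
#'                    division_length_um = c(14, 14.2, 13.9))
#' cohortByBirthLength(recs)
#' @export
cohortByBirthLength <- function(records, width = 0.5, min_count = 1L) {
  stopIfNot(width > 0, "width must be > 0")
  stopIfNot(nrow(records) > 0, "empty input")
  if (!"extension_um" %in% names(records))
    records <- computeExtension(records)
  bl <- records$birth_length_um
  e <- records$extension_um
  k <- floor(bl / width)
  levels_k <- seq(min(k), max(k))
  fk <- factor(k, levels = levels_k)
  n <- as.integer(table(fk))
  keep <- n > 0
  agg <- function(v, f) as.numeric(tapply(v, f, mean))
  sds <- as.numeric(tapply(e, fk, stats::sd))
  out <- data.frame(
    bin_start = levels_k * width,
    bin_end = (levels_k + 1) * width,
    n = n,
    mean_bl = agg(bl, fk),
    mean_e = agg(e, fk),
    sd_e = sds,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out$low_n <- out$n < min_count
  rownames(out) <- NULL
  out
}

#' Fit the birth-length versus extension regression
#'
#' Ordinary least squares of extension `E = D - BL` on birth length `BL`
#' over the raw (non-cohorted) records. The slope diagnoses the
#' size-control mode: about -1 for a sizer, 0 for an adder, positive for a
#' timer under exponential growth; wild-type fission yeast sits around -0.7
#' to -0.8.
#'
#' @param records data.frame with `birth_length_um` and
#'   `division_length_um` (extension computed if absent).
#' @param strain strain label; taken from a `strain` column when present.
#' @param cohort_width width for the reported cohort table (um).
#' @param thresholds passed to [classifyControlMode()].
#' @return a [HomeostasisFit-class] object.
#' @examples
#' recs <- data.frame(birth_length_um = c(6, 7, 8),
#'                    division_length_um = c(10, 10.5, 10.5))
#' fitBLE(recs)  # slope -0.75
#' @export
fitBLE <- function(records, strain = NULL, cohort_width = 0.5,
                   thresholds = c(sizer = -0.6, impaired = -0.2,
                                  timer = 0.2)) {
  if (!"extension_um" %in% names(records))
    records <- computeExtension(records)
  bl <- records$birth_length_um
  e <- records$extension_um
  stopIfNot(length(bl) >= 3, "BL/E fit requires at least 3 records")
  n_distinct <- length(unique(bl))
  stopIfNot(n_distinct >= 2 && stats::sd(bl) > 0,
            "BL/E fit requires variation in birth length")
  if (n_distinct < 10)
    warning("fewer than 10 distinct birth lengths; slope will be unstable")
  if (is.null(strain)) {
    strain <- if ("strain" %in% names(records))
      as.character(records$strain[1]) else "unknown"
  }
  fit <- stats::lm(e ~ bl)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  neg <- if ("neg_extension" %in% names(records))
    sum(records$neg_extension) else sum(e < 0)
  new("HomeostasisFit",
      strain = strain,
      n = length(e),
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      slope_se = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      cohorts = cohortByBirthLength(records, width = cohort_width),
      mode_label = classifyControlMode(slope, thresholds = thresholds),
      n_negative_extension = as.integer(neg))
}

#' Classify the size-control mode from a BL/E slope
#'
#' Maps a BL/E regression slope to a control-mode label using configurable
#' thresholds: `slope <= thresholds["sizer"]` is `sizer_like`;
#' up to `thresholds["impaired"]` is `impaired` (homeostasis present but
#' weakened); between `thresholds["impaired"]` and `thresholds["timer"]` is
#' `adder_like`; at or above `thresholds["timer"]` is `timer_like`. Defaults
#' are (-0.6, -0.2, +0.2).
#'
#' @param x a numeric slope or a [HomeostasisFit-class] object.
#' @param thresholds named numeric vector with elements `sizer`, `impaired`,
#'   `timer` (increasing).
#' @return one of `"sizer_like"`, `"impaired"`, `"adder_like"`,
#'   `"timer_like"`.
#' @examples
#' classifyControlMode(-0.72)   # sizer_like (wild type)
#' classifyControlMode(-0.066)  # adder_like (homeostasis lost)
#' classifyControlMode(-0.46)   # impaired
#' @export
setGeneric("classifyControlMode",
           function(x, thresholds = c(sizer = -0.6, impaired = -0.2,
                                      timer = 0.2))
             standardGeneric("classifyControlMode"))

#' @rdname classifyControlMode
#' @export
setMethod("classifyControlMode", "numeric", function(x, thresholds) {
  stopIfNot(all(c("sizer", "impaired", "timer") %in% names(thresholds)),
            "thresholds needs elements 'sizer', 'impaired', 'timer'")
  stopIfNot(thresholds[["sizer"]] < thresholds[["impaired"]] &&
              thresholds[["impaired"]] < thresholds[["timer"]],
            "thresholds must be increasing")
  vapply(x, function(s) {
    if (s <= thresholds[["sizer"]]) "sizer_like"
    else if (s <= thresholds[["impaired"]]) "impaired"
    else if (s < thresholds[["timer"]]) "adder_like"
    else "timer_like"
  }, character(1))
})

#' @rdname classifyControlMode
#' @export
setMethod("classifyControlMode", "HomeostasisFit", function(x, thresholds) {
  classifyControlMode(x@slope, thresholds = thresholds)
})

#' BL/E scatter plot with cohort means
#'
#' Scatter of per-cell extension against birth length, overlaid with cohort
#' means (+/- SD error bars) in 0.5 um birth-length bins and the raw-data
#' regression line.
#'
#' @inheritParams fitBLE
#' @param fit optional precomputed [HomeostasisFit-class]; fitted if `NULL`.
#' @return a ggplot object.
#' @export
plotBLE <- function(records, fit = NULL, cohort_width = 0.5) {
  if (!"extension_um" %in% names(records))
    records <- computeExtension(records)
  if (is.null(fit)) fit <- fitBLE(records, cohort_width = cohort_width)
  co <- fit@cohorts
  ggplot2::ggplot(records,
                  ggplot2::aes(x = birth_length_um,
                               y = extension_um)) +
    ggplot2::geom_point(colour = "grey75", size = 0.8) +
    ggplot2::geom_errorbar(
      data = co,
      ggplot2::aes(x = mean_bl, y = mean_e,
                   ymin = mean_e - sd_e,
                   ymax = mean_e + sd_e),
      width = 0.1, colour = "grey30") +
    ggplot2::geom_point(data = co,
                        ggplot2::aes(x = mean_bl, y = mean_e),
                        colour = "grey30", size = 2) +
    ggplot2::geom_abline(slope = fit@slope, intercept = fit@intercept,
                         colour = "red") +
    ggplot2::labs(
      x = "Cell length at birth (µm)",
      y = "Length extension (µm)",
      title = sprintf("%s: slope %.2f (%s)", fit@strain, fit@slope,
                      fit@mode_label)) +
    ggplot2::theme_classic()
}

#' Histogram of cell length at division
#'
#' Frequency distribution of division lengths with 1 um bins.
#'
#' @param records data.frame with `division_length_um`.
#' @param binwidth bin width in um.
#' @return a ggplot object.
#' @export
lengthHistogram <- function(records, binwidth = 1) {
  stopIfNot("division_length_um" %in% names(records),
            "missing required column 'division_length_um'",
            class = "cellsizer_format_error")
  ggplot2::ggplot(records,
                  ggplot2::aes(x = division_length_um)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Cell length at division (µm)", y = "Cells") +
    ggplot2::theme_classic()
}
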