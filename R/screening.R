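#' Per-strain summaries of cell length at division
#'
#' One summary row per strain on the division-length column: n, mean, SD,
#' CV%, CQV%, skewness, quartiles, min and max. Strains with n < 2 are
#' reported with missing statistics and are excluded from testing.
#'
#' @param records data.frame of cell records.
#' @param length_col name of the length column (default
#'   `"division_length_um"`).
#' @param strain_col name of the strain column.
#' @return data.frame with columns `strain`, `n`, `mean_um`, `sd_um`,
#'   `cv_pct`, `cqv_pct`, `skewness`, `q1_um`, `median_um`, `q3_um`,
#'   `min_um`, `max_um`.
#' @export
summarizeStrains <- function(records, length_col = "division_length_um",
                             strain_col = "strain") {
  for (col in c(length_col, strain_col)) {
    if (!col %in% names(records))
      stop(errorCondition(sprintf("missing required column '%s'", col),
           class = c("cellsizer_format_error", "error", "condition")))
  }
  groups <- split(as.numeric(records[[length_col]]),
                  as.character(records[[strain_col]]))
  rows <- lapply(names(groups), function(s) {
    v <- groups[[s]]
    n <- length(v)
    if (n < 2) {
      return(data.frame(strain = s, n = n, mean_um = if (n) mean(v) else NA,
                        sd_um = NA_real_, cv_pct = NA_real_,
                        cqv_pct = NA_real_, skewness = NA_real_,
                        q1_um = NA_real_, median_um = NA_real_,
                        q3_um = NA_real_, min_um = NA_real_,
                        max_um = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      strain = s, n = n, mean_um = mean(v), sd_um = stats::sd(v),
      cv_pct = cvPct(v),
      cqv_pct = if (n >= 4 && q[1] + q[3] > 0) cqvPct(v) else NA_real_,
      skewness = if (n >= 3 && stats::sd(v) > 0) sampleSkewness(v)
                 else NA_real_,
      q1_um = q[1], median_um = q[2], q3_um = q[3],
      min_um = min(v), max_um = max(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a candidate strain for increased size variability at division
#'
#' Applies the four selection gates used to pick size-homeostasis mutant
#' candidates:
#' \itemize{
#'   \item `n_ok`: the candidate sample has at least `min_n` cells
#'     (default 50, the SD-precision minimum);
#'   \item `cv_increased`: candidate CV exceeds the control CV (direction
#'     check);
#'   \item `cv_significant`: the two-sided Feltz-Miller CV-equality test
#'     gives `p < alpha` (default 0.001);
#'   \item `skew_ok`: candidate skewness lies in `skew_range` (default
#'     \[-1, +1\]), excluding distributions skewed towards larger cells by
#'     checkpoint-arrested elongated cells.
#' }
#' `selected` is the conjunction of all four. The significance test is
#' two-sided; directionality comes only from the `cv_increased` gate (the
#' p-value is never halved). An undersized candidate yields
#' `n_ok = FALSE, selected = FALSE`, not an error. The control sample size
#' is reported but not gated.
#'
#' @param candidate,control numeric vectors of division lengths (um), each
#'   n >= 2.
#' @param alpha significance level for the CV-equality test.
#' @param skew_range length-2 numeric, allowed skewness interval.
#' @param min_n minimum candidate sample size.
#' @param strain,control_strain labels for the report.
#' @return a one-row data.frame: `strain`, `n`, `control_n`, `cv_pct`,
#'   `control_cv_pct`, `skewness`, `p_value`, `n_ok`, `cv_increased`,
#'   `cv_significant`, `skew_ok`, `selected`.
#' @examples
#' set.seed(1)
#' ctrl <- rnorm(200, 14, 1.12)
#' cand <- rnorm(200, 14, 2.24)
#' screenSelect(cand, ctrl)$selected
#' @export
screenSelect <- function(candidate, control, alpha = 0.001,
                         skew_range = c(-1, 1), min_n = 50L,
                         strain = "candidate",
                         control_strain = "control") {
  candidate <- as.numeric(candidate)
  control <- as.numeric(control)
  stopIfNot(length(candidate) >= 2 && length(control) >= 2,
            "both samples need n >= 2")
  stopIfNot(length(skew_range) == 2 && skew_range[1] < skew_range[2],
            "skew_range must be an increasing length-2 vector")
  test <- cvEqualityTest(list(control = control, candidate = candidate))
  cv_cand <- cvPct(candidate)
  cv_ctrl <- cvPct(control)
  g1 <- if (stats::sd(candidate) > 0 && length(candidate) >= 3)
    sampleSkewness(candidate) else NA_real_
  n_ok <- length(candidate) >= min_n
  cv_increased <- cv_cand > cv_ctrl
  cv_significant <- test@p_value < alpha
  skew_ok <- !is.na(g1) && g1 >= skew_range[1] && g1 <= skew_range[2]
  data.frame(
    strain = strain, n = length(candidate), control_n = length(control),
    cv_pct = cv_cand, control_cv_pct = cv_ctrl, skewness = g1,
    p_value = test@p_value,
    n_ok = n_ok, cv_increased = cv_increased,
    cv_significant = cv_significant, skew_ok = skew_ok,
    selected = n_ok && cv_increased && cv_significant && skew_ok,
    stringsAsFactors = FALSE)
}

#' Run the screen over a multi-strain table
#'
#' Convenience wrapper: screens every strain in `records` against the named
#' control strain with [screenSelect()].
#'
#' @inheritParams summarizeStrains
#' @param control_strain name of the control strain in `strain_col`.
#' @param ... passed to [screenSelect()].
#' @return data.frame with one [screenSelect()] row per non-control strain.
#' @export
screenStrains <- function(records, control_strain,
                          length_col = "division_length_um",
                          strain_col = "strain", ...) {
  strains <- unique(as.character(records[[strain_col]]))
  stopIfNot(control_strain %in% strains,
            sprintf("control strain '%s' not present", control_strain))
  ctrl <- as.numeric(records[[length_col]][
    records[[strain_col]] == control_strain])
  rows <- lapply(setdiff(strains, control_strain), function(s) {
    cand <- as.numeric(records[[length_col]][records[[strain_col]] == s])
    screenSelect(cand, ctrl, strain = s,
                 control_strain = control_strain, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
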