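#' @import methods
NULL

.CONTROL_MODELS <- c("sizer", "adder", "timer")
.GROWTH_MODELS <- c("linear", "exponential")
.MODE_LABELS <- c("sizer_like", "impaired", "adder_like", "timer_like")

#' Parameters for the stochastic lineage simulator
#'
#' `SimParams` holds the full parameterisation of a single-cell lineage
#' simulation: the division-control model (sizer, adder or timer), the growth
#' law, the stochastic noise sources, and the time-lapse sampling model.
#'
#' @slot control_model `"sizer"`, `"adder"` or `"timer"`. A sizer divides on
#'   reaching a target length, an adder after adding a fixed length increment,
#'   a timer after a fixed duration.
#' @slot growth_model `"linear"` (length grows as `BL + v*t`) or
#'   `"exponential"` (`BL * exp(r*t)`). Fission yeast grows by linear
#'   extension, so `"linear"` is the default.
#' @slot growth_rate linear rate `v` in um/min, or exponential rate `r` in
#'   1/min.
#' @slot target_length sizer target length `L_T` (um).
#' @slot increment adder length increment `Delta` (um).
#' @slot duration timer cycle duration (min).
#' @slot trigger_noise_sd SD of the division-trigger noise: um for
#'   sizer/adder, min for timer.
#' @slot asym_sd SD of the daughter fraction around 0.5 (dimensionless);
#'   fractions are clipped to \[0.3, 0.7\].
#' @slot meas_noise_sd SD of additive length measurement noise (um), applied
#'   independently to recorded birth and division lengths.
#' @slot frame_interval time-lapse frame interval (min); `0` disables frame
#'   sampling and records true lengths and times.
#' @slot n_founders number of founder cells.
#' @slot founder_mean,founder_sd normal distribution of founder birth lengths
#'   (um).
#' @slot max_generations cells are recorded for this many generations
#'   (founders are generation 1).
#' @slot total_time simulated observation window (min); only cells dividing
#'   within it are emitted.
#' @slot seed integer seed; identical seed and parameters give bit-identical
#'   output.
#'
#' @seealso [SimParams()], [simulateLineages()], [sizerPreset()]
#' @export
setClass("SimParams",
  slots = c(
    control_model = "character",
    growth_model = "character",
    growth_rate = "numeric",
    target_length = "numeric",
    increment = "numeric",
    duration = "numeric",
    trigger_noise_sd = "numeric",
    asym_sd = "numeric",
    meas_noise_sd = "numeric",
    frame_interval = "numeric",
    n_founders = "integer",
    founder_mean = "numeric",
    founder_sd = "numeric",
    max_generations = "integer",
    total_time = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (!object@control_model %in% .CONTROL_MODELS)
    msg <- c(msg, sprintf("control_model must be one of %s",
                          paste(.CONTROL_MODELS, collapse = ", ")))
  if (!object@growth_model %in% .GROWTH_MODELS)
    msg <- c(msg, sprintf("growth_model must be one of %s",
                          paste(.GROWTH_MODELS, collapse = ", ")))
  if (!isTRUE(object@growth_rate > 0))
    msg <- c(msg, "growth_rate must be > 0")
  trig <- switch(object@control_model,
    sizer = object@target_length,
    adder = object@increment,
    timer = object@duration)
  if (!isTRUE(trig > 0))
    msg <- c(msg, sprintf("trigger parameter for the %s model must be > 0",
                          object@control_model))
  for (s in c("trigger_noise_sd", "asym_sd", "meas_noise_sd")) {
    if (!isTRUE(slot(object, s) >= 0)) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (!isTRUE(object@frame_interval >= 0))
    msg <- c(msg, "frame_interval must be >= 0")
  if (!isTRUE(object@n_founders >= 1L))
    msg <- c(msg, "n_founders must be >= 1")
  if (!isTRUE(object@founder_mean > 0))
    msg <- c(msg, "founder_mean must be > 0")
  if (!isTRUE(object@founder_sd >= 0))
    msg <- c(msg, "founder_sd must be >= 0")
  if (!isTRUE(object@max_generations >= 1L))
    msg <- c(msg, "max_generations must be >= 1")
  if (!isTRUE(object@total_time > 0))
    msg <- c(msg, "total_time must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' Constructor for [SimParams-class]. Defaults describe a wild-type-like
#' fission yeast population: sizer control with a 14 um division target,
#' linear extension at 0.0467 um/min, 1.12 um trigger noise (division-length
#' CV of 8%), near-symmetric division, 10-min time-lapse frames and three
#' recorded generations.
#'
#' @param control_model,growth_model,growth_rate,target_length,increment
#'   see [SimParams-class].
#' @param duration,trigger_noise_sd,asym_sd,meas_noise_sd,frame_interval
#'   see [SimParams-class].
#' @param n_founders,founder_mean,founder_sd,max_generations,total_time,seed
#'   see [SimParams-class].
#' @return a validated `SimParams` object.
#' @examples
#' p <- SimParams(trigger_noise_sd = 0, asym_sd = 0, frame_interval = 0,
#'                founder_sd = 0, founder_mean = 7, n_founders = 2)
#' recs <- simulateLineages(p)
#' all(recs$division_length_um == 14)
#' @export
SimParams <- function(control_model = "sizer",
                      growth_model = "linear",
                      growth_rate = 0.0467,
                      target_length = 14,
                      increment = 7,
                      duration = 140,
                      trigger_noise_sd = 1.12,
                      asym_sd = 0.02,
                      meas_noise_sd = 0,
                      frame_interval = 10,
                      n_founders = 100L,
                      founder_mean = 7,
                      founder_sd = 0.7,
                      max_generations = 3L,
                      total_time = 720,
                      seed = 1L) {
  new("SimParams",
      control_model = control_model,
      growth_model = growth_model,
      growth_rate = as.numeric(growth_rate),
      target_length = as.numeric(target_length),
      increment = as.numeric(increment),
      duration = as.numeric(duration),
      trigger_noise_sd = as.numeric(trigger_noise_sd),
      asym_sd = as.numeric(asym_sd),
      meas_noise_sd = as.numeric(meas_noise_sd),
      frame_interval = as.numeric(frame_interval),
      n_founders = as.integer(n_founders),
      founder_mean = as.numeric(founder_mean),
      founder_sd = as.numeric(founder_sd),
      max_generations = as.integer(max_generations),
      total_time = as.numeric(total_time),
      seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  trig <- switch(object@control_model,
    sizer = sprintf("target L_T = %g um", object@target_length),
    adder = sprintf("increment Delta = %g um", object@increment),
    timer = sprintf("duration = %g min", object@duration))
  cat("SimParams:", object@control_model, "control,",
      object@growth_model, "growth\n")
  cat("  ", trig, ", trigger noise SD ", object@trigger_noise_sd, "\n",
      sep = "")
  cat(sprintf("  growth rate %g, asym SD %g, meas noise SD %g um\n",
              object@growth_rate, object@asym_sd, object@meas_noise_sd))
  cat(sprintf("  frames every %g min, %d founders (N(%g, %g)), %d generations, %g min, seed %d\n",
              object@frame_interval, object@n_founders, object@founder_mean,
              object@founder_sd, object@max_generations, object@total_time,
              object@seed))
})

#' Parameters for the multinucleate division-synchrony simulator
#'
#' Emulates cytokinesis-blocked cells whose nuclei divide once per nuclear
#' cycle: in `synchronous` mode all nuclei in a cell divide together (counts
#' 1, 2, 4, 8, ...); in `independent` mode each nucleus divides independently
#' with probability `division_prob`, producing intermediate counts (3, 5, 6,
#' 7, ...) that mark loss of synchrony.
#'
#' @slot mode `"synchronous"` or `"independent"`.
#' @slot division_prob per-nucleus per-cycle division probability in
#'   \[0, 1\] (independent mode; ignored when synchronous).
#' @slot n_cycles number of nuclear division cycles.
#' @slot n_cells number of cells.
#' @slot seed integer seed.
#' @seealso [MultinucSimParams()], [simulateMultinucleate()]
#' @export
setClass("MultinucSimParams",
  slots = c(
    mode = "character",
    division_prob = "numeric",
    n_cycles = "integer",
    n_cells = "integer",
    seed = "integer"
  )
)

setValidity("MultinucSimParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("synchronous", "independent"))
    msg <- c(msg, "mode must be 'synchronous' or 'independent'")
  if (!isTRUE(object@division_prob >= 0 && object@division_prob <= 1))
    msg <- c(msg, "division_prob must be in [0, 1]")
  if (!isTRUE(object@n_cycles >= 1L)) msg <- c(msg, "n_cycles must be >= 1")
  if (!isTRUE(object@n_cells >= 1L)) msg <- c(msg, "n_cells must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname MultinucSimParams-class
#' @param mode,division_prob,n_cycles,n_cells,seed see slots.
#' @return a validated `MultinucSimParams` object.
#' @export
MultinucSimParams <- function(mode = "synchronous",
                              division_prob = 1,
                              n_cycles = 3L,
                              n_cells = 500L,
                              seed = 1L) {
  new("MultinucSimParams", mode = mode,
      division_prob = as.numeric(division_prob),
      n_cycles = as.integer(n_cycles), n_cells = as.integer(n_cells),
      seed = as.integer(seed))
}

setMethod("show", "MultinucSimParams", function(object) {
  cat(sprintf("MultinucSimParams: %s mode, q = %g, %d cycles, %d cells, seed %d\n",
              object@mode, object@division_prob, object@n_cycles,
              object@n_cells, object@seed))
})

#' Parameters for the per-nucleus intensity simulator
#'
#' Emulates per-nucleus fluorescence measurements in multinucleate cells: a
#' cell-level mean intensity drawn from
#' `N(mean_intensity, between_cell_sd)` and per-nucleus intensities drawn
#' around it with SD `within_cell_sd`. High within-cell SD mimics
#' uncoordinated nuclear accumulation of a fluorescent cell-cycle marker.
#'
#' @slot n_cells number of cells.
#' @slot nuclei_per_cell nuclei per cell (>= 2; default 4, matching
#'   four-nuclei cells).
#' @slot between_cell_sd,within_cell_sd,mean_intensity intensity model in
#'   arbitrary units; intensities are floored at a small positive value.
#' @slot seed integer seed.
#' @seealso [IntensitySimParams()], [simulateNuclearIntensities()]
#' @export
setClass("IntensitySimParams",
  slots = c(
    n_cells = "integer",
    nuclei_per_cell = "integer",
    between_cell_sd = "numeric",
    within_cell_sd = "numeric",
    mean_intensity = "numeric",
    seed = "integer"
  )
)

setValidity("IntensitySimParams", function(object) {
  msg <- character()
  if (!isTRUE(object@n_cells >= 1L)) msg <- c(msg, "n_cells must be >= 1")
  if (!isTRUE(object@nuclei_per_cell >= 2L))
    msg <- c(msg, "nuclei_per_cell must be >= 2")
  if (!isTRUE(object@between_cell_sd >= 0))
    msg <- c(msg, "between_cell_sd must be >= 0")
  if (!isTRUE(object@within_cell_sd >= 0))
    msg <- c(msg, "within_cell_sd must be >= 0")
  if (!isTRUE(object@mean_intensity > 0))
    msg <- c(msg, "mean_intensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname IntensitySimParams-class
#' @param n_cells,nuclei_per_cell,between_cell_sd,within_cell_sd see slots.
#' @param mean_intensity,seed see slots.
#' @return a validated `IntensitySimParams` object.
#' @export
IntensitySimParams <- function(n_cells = 5L,
                               nuclei_per_cell = 4L,
                               between_cell_sd = 10,
                               within_cell_sd = 5,
                               mean_intensity = 100,
                               seed = 1L) {
  new("IntensitySimParams", n_cells = as.integer(n_cells),
      nuclei_per_cell = as.integer(nuclei_per_cell),
      between_cell_sd = as.numeric(between_cell_sd),
      within_cell_sd = as.numeric(within_cell_sd),
      mean_intensity = as.numeric(mean_intensity),
      seed = as.integer(seed))
}

setMethod("show", "IntensitySimParams", function(object) {
  cat(sprintf("IntensitySimParams: %d cells x %d nuclei, mean %g a.u., between SD %g, within SD %g, seed %d\n",
              object@n_cells, object@nuclei_per_cell, object@mean_intensity,
              object@between_cell_sd, object@within_cell_sd, object@seed))
})

#' Result of the asymptotic test for equality of coefficients of variation
#'
#' @slot groups group labels.
#' @slot cv per-group CV as a fraction (`s_i / mean_i`).
#' @slot n per-group sample sizes.
#' @slot weights per-group weights `m_i = n_i - 1`.
#' @slot pooled_cv weighted pooled CV (fraction).
#' @slot statistic the asymptotic chi-square statistic `D_AD`.
#' @slot df degrees of freedom (`k - 1`).
#' @slot p_value upper-tail chi-square p-value.
#' @slot method description of the test variant.
#' @seealso [cvEqualityTest()], [cvEqualityPermutation()]
#' @export
setClass("CVTestResult",
  slots = c(
    groups = "character",
    cv = "numeric",
    n = "integer",
    weights = "numeric",
    pooled_cv = "numeric",
    statistic = "numeric",
    df = "integer",
    p_value = "numeric",
    method = "character"
  )
)

setValidity("CVTestResult", function(object) {
  msg <- character()
  if (!isTRUE(object@statistic >= 0)) msg <- c(msg, "statistic must be >= 0")
  if (!isTRUE(object@p_value >= 0 && object@p_value <= 1))
    msg <- c(msg, "p_value must be in [0, 1]")
  if (length(object@groups) != length(object@cv))
    msg <- c(msg, "groups and cv must have equal length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CVTestResult", function(object) {
  cat(object@method, "\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d, CV=%.2f%%)", object@groups, object@n,
                            100 * object@cv), collapse = ", ")))
  cat(sprintf("  pooled CV = %.2f%%, D_AD = %.4g, df = %d, p = %.4g\n",
              100 * object@pooled_cv, object@statistic, object@df,
              object@p_value))
})

#' Birth-length versus extension (BL/E) homeostasis fit
#'
#' Ordinary least squares of per-cycle length extension `E = D - BL` on birth
#' length `BL`, fitted on the raw non-cohorted records, together with the
#' 0.5 um birth-length cohort table used for display and the size-control
#' classification of the slope.
#'
#' @slot strain strain label.
#' @slot n number of cells in the fit.
#' @slot slope,intercept,slope_se,r_squared OLS estimates; the slope is
#'   dimensionless, the intercept in um.
#' @slot cohorts data.frame of birth-length cohorts: `bin_start`, `bin_end`,
#'   `n`, `mean_bl`, `mean_e`, `sd_e`, `low_n` flag.
#' @slot mode_label `"sizer_like"`, `"impaired"`, `"adder_like"` or
#'   `"timer_like"`.
#' @slot n_negative_extension number of retained records with E < 0.
#' @seealso [fitBLE()], [classifyControlMode()], [cohortByBirthLength()]
#' @export
setClass("HomeostasisFit",
  slots = c(
    strain = "character",
    n = "integer",
    slope = "numeric",
    intercept = "numeric",
    slope_se = "numeric",
    r_squared = "numeric",
    cohorts = "data.frame",
    mode_label = "character",
    n_negative_extension = "integer"
  )
)

setValidity("HomeostasisFit", function(object) {
  msg <- character()
  if (!object@mode_label %in% .MODE_LABELS)
    msg <- c(msg, sprintf("mode_label must be one of %s",
                          paste(.MODE_LABELS, collapse = ", ")))
  if (!isTRUE(object@r_squared >= 0 && object@r_squared <= 1 + 1e-12))
    msg <- c(msg, "r_squared must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HomeostasisFit", function(object) {
  cat(sprintf("BL/E homeostasis fit for '%s' (n = %d cells)\n",
              object@strain, object@n))
  cat(sprintf("  slope = %.3f (SE %.3f), intercept = %.3f um, R^2 = %.3f\n",
              object@slope, object@slope_se, object@intercept,
              object@r_squared))
  cat(sprintf("  control mode: %s; %d cohorts; %d record(s) with negative extension\n",
              object@mode_label, nrow(object@cohorts),
              object@n_negative_extension))
})
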