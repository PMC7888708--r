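#' Simulate single-cell lineages under sizer, adder or timer control
#'
#' Generates completed cell cycles for a population founded by
#' `n_founders` cells with birth lengths drawn from
#' `N(founder_mean, founder_sd)` (truncated to positive values). Each cell
#' grows continuously (linear `L(t) = BL + v t` or exponential
#' `L(t) = BL e^{r t}`) and divides when its control trigger fires:
#' at length `L_T + eps` (sizer), at length `BL + Delta + eps` (adder) or at
#' age `T_dur + eps` (timer), with `eps ~ N(0, trigger_noise_sd)` drawn
#' independently per cell. At division the daughters receive fractions `f`
#' and `1 - f` of the division length, `f ~ N(0.5, asym_sd)` clipped to
#' \[0.3, 0.7\].
#'
#' When `frame_interval > 0`, recorded quantities follow the time-lapse
#' convention: birth length is the true length at the first frame at or after
#' the actual birth, division length the true length at the last frame at or
#' before the actual division, each perturbed by independent
#' `N(0, meas_noise_sd)` measurement noise, and cycle time is the difference
#' of the two frame times. With `frame_interval = 0` true lengths and times
#' are recorded (plus measurement noise if any).
#'
#' Cells whose trigger is already satisfied at birth divide after one frame
#' interval (one minute when frame sampling is disabled) and are flagged, not
#' dropped. Only cells with `generation <= max_generations` that divide
#' before `total_time` are emitted.
#'
#' @param params a [SimParams-class] object.
#' @param strain strain label stored in the records.
#' @return a data.frame of completed cell cycles with columns `cell_id`,
#'   `lineage_id`, `strain`, `generation`, `birth_time_min`,
#'   `birth_length_um`, `division_length_um`, `extension_um`,
#'   `cycle_time_min` and `flagged` (trigger satisfied at birth or
#'   non-positive recorded cycle time). `extension_um` is exactly
#'   `division_length_um - birth_length_um`. Attributes: `n_flagged_trigger`,
#'   `n_clipped_fraction`, and `frame_convention` describing the sampling
#'   rule.
#' @examples
#' recs <- simulateLineages(sizerPreset(n_founders = 10))
#' head(recs)
#' @seealso [SimParams()], [sizerPreset()], [adderPreset()], [timerPreset()]
#' @export
simulateLineages <- function(params, strain = "sim") {
  validObject(params)
  gm <- params@growth_model
  rate <- params@growth_rate
  dt <- params@frame_interval
  sm <- params@meas_noise_sd

  withSeed(params@seed, {
    # founders: truncated-normal birth lengths (resample non-positive draws)
    bl <- stats::rnorm(params@n_founders, params@founder_mean,
                       params@founder_sd)
    for (i in seq_len(100)) {
      bad <- bl <= 0
      if (!any(bad)) break
      bl[bad] <- stats::rnorm(sum(bad), params@founder_mean,
                              params@founder_sd)
    }
    stopIfNot(all(bl > 0), "could not draw positive founder lengths")

    t_birth <- rep(0, params@n_founders)
    lineage <- seq_len(params@n_founders)
    n_flag_trigger <- 0L
    n_clip <- 0L
    out <- vector("list", params@max_generations)

    for (g in seq_len(params@max_generations)) {
      n <- length(bl)
      if (n == 0L) break
      eps <- stats::rnorm(n, 0, params@trigger_noise_sd)

      # trigger length (sizer/adder) or age (timer)
      if (params@control_model == "timer") {
        tau <- params@duration + eps
        tau[!is.finite(tau)] <- -1
      } else {
        l_trig <- switch(params@control_model,
          sizer = params@target_length + eps,
          adder = bl + params@increment + eps)
        if (gm == "linear") {
          tau <- (l_trig - bl) / rate
        } else {
          tau <- ifelse(l_trig > bl, log(l_trig / bl) / rate, -1)
        }
      }
      flagged <- !is.finite(tau) | tau <= 0
      n_flag_trigger <- n_flag_trigger + sum(flagged)
      tau[flagged] <- if (dt > 0) dt else 1

      d_true <- growLength(bl, tau, gm, rate)
      t_div <- t_birth + tau

      if (dt > 0) {
        fb <- ceiling(t_birth / dt) * dt
        fd <- floor(t_div / dt) * dt
        bl_rec <- growLength(bl, fb - t_birth, gm, rate)
        d_rec <- growLength(bl, fd - t_birth, gm, rate)
        ct_rec <- fd - fb
        tb_rec <- fb
      } else {
        bl_rec <- bl
        d_rec <- d_true
        ct_rec <- tau
        tb_rec <- t_birth
      }
      if (sm > 0) {
        bl_rec <- bl_rec + stats::rnorm(n, 0, sm)
        d_rec <- d_rec + stats::rnorm(n, 0, sm)
      }
      flagged <- flagged | ct_rec <= 0

      emit <- t_div <= params@total_time
      if (any(emit)) {
        out[[g]] <- data.frame(
          cell_id = sprintf("L%d_G%d_C%d", lineage[emit], g,
                            seq_len(sum(emit))),
          lineage_id = lineage[emit],
          strain = strain,
          generation = g,
          birth_time_min = tb_rec[emit],
          birth_length_um = bl_rec[emit],
          division_length_um = d_rec[emit],
          extension_um = d_rec[emit] - bl_rec[emit],
          cycle_time_min = ct_rec[emit],
          flagged = flagged[emit],
          stringsAsFactors = FALSE
        )
      }

      if (g < params@max_generations && any(emit)) {
        nd <- sum(emit)
        f <- stats::rnorm(nd, 0.5, params@asym_sd)
        clip <- f < 0.3 | f > 0.7
        n_clip <- n_clip + sum(clip)
        f <- pmin(pmax(f, 0.3), 0.7)
        bl <- c(f * d_true[emit], (1 - f) * d_true[emit])
        t_birth <- rep(t_div[emit], 2L)
        lineage <- rep(lineage[emit], 2L)
      } else {
        bl <- numeric(0)
      }
    }

    recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(recs)) {
      stop("no completed cell cycles within total_time")
    }
    rownames(recs) <- NULL
    attr(recs, "n_flagged_trigger") <- n_flag_trigger
    attr(recs, "n_clipped_fraction") <- n_clip
    attr(recs, "frame_convention") <-
      if (dt > 0) {
        paste0("birth: first frame at/after separation; division: last ",
               "frame at/before division; frame interval ", dt, " min")
      } else {
        "continuous (no frame sampling)"
      }
    recs
  })
}

#' Wild-type-like sizer preset
#'
#' Sizer control with target length 14 um, trigger noise SD 1.12 um (an 8%
#' division-length CV), linear extension at 0.0467 um/min and near-symmetric
#' division. Founder birth lengths are centred at half the target with the
#' stationary birth SD (half the division SD). Frame sampling and
#' measurement noise are off by default so that the recorded lengths are the
#' true lengths; set `frame_interval = 10` for the time-lapse convention.
#'
#' @param n_founders number of founders; with three recorded generations each
#'   founder contributes up to 7 completed cycles.
#' @param seed integer seed.
#' @param frame_interval,meas_noise_sd see [SimParams-class].
#' @return a [SimParams-class] object.
#' @export
sizerPreset <- function(n_founders = 100L, seed = 1L, frame_interval = 0,
                        meas_noise_sd = 0) {
  SimParams(control_model = "sizer", growth_model = "linear",
            growth_rate = 0.0467, target_length = 14,
            trigger_noise_sd = 1.12, asym_sd = 0.02,
            meas_noise_sd = meas_noise_sd, frame_interval = frame_interval,
            n_founders = n_founders, founder_mean = 7, founder_sd = 0.56,
            max_generations = 3L, total_time = 1e6, seed = seed)
}

#' Adder-like preset with doubled size variability
#'
#' Adder control adding 7 um per cycle with trigger noise SD 1.94 um, chosen
#' so that the stationary division-length CV is about 16% (the adder
#' stationary SD is `sqrt(4/3)` times the per-cycle noise SD): twice the
#' sizer preset's 8%. Founders start at the 7 um fixed point with the
#' stationary birth SD.
#'
#' @inheritParams sizerPreset
#' @return a [SimParams-class] object.
#' @export
adderPreset <- function(n_founders = 100L, seed = 1L, frame_interval = 0,
                        meas_noise_sd = 0) {
  SimParams(control_model = "adder", growth_model = "linear",
            growth_rate = 0.0467, increment = 7,
            trigger_noise_sd = 1.94, asym_sd = 0.02,
            meas_noise_sd = meas_noise_sd, frame_interval = frame_interval,
            n_founders = n_founders, founder_mean = 7, founder_sd = 1.12,
            max_generations = 3L, total_time = 1e6, seed = seed)
}

#' Timer preset under exponential growth
#'
#' Timer control with a 140-min cycle and exponential growth at rate
#' `log(2)/140` per min, so length doubles over one mean cycle
#' (`r * T = log 2`). Under exponential growth a timer has no size feedback
#' and the BL/E slope is positive (about +1 at `r T = log 2`).
#'
#' @inheritParams sizerPreset
#' @param trigger_noise_sd timer duration noise SD in minutes.
#' @return a [SimParams-class] object.
#' @export
timerPreset <- function(n_founders = 100L, seed = 1L, frame_interval = 0,
                        meas_noise_sd = 0, trigger_noise_sd = 10) {
  SimParams(control_model = "timer", growth_model = "exponential",
            growth_rate = log(2) / 140, duration = 140,
            trigger_noise_sd = trigger_noise_sd, asym_sd = 0.02,
            meas_noise_sd = meas_noise_sd, frame_interval = frame_interval,
            n_founders = n_founders, founder_mean = 7, founder_sd = 0.7,
            max_generations = 3L, total_time = 1e6, seed = seed)
}

#' Simulate nuclei counts in cytokinesis-blocked cells
#'
#' Every cell starts with one nucleus. Per nuclear cycle, `synchronous` mode
#' doubles every cell's nuclei (1, 2, 4, 8, ...); `independent` mode divides
#' each nucleus independently with probability `division_prob`, so a cell
#' with `k` nuclei gains `Binomial(k, q)` nuclei. Counts outside the
#' power-of-two series (3, 5, 6, 7) mark asynchronous nuclear division.
#'
#' @param params a [MultinucSimParams-class] object.
#' @return a long data.frame with columns `cell_id`, `cycle` (1-based) and
#'   `nuclei_count`, giving each cell's count after each cycle.
#' @examples
#' counts <- simulateMultinucleate(MultinucSimParams(mode = "synchronous",
#'                                                   n_cycles = 3,
#'                                                   n_cells = 4))
#' subset(counts, cycle == 3)$nuclei_count  # all 8
#' @export
simulateMultinucleate <- function(params) {
  validObject(params)
  withSeed(params@seed, {
    counts <- rep(1L, params@n_cells)
    out <- vector("list", params@n_cycles)
    for (cyc in seq_len(params@n_cycles)) {
      if (params@mode == "synchronous") {
        counts <- counts * 2L
      } else {
        counts <- counts + stats::rbinom(params@n_cells, counts,
                                         params@division_prob)
      }
      out[[cyc]] <- data.frame(cell_id = seq_len(params@n_cells),
                               cycle = cyc, nuclei_count = counts)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate per-nucleus fluorescence intensities
#'
#' Each cell's mean intensity is drawn from
#' `N(mean_intensity, between_cell_sd)` and its per-nucleus intensities from
#' `N(cell mean, within_cell_sd)`. Intensities are floored at a small
#' positive value (1e-6 of the mean) so downstream CVs are defined.
#'
#' @param params an [IntensitySimParams-class] object.
#' @return a long data.frame with columns `cell_id`, `nucleus_index` and
#'   `intensity_au`.
#' @seealso [perCellIntensityCV()]
#' @export
simulateNuclearIntensities <- function(params) {
  validObject(params)
  withSeed(params@seed, {
    mu <- stats::rnorm(params@n_cells, params@mean_intensity,
                       params@between_cell_sd)
    k <- params@nuclei_per_cell
    vals <- stats::rnorm(params@n_cells * k, rep(mu, each = k),
                         params@within_cell_sd)
    floor_val <- 1e-6 * params@mean_intensity
    vals <- pmax(vals, floor_val)
    data.frame(cell_id = rep(seq_len(params@n_cells), each = k),
               nucleus_index = rep(seq_len(k), times = params@n_cells),
               intensity_au = vals)
  })
}
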