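.RECORD_COLS <- c("cell_id", "lineage_id", "strain", "generation",
                  "birth_time_min", "birth_length_um",
                  "division_length_um", "extension_um", "cycle_time_min")
.NUMERIC_RECORD_COLS <- c("generation", "birth_time_min", "birth_length_um",
                          "division_length_um", "extension_um",
                          "cycle_time_min")

formatError <- function(msg) {
  stop(errorCondition(msg,
       class = c("cellsizer_format_error", "error", "condition")))
}

.delimFor <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a table of single-cell records
#'
#' Reads a CSV or TSV (delimiter chosen from the file extension: `.tsv` /
#' `.txt` are tab-separated) of completed cell cycles and validates it:
#' all required columns must be present, numeric columns must parse (a
#' failing row is reported with its line number), and lengths outside the
#' 1-50 um range trigger a unit-sanity warning.
#'
#' @param path file path.
#' @param required required column names; defaults to the full cell-record
#'   header.
#' @return validated data.frame of records.
#' @seealso [writeCellRecords()]
#' @export
readCellRecords <- function(path, required = .RECORD_COLS) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  for (col in intersect(.NUMERIC_RECORD_COLS, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      formatError(sprintf(
        "non-numeric value '%s' in column '%s' at line %d",
        df[[col]][bad[1]], col, bad[1] + 1L))
    df[[col]] <- v
  }
  if ("flagged" %in% names(df)) df$flagged <- as.logical(df$flagged)
  for (col in intersect(c("birth_length_um", "division_length_um"),
                        names(df))) {
    out_of_range <- df[[col]] < 1 | df[[col]] > 50
    if (any(out_of_range, na.rm = TRUE))
      warning(sprintf(
        "%d value(s) in '%s' outside the 1-50 um range; check units",
        sum(out_of_range, na.rm = TRUE), col))
  }
  df
}

#' Write cell records to CSV/TSV
#'
#' Writes the standard cell-record header (`cell_id, lineage_id, strain,
#' generation, birth_time_min, birth_length_um, division_length_um,
#' extension_um, cycle_time_min`); column names carry the units. The
#' delimiter follows the file extension.
#'
#' @param records data.frame of records.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
writeCellRecords <- function(records, path) {
  missing <- setdiff(.RECORD_COLS, names(records))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  utils::write.table(records[, .RECORD_COLS], path, sep = .delimFor(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read long-format nuclei counts
#'
#' Long format with header `cell_id, cycle, nuclei_count`, as produced by
#' [simulateMultinucleate()].
#'
#' @param counts data.frame with columns `cell_id`, `cycle`,
#'   `nuclei_count`.
#' @param path file path.
#' @return `path` invisibly (write) or the validated data.frame (read).
#' @export
writeNucleiCounts <- function(counts, path) {
  cols <- c("cell_id", "cycle", "nuclei_count")
  missing <- setdiff(cols, names(counts))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  utils::write.table(counts[, cols], path, sep = .delimFor(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNucleiCounts
#' @export
readNucleiCounts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_id", "cycle", "nuclei_count"), names(df))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  df
}

#' Write / read long-format per-nucleus intensities
#'
#' Long format with header `cell_id, nucleus_index, intensity_au`, as
#' produced by [simulateNuclearIntensities()].
#'
#' @param intensities data.frame with columns `cell_id`, `nucleus_index`,
#'   `intensity_au`.
#' @param path file path.
#' @return `path` invisibly (write) or the validated data.frame (read).
#' @export
writeIntensities <- function(intensities, path) {
  cols <- c("cell_id", "nucleus_index", "intensity_au")
  missing <- setdiff(cols, names(intensities))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  utils::write.table(intensities[, cols], path, sep = .delimFor(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIntensities
#' @export
readIntensities <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_id", "nucleus_index", "intensity_au"),
                     names(df))
  if (length(missing))
    formatError(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  df
}

.simParamsFromList <- function(x) {
  known <- names(formals(SimParams))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    formatError(sprintf("unknown SimParams field(s): %s",
                        paste(unknown, collapse = ", ")))
  do.call(SimParams, x)
}

.simParamsToList <- function(p) {
  fields <- names(formals(SimParams))
  out <- lapply(fields, function(f) slot(p, f))
  names(out) <- fields
  out
}

.defaultConfig <- function() {
  list(
    seed = 1L,
    output_dir = "cellsizer_out",
    control = "wildtype",
    alpha = 0.001,
    skew_range = c(-1, 1),
    min_n = 50L,
    cohort_width = 0.5,
    thresholds = list(sizer = -0.6, impaired = -0.2, timer = 0.2),
    strains = list(
      wildtype = .simParamsToList(sizerPreset()),
      mutant = .simParamsToList(adderPreset())
    ),
    multinucleate = NULL,
    intensities = NULL,
    log_level = "INFO"
  )
}

#' Read / write a pipeline run configuration
#'
#' The configuration is a YAML file whose field names mirror the function
#' arguments they configure: top-level `seed`, `output_dir`, `control`,
#' `alpha`, `skew_range`, `min_n`, `cohort_width`, `thresholds`
#' (`sizer`/`impaired`/`timer`), a `strains` block of named
#' [SimParams()] field lists, and optional `multinucleate`
#' ([MultinucSimParams()] fields) and `intensities`
#' ([IntensitySimParams()] fields) blocks. Missing fields take the
#' documented defaults; unknown simulator fields are an error. Writing a
#' configuration and reading it back round-trips exactly.
#'
#' @param path YAML file path.
#' @return a named configuration list.
#' @seealso [runPipeline()]
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- .defaultConfig()
  for (nm in names(user)) cfg[nm] <- list(user[[nm]])  # keeps NULL blocks
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_n <- as.integer(cfg$min_n)
  cfg$skew_range <- as.numeric(unlist(cfg$skew_range))
  th <- cfg$thresholds
  stopIfNot(all(c("sizer", "impaired", "timer") %in% names(th)),
            "thresholds needs named fields sizer, impaired, timer")
  cfg$thresholds <- list(sizer = as.numeric(th[["sizer"]]),
                         impaired = as.numeric(th[["impaired"]]),
                         timer = as.numeric(th[["timer"]]))
  stopIfNot(length(cfg$strains) >= 1, "config needs at least one strain")
  # validate simulator blocks early so errors name the offending stage
  for (s in names(cfg$strains)) .simParamsFromList(cfg$strains[[s]])
  cfg
}

#' @rdname readRunConfig
#' @param config configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates every configured strain, writes the combined cell records,
#' per-strain summaries, screen decisions against the control strain,
#' BL/E homeostasis fits with cohort tables, optional multinucleate and
#' intensity outputs, and a run manifest (seed, package version, parameter
#' echo, flagged-record counts). The run is deterministic given the
#' configuration: per-strain seeds are derived as `seed + strain index`,
#' and the manifest contains no timestamps, so repeated runs are
#' byte-identical.
#'
#' @param config configuration list (see [readRunConfig()]); defaults to
#'   the built-in two-strain (sizer wild type vs adder mutant)
#'   configuration.
#' @param output_dir overrides `config$output_dir`.
#' @return invisibly, a list with the computed `records`, `summaries`,
#'   `decisions`, `fits` and the output file paths.
#' @export
runPipeline <- function(config = .defaultConfig(),
                        output_dir = config$output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    strains <- names(config$strains)
    rec_list <- vector("list", length(strains))
    flagged <- integer(length(strains))
    clipped <- integer(length(strains))
    for (i in seq_along(strains)) {
      pl <- config$strains[[i]]
      pl$seed <- as.integer(config$seed + i)
      p <- .simParamsFromList(pl)
      r <- simulateLineages(p, strain = strains[i])
      flagged[i] <- attr(r, "n_flagged_trigger")
      clipped[i] <- attr(r, "n_clipped_fraction")
      rec_list[[i]] <- r
    }
    records <- do.call(rbind, rec_list)
    writeCellRecords(records, file.path(output_dir, "cell_records.csv"))

    stage <- "summarize"
    summaries <- summarizeStrains(records)
    utils::write.csv(summaries, file.path(output_dir, "summaries.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "screen"
    decisions <- if (length(strains) > 1 &&
                     config$control %in% strains) {
      d <- screenStrains(records, config$control, alpha = config$alpha,
                         skew_range = config$skew_range,
                         min_n = config$min_n)
      utils::write.csv(d, file.path(output_dir, "screen_decisions.csv"),
                       row.names = FALSE, quote = FALSE)
      d
    } else NULL

    stage <- "homeostasis"
    fits <- lapply(strains, function(s) {
      fitBLE(records[records$strain == s, , drop = FALSE], strain = s,
             cohort_width = config$cohort_width,
             thresholds = unlist(config$thresholds))
    })
    names(fits) <- strains
    fit_df <- do.call(rbind, lapply(fits, function(f) data.frame(
      strain = f@strain, n = f@n, slope = f@slope,
      intercept_um = f@intercept, slope_se = f@slope_se,
      r_squared = f@r_squared, mode_label = f@mode_label,
      n_negative_extension = f@n_negative_extension,
      stringsAsFactors = FALSE)))
    utils::write.csv(fit_df, file.path(output_dir, "homeostasis_fits.csv"),
                     row.names = FALSE, quote = FALSE)
    cohort_df <- do.call(rbind, lapply(fits, function(f)
      cbind(strain = f@strain, f@cohorts)))
    utils::write.csv(cohort_df, file.path(output_dir, "cohorts.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "multinuclear"
    multinuc <- NULL
    if (!is.null(config$multinucleate)) {
      mp <- do.call(MultinucSimParams, c(config$multinucleate,
                                         list(seed = config$seed)))
      counts <- simulateMultinucleate(mp)
      writeNucleiCounts(counts,
                        file.path(output_dir, "nuclei_counts.csv"))
      final <- counts$nuclei_count[counts$cycle == max(counts$cycle)]
      multinuc <- nucleiCountDistribution(final)
      utils::write.csv(multinuc,
                       file.path(output_dir, "nuclei_distribution.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    intens <- NULL
    if (!is.null(config$intensities)) {
      ip <- do.call(IntensitySimParams, c(config$intensities,
                                          list(seed = config$seed)))
      iv <- simulateNuclearIntensities(ip)
      writeIntensities(iv, file.path(output_dir, "intensities.csv"))
      intens <- perCellIntensityCV(iv)
      utils::write.csv(intens,
                       file.path(output_dir, "intensity_cv.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    stage <- "manifest"
    manifest <- list(
      package = "cellsizer",
      version = as.character(utils::packageVersion("cellsizer")),
      seed = config$seed,
      control = config$control,
      parameters = config,
      n_records = nrow(records),
      n_flagged_trigger = as.list(stats::setNames(flagged, strains)),
      n_clipped_fraction = as.list(stats::setNames(clipped, strains)),
      n_negative_extension = sum(fit_df$n_negative_extension)
    )
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
    if (identical(config$log_level, "INFO")) {
      message(sprintf(
        "pipeline: %d records; flagged triggers %d; clipped fractions %d; negative extensions %d",
        nrow(records), sum(flagged), sum(clipped),
        sum(fit_df$n_negative_extension)))
    }
    list(records = records, summaries = summaries, decisions = decisions,
         fits = fits, multinucleate = multinuc, intensities = intens,
         output_dir = output_dir)
  }, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage,
              conditionMessage(e)),
      class = c("cellsizer_pipeline_error", "error", "condition")))
  })
  invisible(res)
}
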