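utils::globalVariables(c("birth_length_um", "extension_um", "mean_bl",
                         "mean_e", "sd_e", "division_length_um"))

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Length at time t for a cell born at length bl.
growLength <- function(bl, t, growth_model, rate) {
  if (growth_model == "linear") bl + rate * t else bl * exp(rate * t)
}

stopIfNot <- function(cond, msg, class = "cellsizer_error") {
  if (!isTRUE(cond)) {
    stop(errorCondition(msg, class = c(class, "error", "condition")))
  }
  invisible(TRUE)
}
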