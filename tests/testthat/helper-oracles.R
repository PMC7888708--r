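# Construct a vector with exactly the requested mean (1) and CV (fraction).
exactCVVector <- function(n, cv) {
  z <- scale(seq_len(n))[, 1]
  1 + cv * z / stats::sd(z)
}

# Exact distribution of nuclei counts after `cycles` rounds of independent
# per-nucleus division with probability q, starting from one nucleus.
# Dynamic-programming enumeration over the branching process.
branchingDist <- function(q, cycles) {
  dist <- c(`1` = 1)
  for (cyc in seq_len(cycles)) {
    new <- numeric(2 * max(as.integer(names(dist))))
    for (k in as.integer(names(dist))) {
      pk <- dist[[as.character(k)]]
      for (j in 0:k) {
        new[k + j] <- new[k + j] + pk * stats::dbinom(j, k, q)
      }
    }
    keep <- which(new > 0)
    dist <- stats::setNames(new[keep], keep)
  }
  dist
}

# Small deterministic record table for binning / regression tests.
makeRecords <- function(bl, d, strain = "s") {
  data.frame(cell_id = paste0("c", seq_along(bl)),
             lineage_id = seq_along(bl), strain = strain,
             generation = 1L, birth_time_min = 0,
             birth_length_um = bl, division_length_um = d,
             extension_um = d - bl,
             cycle_time_min = 100, stringsAsFactors = FALSE)
}
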