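# Shared fixtures: small simulated plates and hand-built traces.

logisticTrace <- function(F0 = 1, drift = 0, A = 10, k = 1.2, c50 = 26,
                          nCycles = 40, noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cyc <- seq_len(nCycles)
  y <- F0 + drift * cyc + A / (1 + exp(-k * (cyc - c50)))
  if (noiseSd > 0) y <- y + rnorm(nCycles, 0, noiseSd)
  y
}

miniPlate <- function(nWells = 300, lambda = 30, seed = 1,
                      channels = "FAM", regions = "protein", ...) {
  simulatePlate(plateSimParams(nWells = nWells, targetCopies = lambda,
                               channels = channels, regions = regions, ...),
                seed = seed)
}

# Direct multinomial occupancy draw (the generator's stated placement rule),
# used where only partition counts matter and full traces would be waste.
occupancyDraw <- function(lambda, N) {
  counts <- tabulate(sample.int(N, round(lambda), replace = TRUE), nbins = N)
  sum(counts >= 1L)
}
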