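`%||%` <- function(a, b) if (is.null(a)) b else a

## The five quantized desired-output levels: maximal decrease, moderate
## decrease, no change, moderate increase, maximal increase.
.ms_levels <- c(0.30, 0.40, 0.50, 0.60, 0.70)

## Numeric tolerance for grid / level comparisons.
.ms_eps <- 1e-9

clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)

## Clip a magnitude matrix to its per-class bounds and zero pruned cells.
clip_magnitudes <- function(mag, class, prune_mask, bounds) {
  for (cl in names(bounds)) {
    sel <- class == cl
    mag[sel] <- clip(mag[sel], bounds[[cl]]["lower"], bounds[[cl]]["upper"])
  }
  mag[prune_mask] <- 0
  mag
}
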