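#' Screen a chronic drug/hormone combination
#'
#' Enumerates and evaluates the TSC-strength configurations of each
#' supplied network under chronic administration of the combination
#' (its input units held at 1), keeps the adapted configurations, pools
#' them by concatenation across networks, and averages their monoamine
#' levels component-wise into a monoamine vector [5HT NE DA].  Pooling
#' before averaging (rather than a mean of per-network means) weights
#' each adapted configuration equally.
#'
#' @param models List of trained `ms_network`s (the representative
#'   networks; the reference protocol uses three).
#' @param combo Character vector of 1-3 input units forming the
#'   combination, or a list with `name` and `inputs`.
#' @param tscs An `ms_tsc_spec`.
#' @param max_degree Maximum total adjustments per configuration.
#' @param criteria An [ms_criteria()].
#' @param regions Passed to [evaluate_configurations()].
#' @return Object of class `ms_screen`: list with `name`, `vector`
#'   (named means over the monoamines present), `n_adapted` (per
#'   network), `records` (pooled adapted records), and `empty` (TRUE
#'   when no configuration of any network adapted -- an explicit flag,
#'   never a silent zero).
#' @export
screen_combination <- function(models, combo, tscs, max_degree = 6,
                               criteria = ms_criteria(), regions = NULL) {
  if (inherits(models, "ms_network")) models <- list(models)
  stopifnot(length(models) >= 1)
  if (is.list(combo) && !is.null(combo$inputs)) {
    name <- combo$name %||% paste(combo$inputs, collapse = "+")
    inputs <- combo$inputs
  } else {
    inputs <- as.character(combo)
    name <- paste(inputs, collapse = "+")
  }
  if (!length(inputs)) stop("combination needs at least one input",
                            call. = FALSE)
  per <- lapply(models, function(m) {
    cfg <- enumerate_configurations(m, tscs, max_degree = max_degree)
    rec <- evaluate_configurations(m, cfg, inputs, criteria,
                                   regions = regions)
    rec[rec$adapted, , drop = FALSE]
  })
  n_adapted <- vapply(per, nrow, 0L)
  pooled <- do.call(rbind, lapply(per, as.data.frame))
  mono <- intersect(c("fht", "ne", "da"), colnames(pooled))
  out <- list(name = name, inputs = inputs,
              vector = if (nrow(pooled)) colMeans(pooled[, mono, drop = FALSE])
                       else stats::setNames(rep(NA_real_, length(mono)), mono),
              n_adapted = n_adapted,
              records = pooled,
              empty = nrow(pooled) == 0L)
  class(out) <- "ms_screen"
  out
}

#' @export
print.ms_screen <- function(x, ...) {
  cat("<ms_screen> ", x$name, ": ",
      if (x$empty) "no adapted configurations"
      else paste(names(x$vector), round(x$vector, 3), collapse = ", "),
      " (n = ", paste(x$n_adapted, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Reference monoamine vectors
#'
#' The three landmarks against which adapted monoamine vectors
#' [5HT NE DA] are ranked: baseline [0.50 0.50 0.50], therapeutic
#' [0.70 0.70 0.70], and excess [0.80 0.80 0.80] (levels high enough to
#' suggest side effects).
#'
#' @param baseline,therapeutic,excess Per-monoamine reference levels.
#' @return Named list of three numeric 3-vectors.
#' @export
reference_vectors <- function(baseline = 0.50, therapeutic = 0.70,
                              excess = 0.80) {
  mk <- function(v) stats::setNames(rep(v, 3), c("fht", "ne", "da"))
  list(baseline = mk(baseline), therapeutic = mk(therapeutic),
       excess = mk(excess))
}

#' Rank screened combinations against the reference vectors
#'
#' Combinations whose mean monoamine vector has any component above the
#' excess level form the "excess" block, ordered by Euclidean distance
#' from the excess reference vector; all remaining combinations, plus a
#' baseline reference row, form the "therapeutic" block, ordered by
#' distance from the therapeutic reference vector.  The excess block is
#' listed first; ties break lexicographically by name.
#'
#' @param screens List of `ms_screen` results (or a data frame with
#'   columns `name`, `fht`, `ne`, `da`).
#' @param refs Reference vectors from [reference_vectors()].
#' @param baseline_row Include the baseline reference vector as a row?
#' @return Data frame (one row per combination, ordered for display):
#'   `name`, the monoamine means, `block`, `distance`.
#' @export
rank_combinations <- function(screens, refs = reference_vectors(),
                              baseline_row = TRUE) {
  if (inherits(screens, "data.frame")) {
    df <- screens
  } else {
    if (inherits(screens, "ms_screen")) screens <- list(screens)
    keep <- !vapply(screens, `[[`, TRUE, "empty")
    df <- do.call(rbind, lapply(screens[keep], function(s)
      data.frame(name = s$name, t(s$vector), stringsAsFactors = FALSE)))
  }
  if (is.null(df) || !nrow(df)) stop("no non-empty vectors to rank",
                                     call. = FALSE)
  mono <- intersect(c("fht", "ne", "da"), colnames(df))
  if (baseline_row) {
    base <- data.frame(name = "Baseline reference",
                       as.list(refs$baseline[mono]))
    df <- rbind(df[, c("name", mono)], base)
  }
  m <- as.matrix(df[, mono, drop = FALSE])
  excess <- apply(m, 1, function(r) any(r > refs$excess[mono] + .ms_eps))
  dist_to <- function(ref) sqrt(rowSums(sweep(m, 2, ref[mono])^2))
  df$block <- ifelse(excess, "excess", "therapeutic")
  df$distance <- ifelse(excess, dist_to(refs$excess),
                        dist_to(refs$therapeutic))
  ord <- order(factor(df$block, levels = c("excess", "therapeutic")),
               df$distance, df$name)
  out <- df[ord, c("name", mono, "block", "distance")]
  rownames(out) <- NULL
  out
}
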