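#' Declare adjustable transmitter-system components
#'
#' An adjustable TSC is a protein (receptor or transporter) whose
#' efficacy is one connection weight in the network; neuroadaptation is
#' modeled as discrete +/- 0.50 adjustments of these magnitudes within
#' [0, 10].  The full-scale model has exactly ten ([fullscale_tscs()]);
#' the demo carries three.
#'
#' @param from Sending unit per TSC (the protein unit).
#' @param to Receiving unit per TSC (the regulated unit).
#' @param label Short unique label per TSC, receiving unit first (e.g.
#'   `DR_5HT1AR`).
#' @return An object of class `ms_tsc_spec` (data frame with columns
#'   `from`, `to`, `label`).
#' @export
ms_tsc_spec <- function(from, to, label) {
  stopifnot(length(from) == length(to), length(label) == length(from))
  if (anyDuplicated(label))
    stop("TSC labels must be unique", call. = FALSE)
  structure(data.frame(from = as.character(from), to = as.character(to),
                       label = as.character(label), stringsAsFactors = FALSE),
            class = c("ms_tsc_spec", "data.frame"))
}

## Resolve TSC entries to weight-matrix cells; errors on unknown units
## or pruned connections.
resolve_tscs <- function(network, tscs) {
  stopifnot(inherits(tscs, "ms_tsc_spec"))
  rows <- match(tscs$to, rownames(network$magnitude))
  cols <- match(tscs$from, colnames(network$magnitude))
  bad <- which(is.na(rows) | is.na(cols))
  if (length(bad))
    stop("TSC(s) not resolvable in this network: ",
         paste(tscs$label[bad], collapse = ", "), call. = FALSE)
  pruned <- which(network$prune_mask[cbind(rows, cols)])
  if (length(pruned))
    stop("TSC connection(s) are pruned: ",
         paste(tscs$label[pruned], collapse = ", "), call. = FALSE)
  list(rows = rows, cols = cols,
       base = network$magnitude[cbind(rows, cols)], labels = tscs$label)
}

## All integer offset vectors of dimension n with sum(|x|) <= degree.
## Memoized on (n, degree); dimensions are interchangeable.
.offset_lattice <- local({
  memo <- new.env(parent = emptyenv())
  function(n, degree) {
    key <- paste(n, degree)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 0L) {
      matrix(integer(0), nrow = 1, ncol = 0)
    } else {
      blocks <- lapply((-degree):degree, function(v) {
        rest <- .offset_lattice(n - 1L, degree - abs(v))
        cbind(rep.int(as.integer(v), nrow(rest)), rest)
      })
      do.call(rbind, blocks)
    }
    memo[[key]] <- out
    out
  }
})

#' Enumerate TSC-strength configurations
#'
#' The set of all joint adjustments of the adjustable TSC magnitudes
#' reachable from the trained (normative) values by single +/- increment
#' steps: every integer offset vector with total adjustment count
#' (L1 norm) at most `max_degree` whose resulting magnitudes all stay
#' within [0, 10].  Any such vector is reachable by a move sequence that
#' adjusts each TSC monotonically, so the set equals the breadth-first
#' closure over single-step moves.
#'
#' @param network A trained `ms_network`.
#' @param tscs An `ms_tsc_spec`.
#' @param max_degree Maximum total number of adjustments (default 6).
#' @param increment Magnitude step per adjustment (default 0.50).
#' @return Object of class `ms_configurations`: list with `offsets`
#'   (integer matrix, configurations x TSCs, origin first), `magnitudes`
#'   (resulting magnitudes), `degree` (per-configuration L1 norm),
#'   `base`, `increment`, and resolved TSC indices.
#' @examples
#' demo <- build_demo_model()
#' net <- initialize_network(demo$structure, seed = 1)
#' nrow(enumerate_configurations(net, demo$tscs, max_degree = 2)$offsets)
#' @export
enumerate_configurations <- function(network, tscs, max_degree = 6,
                                     increment = 0.5) {
  if (max_degree < 0) stop("`max_degree` must be >= 0", call. = FALSE)
  rt <- resolve_tscs(network, tscs)
  n <- length(rt$base)
  off <- .offset_lattice(n, as.integer(max_degree))
  mags <- sweep(off * increment, 2L, rt$base, `+`)
  ok <- rowSums(mags < -.ms_eps | mags > 10 + .ms_eps) == 0L
  off <- off[ok, , drop = FALSE]
  mags <- clip(mags[ok, , drop = FALSE], 0, 10)
  deg <- rowSums(abs(off))
  ord <- order(deg, apply(off, 1, paste, collapse = ","))
  colnames(off) <- colnames(mags) <- rt$labels
  structure(list(offsets = off[ord, , drop = FALSE],
                 magnitudes = mags[ord, , drop = FALSE],
                 degree = deg[ord], base = rt$base,
                 increment = increment, rows = rt$rows, cols = rt$cols,
                 labels = rt$labels, max_degree = max_degree),
            class = "ms_configurations")
}

#' @export
print.ms_configurations <- function(x, ...) {
  cat("<ms_configurations> ", nrow(x$offsets), " configurations of ",
      length(x$base), " TSCs, degree <= ", x$max_degree,
      " (increment ", x$increment, ")\n", sep = "")
  invisible(x)
}

#' Therapeutic criteria
#'
#' Thresholds defining a therapeutic monoamine/hormone profile: the
#' serotonin level must reach the therapeutic floor (0.70, double the
#' acute-SSRI increase over the 0.50 baseline) and cortisol must not
#' exceed the therapeutic ceiling (0.70, a decrease from the acute
#' level).  Floors for NE and DA (also 0.70) are available but only
#' applied when `require_ne_da = TRUE`.  `excess_level` (0.80) marks
#' monoamine levels high enough to suggest side effects.
#'
#' @param fht_floor,cort_ceiling,ne_floor,da_floor,excess_level
#'   Thresholds in (0, 1).
#' @param require_ne_da Apply the NE/DA floors in
#'   [classify_therapeutic()]?
#' @return An object of class `ms_criteria`.
#' @export
ms_criteria <- function(fht_floor = 0.70, cort_ceiling = 0.70,
                        ne_floor = 0.70, da_floor = 0.70,
                        excess_level = 0.80, require_ne_da = FALSE) {
  vals <- c(fht_floor, cort_ceiling, ne_floor, da_floor, excess_level)
  if (any(vals <= 0 | vals >= 1))
    stop("criteria thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(fht_floor = fht_floor, cort_ceiling = cort_ceiling,
                 ne_floor = ne_floor, da_floor = da_floor,
                 excess_level = excess_level, require_ne_da = require_ne_da),
            class = "ms_criteria")
}

## Units carrying the monoamine/hormone levels, restricted to those
## present in the network.
.level_units <- function(network) {
  all_lv <- c(fht = "5HT", ne = "NE", da = "DA", cort = "CORT")
  all_lv[all_lv %in% network$units$name]
}

## Region units whose deviation from baseline defines adaptation error.
.adapt_regions <- function(network, regions = NULL) {
  regions <- regions %||% intersect(c("DR", "LC", "VTA", "PVN"),
                                    network$units$name)
  missing_r <- setdiff(regions, network$units$name)
  if (length(missing_r))
    stop("region unit(s) not in network: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  regions
}

#' Evaluate TSC-strength configurations under a chronic input
#'
#' Chronic administration is simulated by holding the drug/hormone input
#' units at 1 while the TSC magnitudes take the configured values.  For
#' each configuration the network is settled and scored: the adaptation
#' error is the sum over the key region units of the absolute deviation
#' of their activity from the no-drug baseline; a configuration is
#' "adapted" when that error is strictly below the initial error (the
#' error of the unadjusted network under the same chronic input), and
#' "therapeutic" when its monoamine/hormone levels satisfy the criteria.
#'
#' @param network A trained `ms_network`.
#' @param configs An `ms_configurations` from
#'   [enumerate_configurations()] (or a bare list with `magnitudes`,
#'   `rows`, `cols`).
#' @param chronic_inputs Character vector of input units held at 1, or a
#'   named numeric vector of input levels.
#' @param criteria An [ms_criteria()].
#' @param regions Region units defining the adaptation error; defaults
#'   to those of DR, LC, VTA, PVN present in the network.
#' @param n_iterations Settle iterations.
#' @return Object of class `ms_adaptation`: a data frame of records (one
#'   row per configuration: offsets, degree, adaptation error, adapted
#'   and therapeutic flags, and the monoamine/hormone levels) with the
#'   chronic input, `initial_error`, and baseline activities attached as
#'   attributes.
#' @export
evaluate_configurations <- function(network, configs, chronic_inputs,
                                    criteria = ms_criteria(),
                                    regions = NULL, n_iterations = 100) {
  regions <- .adapt_regions(network, regions)
  inputs <- .chronic_vector(network, chronic_inputs)
  base_state <- baseline_activities(network, n_iterations = n_iterations)
  base_regions <- base_state$activities[regions]
  A <- settle_batch(network, inputs, configs$rows, configs$cols,
                    t(configs$magnitudes), n_iterations = n_iterations)
  adapt_err <- colSums(abs(A[regions, , drop = FALSE] - base_regions))
  init <- settle(network, inputs, n_iterations = n_iterations)
  initial_error <- sum(abs(init$activities[regions] - base_regions))
  lv <- .level_units(network)
  levels_mat <- t(A[lv, , drop = FALSE])
  colnames(levels_mat) <- names(lv)
  rec <- data.frame(configuration = seq_len(nrow(configs$offsets)),
                    degree = rowSums(abs(configs$offsets)),
                    adaptation_error = adapt_err,
                    adapted = adapt_err < initial_error,
                    levels_mat,
                    stringsAsFactors = FALSE)
  rec$therapeutic <- classify_therapeutic(rec, criteria)
  structure(rec, class = c("ms_adaptation", "data.frame"),
            offsets = configs$offsets, chronic = inputs,
            initial_error = initial_error, regions = regions,
            baseline = base_state$activities, criteria = criteria)
}

#' @rdname evaluate_configurations
#' @param offsets A single integer offset vector over the TSCs (e.g. one
#'   row of an enumeration), for evaluating one configuration.
#' @param tscs The `ms_tsc_spec` the offsets refer to.
#' @export
evaluate_configuration <- function(network, tscs, offsets, chronic_inputs,
                                   criteria = ms_criteria(), regions = NULL,
                                   increment = 0.5, n_iterations = 100) {
  rt <- resolve_tscs(network, tscs)
  stopifnot(length(offsets) == length(rt$base))
  mags <- rt$base + increment * offsets
  if (any(mags < -.ms_eps | mags > 10 + .ms_eps))
    stop("offsets drive a TSC magnitude outside [0, 10]", call. = FALSE)
  cfg <- list(offsets = matrix(as.integer(offsets), nrow = 1,
                               dimnames = list(NULL, rt$labels)),
              magnitudes = matrix(clip(mags, 0, 10), nrow = 1),
              rows = rt$rows, cols = rt$cols)
  evaluate_configurations(network, cfg, chronic_inputs, criteria,
                          regions = regions, n_iterations = n_iterations)
}

.chronic_vector <- function(network, chronic_inputs) {
  if (is.character(chronic_inputs)) {
    inputs <- rep(1, length(chronic_inputs))
    names(inputs) <- chronic_inputs
  } else inputs <- chronic_inputs
  inputs
}

#' Classify the therapeutic status of records
#'
#' A level profile is therapeutic when serotonin is at or above the
#' therapeutic floor and cortisol at or below the therapeutic ceiling
#' (both thresholds inclusive); when `require_ne_da` is set in the
#' criteria, NE and DA must also reach their floors.
#'
#' @param records Data frame with columns `fht` and `cort` (and `ne`,
#'   `da` when required): the levels of 5HT, CORT, NE, DA.
#' @param criteria An [ms_criteria()].
#' @return Logical vector.
#' @export
classify_therapeutic <- function(records, criteria = ms_criteria()) {
  ok <- records$fht >= criteria$fht_floor - .ms_eps &
    records$cort <= criteria$cort_ceiling + .ms_eps
  if (isTRUE(criteria$require_ne_da)) {
    ok <- ok & records$ne >= criteria$ne_floor - .ms_eps &
      records$da >= criteria$da_floor - .ms_eps
  }
  ok
}

#' Pool adapted records into a histogram
#'
#' Bins one monoamine/hormone level over records pooled (concatenated)
#' across one or more networks.  Bins are left-closed, width 0.03 by
#' default, anchored at 0, so counts always sum to the number of records
#' binned.
#'
#' @param records An `ms_adaptation` data frame, a list of them (one per
#'   network), or a bare numeric vector of levels.
#' @param quantity One of `"fht"`, `"ne"`, `"da"`, `"cort"` (ignored for
#'   a bare numeric vector).
#' @param bin_width Positive bin width (default 0.03).
#' @return Data frame with `bin_left`, `bin_right`, `count`.
#' @export
pool_histogram <- function(records, quantity = c("fht", "ne", "da", "cort"),
                           bin_width = 0.03) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (is.numeric(records)) {
    values <- records
  } else {
    quantity <- match.arg(quantity)
    if (inherits(records, "data.frame")) records <- list(records)
    values <- unlist(lapply(records, function(r) r[[quantity]]),
                     use.names = FALSE)
  }
  nbin <- max(ceiling(1 / bin_width), if (length(values))
    floor(max(values) / bin_width) + 1 else 0)
  idx <- floor(values / bin_width + .ms_eps)
  counts <- tabulate(idx + 1L, nbins = nbin)
  data.frame(bin_left = (seq_len(nbin) - 1) * bin_width,
             bin_right = seq_len(nbin) * bin_width,
             count = counts)
}

#' Plot a pooled level histogram
#'
#' Bar rendering of [pool_histogram()] with reference lines at the
#' baseline level (0.50, blue), the mean of the pooled records (green),
#' and the therapeutic threshold (0.70, magenta).
#'
#' @inheritParams pool_histogram
#' @param criteria An [ms_criteria()] (for the threshold line).
#' @param ... Passed to [graphics::barplot()].
#' @return The histogram data frame, invisibly.
#' @export
plot_pool_histogram <- function(records, quantity = c("fht", "ne", "da", "cort"),
                                bin_width = 0.03, criteria = ms_criteria(),
                                ...) {
  quantity <- match.arg(quantity)
  h <- pool_histogram(records, quantity, bin_width)
  if (inherits(records, "data.frame")) records <- list(records)
  values <- unlist(lapply(records, function(r) r[[quantity]]))
  mids <- graphics::barplot(h$count, names.arg = formatC(h$bin_left, 2,
                                                         format = "f"),
                            xlab = quantity, ylab = "configurations", ...)
  at <- function(v) stats::approx(h$bin_left + bin_width / 2, mids, v,
                                  rule = 2)$y
  graphics::abline(v = at(0.50), col = "blue", lty = 3)
  if (length(values)) graphics::abline(v = at(mean(values)), col = "green3")
  thr <- if (quantity == "cort") criteria$cort_ceiling else criteria$fht_floor
  graphics::abline(v = at(thr), col = "magenta")
  invisible(h)
}
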