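#' Training configuration
#'
#' Collects the knobs of the recurrent back-propagation schedule: number
#' of training cycles (one input/desired-output pattern presented per
#' cycle, drawn uniformly at random), the number of settle iterations
#' defining the steady state (100), and per-class learning rates.  The
#' canonical and structure connections learn at rate 1; non-structure
#' connections are disadvantaged at rate 0.10 because they are not known
#' to be involved in the modeled biology.
#'
#' @param cycles Number of training cycles.  The full-scale schedule is
#'   1e6; the demo model trains well at the default 2e4.
#' @param settle_iterations Synchronous update count per steady state.
#' @param learning_rate Named list of per-class rates.
#' @param seed Integer seed controlling pattern order (and nothing else;
#'   the initial weights are fixed by [initialize_network()]).
#' @param checkpoints Number of evenly spaced error-history checkpoints.
#' @return An object of class `ms_training_config`.
#' @export
ms_training_config <- function(cycles = 2e4, settle_iterations = 100,
                               learning_rate = list(canonical = 1,
                                                    structure = 1,
                                                    non_structure = 0.10),
                               seed = 1L, checkpoints = 100) {
  cycles <- as.integer(cycles)
  if (is.na(cycles) || cycles < 1) stop("`cycles` must be >= 1", call. = FALSE)
  if (any(unlist(learning_rate) < 0))
    stop("learning rates must be non-negative", call. = FALSE)
  stopifnot(setequal(names(learning_rate), names(ms_bounds())))
  structure(list(cycles = cycles, settle_iterations = settle_iterations,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 checkpoints = checkpoints),
            class = "ms_training_config")
}

#' Initialize a network from a structure matrix
#'
#' Creates the trainable object: fixed connection signs plus bounded
#' non-negative magnitudes.  Canonical and structure connections take
#' their signs from the valence of the structure matrix; non-structure
#' signs are drawn once (+1 or -1 equiprobably) and stay fixed through
#' training.  Canonical magnitudes start uniformly in [1, 2] (they must
#' exert an influence, floor 1); all other magnitudes start uniformly in
#' [0, 1).
#'
#' @param structure An `ms_structure`.
#' @param seed Integer seed; the same seed reproduces the network
#'   exactly.
#' @return An object of class `ms_network`.
#' @export
initialize_network <- function(structure, seed = 1L) {
  units <- attr(structure, "units")
  mat <- unclass(structure)
  cls <- matrix(names(ms_bounds())[3L - abs(mat)], nrow(mat),
                dimnames = dimnames(mat))
  net <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sgn <- matrix(sample(c(-1, 1), length(mat), replace = TRUE), nrow(mat),
                  dimnames = dimnames(mat))
    sgn[mat != 0L] <- sign(mat[mat != 0L])
    mag <- matrix(stats::runif(length(mat)), nrow(mat),
                  dimnames = dimnames(mat))
    mag[cls == "canonical"] <- 1 + stats::runif(sum(cls == "canonical"))
    list(sign = sgn, magnitude = mag)
  })
  out <- list(units = units, sign = net$sign, magnitude = net$magnitude,
              class = cls,
              prune_mask = matrix(FALSE, nrow(mat), ncol(mat),
                                  dimnames = dimnames(mat)),
              bounds = ms_bounds(), seed = as.integer(seed), history = NULL)
  class(out) <- "ms_network"
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Steady-state error gradient (recurrent back-propagation)
#'
#' Gradient of the squared-error functional
#' \eqn{E = \tfrac12 \sum_k (d_k - x_k)^2} over the targeted outputs of
#' one pattern, evaluated at the settled state.  The adjoint
#' (error-propagation) system \eqn{y = f'(net) (e + W^T y)} is relaxed
#' with the same synchronous schedule as the forward settle; its fixed
#' point gives \eqn{\partial E / \partial w_{ij} = -y_i x_j}, which is
#' mapped onto the trainable magnitudes through each connection's fixed
#' sign.  Pruned connections get gradient 0.
#'
#' @param network An `ms_network`.
#' @param pattern List with elements `inputs` (named 0/1 vector) and
#'   `targets` (named vector of desired levels over output units).
#' @param n_iterations Settle/adjoint iteration count (default 100).
#' @return List with `gradient` (matrix over magnitudes, dE/dm),
#'   `state` (the settled `ms_state`), `error` (the pattern SSE), and
#'   `residual` (final adjoint update size, a convergence diagnostic).
#' @export
steady_state_gradient <- function(network, pattern, n_iterations = 100) {
  if (!length(pattern$targets) || all(is.na(pattern$targets)))
    stop("pattern has no targets", call. = FALSE)
  st <- settle(network, pattern$inputs, n_iterations = n_iterations)
  act <- st$activities
  recv <- rownames(network$magnitude)
  x <- act[recv]
  tg <- pattern$targets[!is.na(pattern$targets)]
  unknown <- setdiff(names(tg), recv)
  if (length(unknown))
    stop("targets name unknown output unit(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  e <- numeric(length(recv)); names(e) <- recv
  e[names(tg)] <- tg - x[names(tg)]
  w <- effective_weights(network)
  wr <- w[, recv, drop = FALSE]          # recv -> recv sub-block
  fp <- x * (1 - x)                      # logistic derivative at the fixed point
  y <- numeric(length(recv))
  residual <- 0
  for (i in seq_len(n_iterations)) {
    ynew <- fp * (e + drop(crossprod(wr, y)))
    if (i == n_iterations) residual <- max(abs(ynew - y))
    y <- ynew
  }
  grad <- -outer(y, act) * network$sign  # dE/dm = sign * dE/dw
  grad[network$prune_mask] <- 0
  dimnames(grad) <- dimnames(network$magnitude)
  list(gradient = grad, state = st, error = sum(e^2) / 2, residual = residual)
}

pattern_at <- function(table, i) {
  list(inputs = table$inputs[i, ], targets = table$targets[i, ])
}

#' Train a network to its truth table
#'
#' Stochastic steady-state gradient descent: each cycle draws one
#' pattern uniformly at random, settles the network, relaxes the adjoint
#' system, and updates the connection magnitudes with per-class learning
#' rates, clipping to the per-class bounds ([1, 10] canonical, [0, 10]
#' otherwise).  Pruned connections stay at 0 throughout.
#'
#' @param network An `ms_network` from [initialize_network()].
#' @param table An `ms_truth_table`.
#' @param config An `ms_training_config`.
#' @return The trained `ms_network`, with `history` (data frame of
#'   checkpoint cycle and RMS error) and `final_error` attached.
#' @examples
#' demo <- build_demo_model()
#' net <- initialize_network(demo$structure, seed = 1)
#' \donttest{
#' net <- train_network(net, demo$truth_table, ms_training_config(seed = 1))
#' settle(net, c(SSRI = 1))$activities[["5HT"]]  # close to 0.60
#' }
#' @export
train_network <- function(network, table, config = ms_training_config()) {
  stopifnot(inherits(table, "ms_truth_table"))
  if (!nrow(table$inputs)) stop("truth table is empty", call. = FALSE)
  rates <- matrix(0, nrow(network$magnitude), ncol(network$magnitude))
  for (cl in names(config$learning_rate))
    rates[network$class == cl] <- config$learning_rate[[cl]]
  mag <- network$magnitude
  every <- max(1L, config$cycles %/% config$checkpoints)
  hist_cycle <- integer(0); hist_rms <- numeric(0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  order_draw <- sample.int(nrow(table$inputs), config$cycles, replace = TRUE)
  for (cycle in seq_len(config$cycles)) {
    network$magnitude <- mag
    g <- steady_state_gradient(network, pattern_at(table, order_draw[cycle]),
                               n_iterations = config$settle_iterations)
    if (!is.finite(g$error))
      stop("non-finite training error at cycle ", cycle, call. = FALSE)
    mag <- clip_magnitudes(mag - rates * g$gradient, network$class,
                           network$prune_mask, network$bounds)
    if (cycle %% every == 0 || cycle == config$cycles) {
      network$magnitude <- mag
      hist_cycle <- c(hist_cycle, cycle)
      hist_rms <- c(hist_rms,
                    evaluate_error(network, table,
                                   n_iterations = config$settle_iterations)$rms)
    }
  }
  network$magnitude <- mag
  network$history <- data.frame(cycle = hist_cycle, rms = hist_rms)
  network$final_error <- hist_rms[length(hist_rms)]
  network$train_seed <- config$seed
  network
}

#' Root-mean-square error over a truth table
#'
#' RMS of (desired - actual) over all (pattern, targeted output) pairs,
#' optionally restricted to a unit subset, plus the mean absolute error
#' per targeted output unit.
#'
#' @param network An `ms_network`.
#' @param table An `ms_truth_table`.
#' @param unit_subset Optional character vector of output units.
#' @param n_iterations Settle iterations per pattern.
#' @return List with `rms` and `mean_abs_error` (named per unit).
#' @export
evaluate_error <- function(network, table, unit_subset = NULL,
                           n_iterations = 100) {
  tg <- table$targets
  if (!is.null(unit_subset)) {
    missing_u <- setdiff(unit_subset, colnames(tg))
    if (length(missing_u))
      stop("unit_subset not in targets: ", paste(missing_u, collapse = ", "),
           call. = FALSE)
    tg <- tg[, unit_subset, drop = FALSE]
  }
  if (all(is.na(tg))) stop("no targets to evaluate", call. = FALSE)
  err <- matrix(NA_real_, nrow(tg), ncol(tg), dimnames = dimnames(tg))
  for (i in seq_len(nrow(tg))) {
    st <- settle(network, table$inputs[i, ], n_iterations = n_iterations)
    has <- !is.na(tg[i, ])
    err[i, has] <- tg[i, has] - st$activities[colnames(tg)[has]]
  }
  list(rms = sqrt(mean(err[!is.na(err)]^2)),
       mean_abs_error = colMeans(abs(err), na.rm = TRUE))
}
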