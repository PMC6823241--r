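#' msadapt: recurrent network models of the monoamine-stress system
#'
#' Core objects: a structure matrix declaring canonical (|entry| = 2),
#' structure (|entry| = 1) and non-structure (0) connections over named
#' units; a network holding fixed connection signs and trainable
#' non-negative magnitudes; and steady states obtained by iterating the
#' sigmoidal unit update.
#'
#' @keywords internal
#' @aliases msadapt-package
"_PACKAGE"

## Unit roles.  Input and bias units send but never receive; hidden and
## output units receive (they are the rows of the weight matrix); output
## units are the only ones eligible to carry desired-output targets.
.ms_roles <- c("input", "hidden", "output", "bias")

#' Logistic squashing function
#'
#' The activation function shared by every unit in the network: the
#' standard logistic \eqn{1 / (1 + e^{-net})}, which maps any finite net
#' input into the open interval (0, 1) and takes the value 0.50 at net
#' input 0 (the "spontaneous" activity of an unconnected unit).
#'
#' @param net Numeric vector of net inputs; must be finite.
#' @return Numeric vector of activations in (0, 1).
#' @examples
#' sigmoid(0)        # 0.5
#' sigmoid(log(3))   # 0.75
#' @export
sigmoid <- function(net) {
  if (!is.numeric(net) || anyNA(net) || any(!is.finite(net)))
    stop("`net` must be finite numeric", call. = FALSE)
  1 / (1 + exp(-net))
}

#' Construct a unit table
#'
#' @param name Character vector of unique unit names.
#' @param role Character vector over \code{c("input","hidden","output","bias")}.
#' @param annotation Optional free-text biological identity per unit.
#' @return A data frame with columns \code{name}, \code{role},
#'   \code{annotation}.
#' @export
ms_units <- function(name, role, annotation = NA_character_) {
  name <- as.character(name)
  role <- as.character(role)
  if (length(name) != length(role))
    stop("`name` and `role` must have equal length", call. = FALSE)
  if (anyDuplicated(name))
    stop("unit names must be unique; duplicated: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(role), .ms_roles)
  if (length(bad))
    stop("unknown unit role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  data.frame(name = name, role = role,
             annotation = rep_len(as.character(annotation), length(name)),
             stringsAsFactors = FALSE)
}

.receiving <- function(units) units$name[units$role %in% c("hidden", "output")]
.sending   <- function(units) units$name

#' Construct and validate a structure matrix
#'
#' The structure matrix declares the connection classes of the model:
#' entries of absolute value 2 mark canonical connections (the key
#' monoamine-stress interactions), absolute value 1 marks structure
#' connections (other empirically known interactions), and 0 marks
#' non-structure connections (free weights).  The sign of a non-zero
#' entry is the valence (excitatory or inhibitory) of the connection.
#' Rows are receiving units (hidden and output), columns sending units
#' (all units).
#'
#' @param mat Integer matrix with entries in \{-2,...,2\}, dimnames set to
#'   receiving and sending unit names.
#' @param units Unit table from [ms_units()]; rows/columns of `mat` must
#'   agree with the roles declared there.
#' @return An object of class `ms_structure`: the validated matrix with
#'   the unit table attached as attribute `units`.
#' @export
ms_structure <- function(mat, units) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  storage.mode(mat) <- "integer"
  bad <- which(is.na(mat) | abs(mat) > 2L, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "structure entries must be integers in -2..2; offending cell row '%s', column '%s'",
      rownames(mat)[bad[1, 1]] %||% bad[1, 1],
      colnames(mat)[bad[1, 2]] %||% bad[1, 2]), call. = FALSE)
  recv <- .receiving(units)
  send <- .sending(units)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("structure matrix needs row and column names", call. = FALSE)
  if (!identical(sort(rownames(mat)), sort(recv)))
    stop("structure rows must be exactly the hidden and output units",
         call. = FALSE)
  if (!identical(sort(colnames(mat)), sort(send)))
    stop("structure columns must be exactly the declared units", call. = FALSE)
  mat <- mat[recv, send, drop = FALSE]
  structure(mat, units = units, class = c("ms_structure", "matrix", "array"))
}

#' Count connection classes of a structure matrix
#'
#' @param structure An `ms_structure`.
#' @return Named integer vector with elements `canonical`, `structure`,
#'   `non_structure`, and `total`.
#' @export
class_counts <- function(structure) {
  a <- abs(unclass(structure))
  c(canonical = sum(a == 2L), structure = sum(a == 1L),
    non_structure = sum(a == 0L), total = length(a))
}

## Default per-class magnitude bounds: all magnitudes are capped at 10;
## canonical magnitudes have floor 1 so they always exert an influence.
ms_bounds <- function() {
  list(canonical     = c(lower = 1, upper = 10),
       structure     = c(lower = 0, upper = 10),
       non_structure = c(lower = 0, upper = 10))
}

#' @export
print.ms_network <- function(x, ...) {
  cc <- table(factor(x$class, levels = names(ms_bounds())))
  cat("<ms_network> ", nrow(x$units), " units (",
      sum(x$units$role == "input"), " input, ",
      sum(x$units$role == "hidden"), " hidden, ",
      sum(x$units$role == "output"), " output, ",
      sum(x$units$role == "bias"), " bias); weight matrix ",
      nrow(x$magnitude), " x ", ncol(x$magnitude), "\n", sep = "")
  cat("  connections: ", cc[["canonical"]], " canonical, ",
      cc[["structure"]], " structure, ", cc[["non_structure"]],
      " non-structure; ", sum(x$prune_mask), " pruned\n", sep = "")
  invisible(x)
}

#' Recover the structure matrix of a network
#'
#' Inverse of [initialize_network()] on the class/valence information:
#' canonical connections map back to sign x 2, structure connections to
#' sign x 1, non-structure connections to 0.
#'
#' @param network An `ms_network`.
#' @return An `ms_structure`.
#' @export
network_structure <- function(network) {
  code <- matrix(0L, nrow(network$class), ncol(network$class),
                 dimnames = dimnames(network$class))
  code[network$class == "canonical"] <- 2L
  code[network$class == "structure"] <- 1L
  ms_structure(code * network$sign, network$units)
}

## Effective signed weight matrix (pruned connections contribute 0).
effective_weights <- function(network) {
  w <- network$sign * network$magnitude
  w[network$prune_mask] <- 0
  w
}

#' Settle a network to its steady state
#'
#' Clamps the input units to the given values (unreferenced inputs
#' default to 0, the bias unit to 1) and synchronously updates every
#' hidden and output unit through the sigmoid of its net input for a
#' fixed number of iterations.  The steady-state response of the model
#' to an input pattern is the resulting activity vector.  Hidden and
#' output activities start from 0.50, the activity of an unconnected
#' unit.
#'
#' @param network An `ms_network` (see [initialize_network()]).
#' @param inputs Named numeric vector of input-unit values (typically 0/1
#'   drug or manipulation indicators); names must be declared input
#'   units.  Missing inputs are taken as 0.
#' @param n_iterations Number of synchronous updates (default 100).
#' @return An object of class `ms_state`: list with `activities` (named
#'   over all units), `max_delta` (largest absolute activity change at
#'   the final iteration, a convergence diagnostic), and `n_iterations`.
#' @examples
#' demo <- build_demo_model()
#' net <- initialize_network(demo$structure, seed = 1)
#' settle(net, c(SSRI = 1))$activities[["5HT"]]
#' @export
settle <- function(network, inputs = numeric(0), n_iterations = 100) {
  act <- .clamped_activities(network, inputs)
  recv <- rownames(network$magnitude)
  w <- effective_weights(network)
  prev <- act[recv]
  for (i in seq_len(n_iterations)) {
    new <- sigmoid(drop(w %*% act))
    act[recv] <- new
    if (i == n_iterations) max_delta <- max(abs(new - prev))
    prev <- new
  }
  if (n_iterations == 0) max_delta <- 0
  structure(list(activities = act, max_delta = max_delta,
                 n_iterations = n_iterations),
            class = "ms_state")
}

## Initial activity vector with inputs and bias clamped.
.clamped_activities <- function(network, inputs) {
  units <- network$units
  act <- rep(0.5, nrow(units))
  names(act) <- units$name
  act[units$role == "input"] <- 0
  act[units$role == "bias"] <- 1
  if (length(inputs)) {
    if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
      stop("`inputs` must be a named vector", call. = FALSE)
    unknown <- setdiff(names(inputs), units$name[units$role == "input"])
    if (length(unknown))
      stop("not declared input unit(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    act[names(inputs)] <- as.numeric(inputs)
  }
  act
}

#' @export
print.ms_state <- function(x, ...) {
  cat("<ms_state> ", length(x$activities), " units after ", x$n_iterations,
      " iterations; final max |delta| = ",
      formatC(x$max_delta, format = "e", digits = 2), "\n", sep = "")
  invisible(x)
}

#' Baseline (no-drug) steady state
#'
#' The baseline activity of a trained network is its settled activity
#' when all inputs are zero; it is the normative reference against which
#' neuroadaptation is measured.
#'
#' @inheritParams settle
#' @return An `ms_state`.
#' @export
baseline_activities <- function(network, n_iterations = 100) {
  settle(network, numeric(0), n_iterations = n_iterations)
}

## Batch settle: activity matrix over configurations that share a network
## but override the magnitudes of a few connections.  `rows`/`cols` index
## the overridden cells; `values` is a k x n matrix of magnitudes, one
## column per configuration.  Inputs are shared across configurations.
settle_batch <- function(network, inputs, rows, cols, values,
                         n_iterations = 100) {
  stopifnot(length(rows) == length(cols), nrow(values) == length(rows))
  nconf <- ncol(values)
  act0 <- .clamped_activities(network, inputs)
  recv <- rownames(network$magnitude)
  w0 <- effective_weights(network)
  sgn <- network$sign[cbind(rows, cols)]
  w0[cbind(rows, cols)] <- 0            # overridden cells applied per column
  sv <- values * sgn                    # signed override weights, k x n
  A <- matrix(act0, nrow = length(act0), ncol = nconf,
              dimnames = list(names(act0), NULL))
  for (i in seq_len(n_iterations)) {
    net <- w0 %*% A
    for (k in seq_along(rows))
      net[rows[k], ] <- net[rows[k], ] + sv[k, ] * A[cols[k], ]
    A[recv, ] <- 1 / (1 + exp(-net))
  }
  A
}
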