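#' Lesion sensitivity of non-structure weights
#'
#' The sensitivity of a connection is the change in table-wide RMS error
#' when that single connection's magnitude is set to 0 (a lesion) with
#' everything else fixed.  The signed change is recorded (a lesion can
#' lower the error); ranking and pruning use its absolute value.  Only
#' non-structure connections are candidates: canonical and structure
#' connections encode known biology and are never pruned.
#'
#' @param network A trained `ms_network`.
#' @param table An `ms_truth_table`.
#' @param n_iterations Settle iterations per pattern.
#' @return Data frame with one row per unpruned non-structure
#'   connection: `to`, `from`, `magnitude`, `delta_rms` (signed), and
#'   `sensitivity` (= |delta_rms|).
#' @export
weight_sensitivity <- function(network, table, n_iterations = 100) {
  cand <- which(network$class == "non_structure" & !network$prune_mask,
                arr.ind = TRUE)
  tg <- table$targets
  nles <- nrow(cand)
  ## one column per lesion plus a final no-lesion column, so the
  ## baseline shares the lesion columns' arithmetic exactly and a
  ## no-op lesion has sensitivity identically 0
  sq_sum <- numeric(nles + 1L)
  n_terms <- 0L
  for (i in seq_len(nrow(table$inputs))) {
    has <- !is.na(tg[i, ])
    if (!any(has)) next
    outs <- colnames(tg)[has]
    A <- settle_batch(network, table$inputs[i, ],
                      rows = cand[, 1], cols = cand[, 2],
                      values = .lesion_values(network, cand, nles),
                      n_iterations = n_iterations)
    err <- A[outs, , drop = FALSE] - tg[i, outs]
    sq_sum <- sq_sum + colSums(err^2)
    n_terms <- n_terms + length(outs)
  }
  rms <- sqrt(sq_sum / n_terms)
  delta <- rms[-(nles + 1L)] - rms[nles + 1L]
  data.frame(to = rownames(network$magnitude)[cand[, 1]],
             from = colnames(network$magnitude)[cand[, 2]],
             magnitude = network$magnitude[cand],
             delta_rms = delta, sensitivity = abs(delta),
             stringsAsFactors = FALSE)
}

## Override value matrix for lesioning: candidate k keeps its trained
## magnitude in every column except column k, where it is 0; the last
## column lesions nothing (the baseline).
.lesion_values <- function(network, cand, nles) {
  v <- matrix(network$magnitude[cand], nles, nles + 1L)
  v[cbind(seq_len(nles), seq_len(nles))] <- 0
  v
}

#' Choose the pruning cutoff that generalizes best
#'
#' Generalizability protocol: for each candidate cutoff (and each of
#' `n_seeds` random initializations) a network is trained on the
#' single-manipulation patterns only, pruned at the cutoff, retrained on
#' the singles, and scored by its RMS error on the held-out combination
#' patterns.  The cutoff minimizing the mean combination error is
#' returned.
#'
#' @param structure An `ms_structure`.
#' @param table An `ms_truth_table` that splits into non-empty singles
#'   and combinations.
#' @param candidate_cutoffs Numeric vector of cutoffs to compare;
#'   `NULL` (default) uses the deciles of the observed |sensitivity|
#'   distribution of the first trained seed.
#' @param n_seeds Number of training replicates per cutoff.
#' @param config Training schedule for each replicate.
#' @return List with `cutoff` (the winner, a member of the candidate
#'   set) and `table` (mean combination RMS per candidate).
#' @export
select_cutoff <- function(structure, table, candidate_cutoffs = NULL,
                          n_seeds = 2, config = ms_training_config()) {
  sp <- split_patterns(table)
  if (is.null(sp$combinations))
    stop("cutoff selection needs combination patterns to test on",
         call. = FALSE)
  if (!is.null(candidate_cutoffs) && !length(candidate_cutoffs))
    stop("`candidate_cutoffs` must be non-empty", call. = FALSE)
  trained <- lapply(seq_len(n_seeds), function(s) {
    cfg <- config; cfg$seed <- config$seed + s - 1L
    train_network(initialize_network(structure, seed = cfg$seed),
                  sp$singles, cfg)
  })
  sens <- lapply(trained, weight_sensitivity, table = sp$singles,
                 n_iterations = config$settle_iterations)
  if (is.null(candidate_cutoffs))
    candidate_cutoffs <- unique(stats::quantile(sens[[1]]$sensitivity,
                                                probs = seq(0.1, 0.9, 0.1),
                                                names = FALSE))
  score <- vapply(candidate_cutoffs, function(cut) {
    mean(vapply(seq_len(n_seeds), function(s) {
      cfg <- config; cfg$seed <- config$seed + s - 1L
      pruned <- apply_prune(trained[[s]], sens[[s]], cut)
      retrained <- train_network(pruned, sp$singles, cfg)
      evaluate_error(retrained, sp$combinations,
                     n_iterations = config$settle_iterations)$rms
    }, 0))
  }, 0)
  list(cutoff = candidate_cutoffs[which.min(score)],
       table = data.frame(cutoff = candidate_cutoffs,
                          mean_combination_rms = score))
}

## Set the prune mask for non-structure weights with |sensitivity|
## strictly below the cutoff (ties at the cutoff are kept).
apply_prune <- function(network, sensitivity, cutoff) {
  kill <- sensitivity[sensitivity$sensitivity < cutoff, c("to", "from")]
  if (nrow(kill)) {
    idx <- cbind(match(kill$to, rownames(network$prune_mask)),
                 match(kill$from, colnames(network$prune_mask)))
    network$prune_mask[idx] <- TRUE
    network$magnitude[idx] <- 0
  }
  network
}

#' Prune a trained network and retrain it
#'
#' Computes lesion sensitivities on the full truth table, prunes the
#' non-structure connections with |sensitivity| below the cutoff
#' (freezing them at magnitude 0), and retrains the remaining weights on
#' the full table.  Canonical and structure connections are never
#' pruned, and the mask is monotone: pruned connections stay pruned.
#'
#' @param network A trained `ms_network`.
#' @param table An `ms_truth_table`.
#' @param cutoff Sensitivity cutoff (e.g. from [select_cutoff()]).
#' @param config Retraining schedule.
#' @return List with `network` (the pruned, retrained `ms_network`) and
#'   `report` (class `ms_pruning_report`: sensitivities, cutoff, counts,
#'   pre/post errors).
#' @export
prune_and_retrain <- function(network, table, cutoff,
                              config = ms_training_config()) {
  sens <- weight_sensitivity(network, table,
                             n_iterations = config$settle_iterations)
  pre_rms <- evaluate_error(network, table,
                            n_iterations = config$settle_iterations)$rms
  pruned <- apply_prune(network, sens, cutoff)
  n_pruned <- sum(pruned$prune_mask)
  retrained <- train_network(pruned, table, config)
  post_rms <- evaluate_error(retrained, table,
                             n_iterations = config$settle_iterations)$rms
  report <- structure(
    list(sensitivity = sens, cutoff = cutoff, n_pruned = n_pruned,
         fraction_pruned = n_pruned / sum(network$class == "non_structure"),
         pre_rms = pre_rms, post_rms = post_rms),
    class = "ms_pruning_report")
  list(network = retrained, report = report)
}

#' @export
print.ms_pruning_report <- function(x, ...) {
  cat("<ms_pruning_report> cutoff ", format(x$cutoff, digits = 4), ": ",
      x$n_pruned, " non-structure connections pruned (",
      round(100 * x$fraction_pruned, 1), "%); RMS ",
      format(x$pre_rms, digits = 3), " -> ", format(x$post_rms, digits = 3),
      "\n", sep = "")
  invisible(x)
}
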