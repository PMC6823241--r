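#' Build the TSC-adjustment transition system
#'
#' The Kripke-style structure over which leads-to propositions are
#' checked: states are the TSC-strength configurations reachable from
#' the trained (origin) configuration within the move budget, moves are
#' single +/- increment adjustments of one TSC respecting the [0, 10]
#' magnitude bounds, and each state is labeled by settling the network
#' at that configuration under the declared chronic input.  Built-in
#' predicates: `fht_high` (5HT at or above the therapeutic floor),
#' `cort_low` (CORT at or below the therapeutic ceiling), and per TSC
#' `<label>_sens_gt_3` / `<label>_desens_gt_3` (net offset at least +3
#' / at most -3 steps).  Path semantics are finite-trace with an
#' explicit move budget: revisiting states consumes moves, and a
#' maximal trajectory either exhausts the budget or reaches a state
#' with no legal move.
#'
#' @param network A trained `ms_network`.
#' @param tscs An `ms_tsc_spec`.
#' @param chronic_inputs Input units held at 1 while labels are
#'   evaluated (the default experiments use chronic SSRI).
#' @param budget Maximum total moves (default 6).
#' @param criteria An [ms_criteria()] supplying the level thresholds.
#' @param increment Magnitude step per move.
#' @return Object of class `ms_transition_system`: states (offset
#'   matrix), labels (logical matrix states x predicates), the key
#'   lookup, budget, and TSC bookkeeping.
#' @export
build_transition_system <- function(network, tscs, chronic_inputs,
                                    budget = 6, criteria = ms_criteria(),
                                    increment = 0.5) {
  if (budget < 0) stop("`budget` must be >= 0", call. = FALSE)
  cfg <- enumerate_configurations(network, tscs, max_degree = budget,
                                  increment = increment)
  rec <- evaluate_configurations(network, cfg, chronic_inputs, criteria)
  n <- nrow(cfg$offsets)
  labels <- cbind(fht_high = rec$fht >= criteria$fht_floor - .ms_eps,
                  cort_low = rec$cort <= criteria$cort_ceiling + .ms_eps)
  for (j in seq_along(cfg$labels)) {
    labels <- cbind(labels,
                    cfg$offsets[, j] >= 3L, cfg$offsets[, j] <= -3L)
    colnames(labels)[ncol(labels) - 1:0] <-
      paste0(cfg$labels[j], c("_sens_gt_3", "_desens_gt_3"))
  }
  keys <- apply(cfg$offsets, 1, paste, collapse = ",")
  index <- stats::setNames(seq_len(n), keys)
  structure(list(offsets = cfg$offsets, magnitudes = cfg$magnitudes,
                 labels = labels, index = index, budget = budget,
                 base = cfg$base, increment = increment,
                 tsc_labels = cfg$labels, chronic = chronic_inputs,
                 records = rec),
            class = "ms_transition_system")
}

#' @export
print.ms_transition_system <- function(x, ...) {
  cat("<ms_transition_system> ", nrow(x$offsets), " states (budget ",
      x$budget, ", ", length(x$tsc_labels), " TSCs); predicates: ",
      paste(colnames(x$labels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.state_key <- function(off) paste(off, collapse = ",")

## Successor state indices of a state (single +/- 1 step on one TSC,
## magnitude staying in [0, 10]).
.successors <- function(ts, idx) {
  off <- ts$offsets[idx, ]
  out <- integer(0)
  for (j in seq_along(off)) {
    for (d in c(-1L, 1L)) {
      nm <- ts$base[j] + (off[j] + d) * ts$increment
      if (nm < -.ms_eps || nm > 10 + .ms_eps) next
      off2 <- off; off2[j] <- off2[j] + d
      out <- c(out, ts$index[[.state_key(off2)]])
    }
  }
  out
}

## Evaluate a boolean formula over predicates ("/\" and, "\/" or, "~"
## not, parentheses) into a per-state logical vector.  Predicate names
## may be non-syntactic (for example starting with a digit), so they
## are substituted by placeholders before parsing.
.eval_formula <- function(ts, formula) {
  preds <- colnames(ts$labels)
  txt <- formula
  env <- new.env(parent = baseenv())
  for (i in order(-nchar(preds))) {
    ph <- paste0(".p", i)
    if (grepl(preds[i], txt, fixed = TRUE)) {
      txt <- gsub(preds[i], ph, txt, fixed = TRUE)
      assign(ph, ts$labels[, preds[i]], envir = env)
    }
  }
  txt <- gsub("/\\", "&", txt, fixed = TRUE)
  txt <- gsub("\\/", "|", txt, fixed = TRUE)
  txt <- gsub("~", "!", txt, fixed = TRUE)
  if (grepl("[A-Za-z0-9_]", gsub("\\.p[0-9]+", "", txt)))
    stop("formula references undeclared predicate(s): ", formula,
         call. = FALSE)
  expr <- str2lang(txt)
  val <- eval(expr, env)
  if (!is.logical(val) || length(val) != nrow(ts$offsets))
    stop("formula did not evaluate to a per-state truth vector: ", formula,
         call. = FALSE)
  val
}

#' Check a bounded leads-to proposition
#'
#' Semantics: over every maximal adjustment trajectory from the origin
#' (a sequence of single-step moves of length at most the budget;
#' maximal means the budget is exhausted or no legal move remains),
#' whenever the antecedent holds at some position, the consequent must
#' hold at that position or at some later position of the same
#' trajectory.  The verdict is computed by memoized search over
#' (configuration, moves-remaining) pairs; a false verdict carries one
#' concrete violating trajectory.
#'
#' @param ts An `ms_transition_system`.
#' @param antecedent Name of a declared predicate.
#' @param consequent Formula string over predicates using the operators
#'   `/\` (and), `\/` (or), `~` (not), and parentheses.
#' @return List with `verdict` (logical) and `counterexample` (`NULL`,
#'   or an integer matrix of offset vectors tracing a violating
#'   trajectory from the origin).
#' @export
check_leads_to <- function(ts, antecedent, consequent) {
  if (!antecedent %in% colnames(ts$labels))
    stop("undeclared antecedent predicate: ", antecedent, call. = FALSE)
  avec <- ts$labels[, antecedent]
  cvec <- .eval_formula(ts, consequent)
  succ_memo <- vector("list", nrow(ts$offsets))
  succ <- function(i) {
    s <- succ_memo[[i]]
    if (is.null(s)) succ_memo[[i]] <<- s <- .successors(ts, i)
    s
  }
  ## bad(i, r): some maximal continuation of exactly r further moves
  ## from state i has the consequent false at every position.
  bad_memo <- new.env(parent = emptyenv())
  bad <- function(i, r) {
    if (cvec[i]) return(FALSE)
    key <- paste0(i, ":", r)
    v <- bad_memo[[key]]
    if (!is.null(v)) return(v)
    s <- if (r > 0L) succ(i) else integer(0)
    v <- if (r == 0L || !length(s)) TRUE
         else any(vapply(s, function(k) bad(k, r - 1L), TRUE))
    bad_memo[[key]] <- v
    v
  }
  ## search reachable (state, moves-remaining) pairs for a violation
  origin <- ts$index[[.state_key(rep(0L, length(ts$base)))]]
  seen <- new.env(parent = emptyenv())
  path <- integer(0)
  hit <- NULL
  dfs <- function(i, r) {
    if (!is.null(hit)) return()
    key <- paste0(i, ":", r)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    path[length(path) + 1L] <<- i
    if (avec[i] && bad(i, r)) {
      hit <<- list(prefix = path, r = r)
    } else if (r > 0L) {
      for (k in succ(i)) dfs(k, r - 1L)
    }
    path <<- path[-length(path)]
  }
  dfs(origin, as.integer(ts$budget))
  if (is.null(hit)) return(list(verdict = TRUE, counterexample = NULL))
  ## extend the violating prefix along consequent-false states
  tail_states <- integer(0)
  i <- hit$prefix[length(hit$prefix)]; r <- hit$r
  while (r > 0L) {
    nxt <- succ(i)
    if (!length(nxt)) break
    k <- nxt[vapply(nxt, function(k) bad(k, r - 1L), TRUE)][1]
    if (is.na(k)) break
    tail_states <- c(tail_states, k)
    i <- k; r <- r - 1L
  }
  ce <- ts$offsets[c(hit$prefix, tail_states), , drop = FALSE]
  rownames(ce) <- NULL
  list(verdict = FALSE, counterexample = ce)
}

#' Run the built-in proposition suite
#'
#' For each adjustable TSC and each direction of adaptation the suite
#' checks the strong proposition that sensitization (or
#' desensitization) by at least three steps leads to high serotonin and
#' low cortisol, and the weakened variant that also accepts losing the
#' three-step adjustment:
#' \preformatted{ TSC_sens_gt_3   |-> fht_high /\ cort_low
#'  TSC_sens_gt_3   |-> (fht_high /\ cort_low) \/ ~TSC_sens_gt_3 }
#' (and the desensitization analogues), per supplied transition system.
#' A row's result is "consistent" only when every system returns the
#' same verdict.
#'
#' @param ts_list List of `ms_transition_system`s (one per
#'   representative network); a single system is accepted.
#' @return Data frame with 20 strong and 20 weakened rows: `tsc`,
#'   `direction`, `form`, one verdict column per system, `consistent`,
#'   and `verdict` (the common verdict, `NA` when inconsistent).
#' @export
run_proposition_suite <- function(ts_list) {
  if (inherits(ts_list, "ms_transition_system")) ts_list <- list(ts_list)
  stopifnot(length(ts_list) >= 1)
  tscs <- ts_list[[1]]$tsc_labels
  grid <- expand.grid(form = c("strong", "weak"),
                      direction = c("sensitization", "desensitization"),
                      tsc = tscs, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    tsc <- grid$tsc[g]
    ante <- paste0(tsc, if (grid$direction[g] == "sensitization")
      "_sens_gt_3" else "_desens_gt_3")
    cons <- if (grid$form[g] == "strong") "fht_high /\\ cort_low"
            else sprintf("(fht_high /\\ cort_low) \\/ ~%s", ante)
    verdicts <- vapply(ts_list, function(ts)
      check_leads_to(ts, ante, cons)$verdict, TRUE)
    data.frame(tsc = tsc, direction = grid$direction[g],
               form = grid$form[g],
               t(stats::setNames(verdicts,
                                 paste0("net", seq_along(verdicts)))),
               consistent = length(unique(verdicts)) == 1L,
               verdict = if (length(unique(verdicts)) == 1L) verdicts[1]
                         else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(factor(out$form, levels = c("strong", "weak")),
            factor(out$direction,
                   levels = c("desensitization", "sensitization")),
            match(out$tsc, tscs)), , drop = FALSE]
}

#' Parse a proposition file
#'
#' One proposition per line, `<antecedent> |-> <formula>`, operators
#' `/\ \/ ~`; blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Data frame with columns `antecedent` and `consequent`.
#' @export
read_propositions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "|->", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("each proposition must be '<antecedent> |-> <formula>'",
         call. = FALSE)
  data.frame(antecedent = trimws(vapply(parts, `[[`, "", 1)),
             consequent = trimws(vapply(parts, `[[`, "", 2)),
             stringsAsFactors = FALSE)
}
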