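## Small transition systems built from the demo structure (untrained
## initializations are fine: labels just need to vary) with 1-2 TSCs.
demo_system <- function(seed, tscs_idx = 1:2, budget = 3,
                        criteria = ms_criteria(fht_floor = 0.45,
                                               cort_ceiling = 0.55)) {
  demo <- build_demo_model()
  net <- initialize_network(demo$structure, seed = seed)
  tscs <- demo$tscs[tscs_idx, ]
  class(tscs) <- c("ms_tsc_spec", "data.frame")
  build_transition_system(net, tscs, "SSRI", budget = budget,
                          criteria = criteria)
}

test_that("transition systems enumerate states and label predicates", {
  demo <- build_demo_model()
  net <- initialize_network(demo$structure, seed = 1)
  one <- demo$tscs[1, ]; class(one) <- c("ms_tsc_spec", "data.frame")
  rt <- resolve_tscs(net, one)
  ## interior magnitude: budget 1 gives origin plus one step each way
  net$magnitude[rt$rows, rt$cols] <- 5
  ts1 <- build_transition_system(net, one, "SSRI", budget = 1)
  expect_identical(nrow(ts1$offsets), 3L)
  ## magnitude at 0: no downward move from the origin
  net$magnitude[rt$rows, rt$cols] <- 0
  ts0 <- build_transition_system(net, one, "SSRI", budget = 1)
  expect_identical(sort(ts0$offsets[, 1]), c(0L, 1L))
  ## offset predicates mark net adjustment of at least three steps
  ts4 <- build_transition_system(net, one, "SSRI", budget = 4)
  lab <- ts4$labels[, "DR_5HT1AR_sens_gt_3"]
  expect_identical(unname(lab), unname(ts4$offsets[, 1] >= 3L))
  expect_error(build_transition_system(net, one, "SSRI", budget = -1),
               ">= 0")
})

test_that("leads-to checker agrees with exhaustive path enumeration", {
  checked <- 0L
  for (seed in 1:6) {
    ts <- demo_system(seed, tscs_idx = seq_len(1 + seed %% 2),
                      budget = 2 + seed %% 2)
    if (count_maximal_paths(ts) > 200) next
    for (ante in colnames(ts$labels)[-(1:2)]) {
      for (cons in c("fht_high /\\ cort_low", "fht_high",
                     "fht_high \\/ cort_low")) {
        got <- check_leads_to(ts, ante, cons)
        want <- oracle_leads_to(ts, ante, .eval_formula(ts, cons))
        expect_identical(got$verdict, want$verdict,
                         label = paste("seed", seed, ante, "->", cons))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 10)
})

test_that("vacuous antecedents and tautological consequents are true", {
  ts <- demo_system(2, tscs_idx = 1, budget = 2)
  ## budget 2 never reaches offset 3: antecedent true nowhere
  expect_true(all(!ts$labels[, "DR_5HT1AR_sens_gt_3"]))
  r <- check_leads_to(ts, "DR_5HT1AR_sens_gt_3", "fht_high /\\ cort_low")
  expect_true(r$verdict)
  expect_null(r$counterexample)
  ## consequent true at every state
  taut <- check_leads_to(ts, "cort_low", "fht_high \\/ ~fht_high")
  expect_true(taut$verdict)
})

test_that("a reachable antecedent with unsatisfiable consequent is refuted", {
  ## single-TSC chain, budget 6: offset +3 reachable (interior
  ## magnitude); consequent false everywhere (impossible conjunction)
  demo <- build_demo_model()
  net <- initialize_network(demo$structure, seed = 3)
  one <- demo$tscs[1, ]; class(one) <- c("ms_tsc_spec", "data.frame")
  rt <- resolve_tscs(net, one)
  net$magnitude[rt$rows, rt$cols] <- 5
  ts <- build_transition_system(net, one, "SSRI", budget = 6)
  expect_true(any(ts$labels[, "DR_5HT1AR_sens_gt_3"]))
  r <- check_leads_to(ts, "DR_5HT1AR_sens_gt_3", "fht_high /\\ ~fht_high")
  expect_false(r$verdict)
  ce <- r$counterexample
  expect_true(is.matrix(ce))
  ## the counterexample replays to a violation: the antecedent holds at
  ## some position and the consequent never afterwards
  idx <- apply(ce, 1, function(o)
    ts$index[[paste(o, collapse = ",")]])
  avec <- ts$labels[idx, "DR_5HT1AR_sens_gt_3"]
  expect_true(any(avec))
  ## consecutive rows differ by exactly one single step
  steps <- abs(diff(ce))
  expect_true(all(rowSums(steps) == 1))
  ## maximality: budget exhausted (moves = rows - 1)
  expect_identical(nrow(ce), as.integer(ts$budget) + 1L)
})

test_that("undeclared predicates and malformed formulas are rejected", {
  ts <- demo_system(4, tscs_idx = 1, budget = 2)
  expect_error(check_leads_to(ts, "no_such_pred", "fht_high"),
               "undeclared antecedent")
  expect_error(check_leads_to(ts, "fht_high", "bogus_pred"),
               "undeclared predicate")
})

test_that("the proposition suite is complete, consistent, and monotone", {
  ts_a <- demo_system(5, tscs_idx = 1:2, budget = 4)
  ts_b <- demo_system(6, tscs_idx = 1:2, budget = 4)
  suite <- run_proposition_suite(list(ts_a, ts_b))
  n_tsc <- length(ts_a$tsc_labels)
  expect_identical(nrow(suite), 4L * n_tsc)     # strong + weak, both directions
  expect_identical(sum(suite$form == "strong"), 2L * n_tsc)
  ## weakening is monotone: strong true implies weak true, per system
  for (tsc in ts_a$tsc_labels) {
    for (dir in c("sensitization", "desensitization")) {
      s <- suite[suite$tsc == tsc & suite$direction == dir, ]
      strong <- s[s$form == "strong", ]; weak <- s[s$form == "weak", ]
      for (col in c("net1", "net2")) {
        if (isTRUE(strong[[col]])) expect_true(weak[[col]])
      }
    }
  }
  ## consistency column: identical verdicts across systems
  expect_identical(suite$consistent, suite$net1 == suite$net2)
  expect_identical(is.na(suite$verdict), !suite$consistent)
})

test_that("proposition files parse into antecedent/consequent pairs", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "",
               "fht_high |-> cort_low",
               "cort_low |-> (fht_high /\\ cort_low) \\/ ~cort_low"), path)
  props <- read_propositions(path)
  expect_identical(nrow(props), 2L)
  expect_identical(props$antecedent[1], "fht_high")
  expect_match(props$consequent[2], "~cort_low", fixed = TRUE)
  writeLines("no arrow here", path)
  expect_error(read_propositions(path), "antecedent")
})
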