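## Shared fixtures.  The trained demo network is expensive (~30 s at the
## default schedule), so it is trained lazily once per test run and
## cached; tests that only need mechanics use shorter schedules.

.cache <- new.env(parent = emptyenv())

trained_demo <- function() {
  if (is.null(.cache$demo_net)) {
    demo <- build_demo_model()
    .cache$demo <- demo
    .cache$demo_net <- train_network(
      initialize_network(demo$structure, seed = 1),
      demo$truth_table, ms_training_config(seed = 1))
  }
  list(demo = .cache$demo, net = .cache$demo_net)
}

## A random small network over explicit units: n_hidden hidden units,
## n_out output units, one input, one bias; random structure entries.
make_small_network <- function(seed, n_hidden = 2, n_out = 2) {
  set.seed(seed)
  units <- ms_units(
    name = c("In1", paste0("H", seq_len(n_hidden)),
             paste0("Out", seq_len(n_out)), "Bias"),
    role = c("input", rep("hidden", n_hidden), rep("output", n_out), "bias"))
  recv <- units$name[units$role %in% c("hidden", "output")]
  mat <- matrix(sample((-2):2, length(recv) * nrow(units), replace = TRUE),
                length(recv), nrow(units),
                dimnames = list(recv, units$name))
  initialize_network(ms_structure(mat, units), seed = seed)
}

## A tiny two-input circuit whose truth table has both single and
## combination patterns, for pruning/generalization tests.  Fast to
## train (few units, few patterns).
make_combo_fixture <- function() {
  units <- ms_units(
    name = c("A", "B", "X", "Y", "H1", "Bias"),
    role = c("input", "input", "output", "output", "hidden", "bias"))
  recv <- units$name[units$role %in% c("hidden", "output")]
  mat <- matrix(0L, length(recv), nrow(units),
                dimnames = list(recv, units$name))
  mat["X", "A"] <- 2L; mat["Y", "B"] <- 2L
  mat["H1", "A"] <- 1L; mat["Y", "H1"] <- 1L
  inputs <- matrix(c(0, 0,
                     1, 0,
                     0, 1,
                     1, 1), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
  targets <- matrix(c(0.50, 0.50,
                      0.60, 0.50,
                      0.50, 0.60,
                      0.60, 0.60), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("X", "Y")))
  list(structure = ms_structure(mat, units),
       truth_table = ms_truth_table(inputs, targets))
}

quick_config <- function(seed = 1, cycles = 2000) {
  ms_training_config(cycles = cycles, seed = seed)
}
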