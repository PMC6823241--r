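test_that("sigmoid anchors: midpoint, symmetry, closed form, domain", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))           # strictly increasing
  expect_error(sigmoid(Inf), "finite")
  expect_error(sigmoid(NA_real_), "finite")
})

test_that("settle of an unconnected network is 0.50 everywhere", {
  net <- make_small_network(seed = 3)
  net$magnitude[] <- 0
  st <- settle(net, c(In1 = 1))
  recv <- rownames(net$magnitude)
  expect_equal(unname(st$activities[recv]), rep(0.5, length(recv)))
  expect_equal(st$max_delta, 0)
  base <- baseline_activities(net)
  expect_equal(unname(base$activities[recv]), rep(0.5, length(recv)))
})

test_that("single self-excitatory unit settles to the scalar fixed point", {
  units <- ms_units(c("In1", "H", "Bias"), c("input", "hidden", "bias"))
  mat <- matrix(0L, 1, 3, dimnames = list("H", c("In1", "H", "Bias")))
  mat["H", "H"] <- 1L
  net <- initialize_network(ms_structure(mat, units), seed = 1)
  net$magnitude[] <- 0                       # isolate the self-connection
  net$magnitude["H", "H"] <- 2.0
  st <- settle(net, numeric(0))
  expect_equal(unname(st$activities[["H"]]), scalar_fixed_point(2.0),
               tolerance = 1e-9)
  expect_equal(round(st$activities[["H"]], 3), 0.844)
})

test_that("settle clamps inputs and bias, is deterministic, stays in (0,1)", {
  net <- make_small_network(seed = 11)
  st1 <- settle(net, c(In1 = 0.7))
  st2 <- settle(net, c(In1 = 0.7))
  expect_identical(st1$activities, st2$activities)
  expect_identical(st1$activities[["In1"]], 0.7)
  expect_identical(st1$activities[["Bias"]], 1)
  recv <- rownames(net$magnitude)
  net$magnitude[] <- 10                 # extreme weights still bounded
  st3 <- settle(net, c(In1 = 1))
  expect_true(all(st3$activities[recv] > 0 & st3$activities[recv] < 1))
  expect_error(settle(net, c(NoSuchInput = 1)), "not declared input")
})

test_that("acyclic chains settle exactly within path-length iterations", {
  units <- ms_units(c("In1", "H1", "H2", "Out1", "Bias"),
                    c("input", "hidden", "hidden", "output", "bias"))
  mat <- matrix(0L, 3, 5,
                dimnames = list(c("H1", "H2", "Out1"), units$name))
  mat["H1", "In1"] <- 1L; mat["H2", "H1"] <- 1L; mat["Out1", "H2"] <- 1L
  net <- initialize_network(ms_structure(mat, units), seed = 2)
  keep <- unclass(ms_structure(mat, units)) != 0L
  net$magnitude[!keep] <- 0                  # acyclic: chain edges only
  short <- settle(net, c(In1 = 1), n_iterations = 3)   # longest path = 3 edges
  long <- settle(net, c(In1 = 1), n_iterations = 100)
  expect_equal(short$activities, long$activities, tolerance = 1e-15)
})

test_that("baseline equals settle at all-zero input and is reproducible", {
  net <- make_small_network(seed = 5)
  b1 <- baseline_activities(net)
  b2 <- baseline_activities(net)
  expect_identical(b1$activities, b2$activities)
  expect_identical(b1$activities, settle(net, numeric(0))$activities)
})

test_that("structure matrix files round-trip and reject bad entries", {
  syn <- generate_synthetic_fullscale(seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure_matrix(syn$structure, path)
  u <- attr(syn$structure, "units")
  back <- read_structure_matrix(path,
                                output_units = u$name[u$role == "output"])
  expect_identical(unclass(back)[, ], unclass(syn$structure)[, ])
  expect_identical(attr(back, "units"), attr(syn$structure, "units"))
  ## corrupt one cell: out-of-range entry must be named in the error
  lines <- readLines(path)
  lines[2] <- sub("\t0\t", "\t3\t", lines[2])
  writeLines(lines, path)
  expect_error(read_structure_matrix(path), "invalid structure entry")
})

test_that("truth table files round-trip; levels and columns validated", {
  demo <- build_demo_model()
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(demo$truth_table, path)
  back <- read_truth_table(path)
  expect_equal(back$inputs, demo$truth_table$inputs, ignore_attr = FALSE)
  expect_equal(back$targets, demo$truth_table$targets)
  expect_identical(back$note, demo$truth_table$note)
  ## a level outside the quantized grid is rejected
  expect_error(
    ms_truth_table(matrix(1, 1, 1, dimnames = list(NULL, "A")),
                   matrix(0.55, 1, 1, dimnames = list(NULL, "X"))),
    "0.30, 0.40, 0.50, 0.60, 0.70")
  ## unknown columns are rejected
  writeLines(c("input:A,whatever", "1,0.5"), path)
  expect_error(read_truth_table(path), "unknown truth-table column")
})

test_that("pattern split partitions by active-input count", {
  demo <- build_demo_model()
  sp <- split_patterns(demo$truth_table)
  expect_identical(nrow(sp$singles$inputs), 5L)   # all Table-1 rows single
  expect_null(sp$combinations)
  expect_identical(sum(!is.na(demo$truth_table$targets[3, ])), 2L)
  ## a target-only row with no active input counts as single (baseline)
  tt <- ms_truth_table(
    matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE,
           dimnames = list(NULL, c("A", "B"))),
    matrix(0.6, 2, 1, dimnames = list(NULL, "X")))
  sp2 <- split_patterns(tt)
  expect_identical(nrow(sp2$singles$inputs), 1L)
  expect_identical(nrow(sp2$combinations$inputs), 1L)
})

test_that("model archives round-trip through JSON", {
  net <- make_small_network(seed = 9)
  net$prune_mask[1, 2] <- TRUE
  net$magnitude[1, 2] <- 0
  path <- withr::local_tempfile(fileext = ".json")
  write_model(net, path)
  back <- read_model(path)
  expect_equal(back$magnitude, net$magnitude)
  expect_identical(back$sign, net$sign)
  expect_identical(back$class, net$class)
  expect_identical(back$prune_mask, net$prune_mask)
  expect_equal(back$bounds, net$bounds)
  st1 <- settle(net, c(In1 = 1)); st2 <- settle(back, c(In1 = 1))
  expect_identical(st1$activities, st2$activities)
})
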