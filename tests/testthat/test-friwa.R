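## FRIWA mechanics are exercised on the demo with relaxed criteria so
## that both resistant and sensitive classes are populated; the
## thresholds themselves are tested in test-adaptation.R.
relaxed <- function() ms_criteria(fht_floor = 0.62, cort_ceiling = 0.68)

friwa_demo <- function(n_starts = 6) {
  td <- trained_demo()
  rec <- evaluate_configurations(
    td$net, enumerate_configurations(td$net, td$demo$tscs, max_degree = 6),
    "SSRI", relaxed(), regions = td$demo$adapt_regions)
  starts <- attr(rec, "offsets")[rec$adapted & rec$therapeutic, ,
                                 drop = FALSE]
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  friwa_sweep(td$net, td$demo$tscs, starts, "SSRI", relaxed(),
              regions = td$demo$adapt_regions)
}

test_that("candidate grids follow the start-relative 0.50 rule", {
  fr <- friwa_demo(n_starts = 2)
  counts <- table(fr$records$start, fr$records$tsc)
  for (s in seq_len(nrow(fr$start_magnitudes))) {
    for (j in seq_along(fr$labels)) {
      w0 <- fr$start_magnitudes[s, j]
      expected <- length(seq(ceiling(-w0 / 0.5 - 1e-9),
                             floor((10 - w0) / 0.5 + 1e-9)))
      expect_identical(unname(counts[as.character(s),
                                     as.character(j)]),
                       as.integer(expected - 1L))  # k = 0 excluded
    }
  }
  ## on-grid start at 3.0: k in -6..14 minus 0 gives 20 candidates
  expect_identical(length(setdiff(seq(-6, 14), 0)), 20L)
  w0 <- 1.3                                             # off-grid example
  ks <- setdiff(seq(ceiling(-w0 / 0.5), floor((10 - w0) / 0.5)), 0)
  expect_identical(length(ks), 19L)   # 2 downward, 17 upward
})

test_that("friwa labels partition candidates and match their flags", {
  fr <- friwa_demo()
  expect_setequal(unique(fr$records$label),
                  intersect(c("excluded", "resistant", "sensitive"),
                            fr$records$label))
  with(fr$records, {
    expect_identical(label == "excluded", !adapted)
    expect_identical(label == "resistant", adapted & therapeutic)
    expect_identical(label == "sensitive", adapted & !therapeutic)
  })
  tab <- table(fr$records$label)
  expect_identical(sum(fr$records$adapted),
                   sum(tab[c("resistant", "sensitive")], na.rm = TRUE))
  ## swept magnitudes stay in range and differ from the start value
  expect_true(all(fr$records$magnitude >= 0 & fr$records$magnitude <= 10))
  expect_true(all(fr$records$k != 0))
})

test_that("non-adapted or non-therapeutic starts are rejected with index", {
  td <- trained_demo()
  origin <- matrix(0L, 1, 3)
  ## the origin is never adapted (strict inequality), so it cannot start
  expect_error(
    friwa_sweep(td$net, td$demo$tscs, origin, "SSRI", relaxed(),
                regions = td$demo$adapt_regions),
    "not adapted and therapeutic: index 1")
})

test_that("per-TSC class means exclude the swept TSC's own values", {
  fr <- friwa_demo()
  sm <- summarize_tsc_means(fr)
  expect_identical(sm$tsc, fr$labels)
  ## recompute by hand for one TSC and class
  v <- friwa_value_matrix(fr)
  sel <- fr$records$label == "resistant"
  for (j in seq_along(fr$labels)) {
    manual <- mean(v[sel, j], na.rm = TRUE)
    expect_equal(sm$resistant_mean[j], manual)
    ## records sweeping TSC j contribute NA there, never a value
    expect_true(all(is.na(v[fr$records$tsc == j, j])))
  }
  ## single-record class: mean equals that record's values
  one <- fr
  keep <- which(fr$records$label == "sensitive")[1]
  one$records <- fr$records[keep, , drop = FALSE]
  m1 <- summarize_tsc_means(one)
  expect_equal(m1$sensitive_mean[-one$records$tsc],
               unname(fr$start_magnitudes[one$records$start,
                                          -one$records$tsc]))
  expect_true(is.nan(m1$sensitive_mean[one$records$tsc]) ||
                is.na(m1$sensitive_mean[one$records$tsc]))
  ## empty class flagged, not zero
  none <- fr
  none$records <- fr$records[fr$records$label == "resistant", , drop = FALSE]
  sm0 <- summarize_tsc_means(none)
  expect_true("sensitive" %in% attr(sm0, "empty_classes"))
  expect_true(all(is.na(sm0$sensitive_mean)))
})

test_that("pairwise correlations: C(n,2) rows, degeneracies flagged", {
  fr <- friwa_demo()
  ct <- tsc_pairwise_correlations(fr, "sensitive")
  expect_identical(nrow(ct), as.integer(choose(length(fr$labels), 2)))
  expect_true(all(c("tsc1", "tsc2", "undefined", "reported") %in%
                    colnames(ct)))
  ## a perfectly duplicated column gives r = 1 and significance
  dup <- fr
  dup$start_magnitudes[, 2] <- dup$start_magnitudes[, 1]
  ## keep only records sweeping TSC 3 so columns 1-2 keep their values
  dup$records <- dup$records[dup$records$tsc == 3 &
                               dup$records$label == "sensitive", ,
                             drop = FALSE]
  if (nrow(dup$records) >= 3 &&
      stats::sd(dup$start_magnitudes[dup$records$start, 1]) > 0) {
    ct2 <- tsc_pairwise_correlations(dup, "sensitive")
    r12 <- ct2[ct2$tsc1 == fr$labels[1] & ct2$tsc2 == fr$labels[2], ]
    expect_equal(unname(r12$r_net1), 1, tolerance = 1e-12)
    expect_lt(r12$p_net1, 0.05)
  }
  ## a constant column is undefined and never reported
  const <- fr
  const$start_magnitudes[, 1] <- 2.5
  const$records <- const$records[const$records$label == "sensitive", ,
                                 drop = FALSE]
  ct3 <- tsc_pairwise_correlations(const, "sensitive")
  c1 <- ct3[ct3$tsc1 == fr$labels[1], ]
  expect_true(all(c1$undefined))
  expect_true(all(!c1$reported))
  ## cross-network consistency: a pair reported only if significant with
  ## the same sign in every network
  both <- tsc_pairwise_correlations(list(fr, fr), "sensitive")
  expect_identical(both$reported,
                   both$p_net1 < 0.05 & both$p_net2 < 0.05 &
                     !both$undefined & sign(both$r_net1) == sign(both$r_net2))
})

test_that("null TSC values are rarely reported at the alpha level", {
  ## independent uniform columns: the all-networks-significant filter
  ## makes reported pairs rare; check a modest empirical rate
  n_rep <- 40
  hits <- 0
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    mk <- function() {
      v <- matrix(runif(30 * 3, 0, 10), 30, 3)
      rec <- data.frame(start = seq_len(30), tsc = sample(1:3, 30, TRUE),
                        label = "sensitive")
      structure(list(records = rec, start_magnitudes = v,
                     labels = paste0("T", 1:3), increment = 0.5),
                class = "ms_friwa")
    }
    ct <- tsc_pairwise_correlations(list(mk(), mk(), mk()), "sensitive")
    hits <- hits + sum(ct$reported)
  }
  ## per-pair chance of passing three independent 5% tests with a common
  ## sign is far below 5%; allow generous slack over 40 x 3 pairs
  expect_lt(hits, 4)
})
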