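#' Demo model: a minimal serotonin/HPA circuit
#'
#' A deterministic, hand-sized realization of the simplified
#' serotonin-plus-stress-axis schematic: the dorsal raphe (DR) produces
#' serotonin (5HT), which excites its inhibitory autoreceptor (5HT1AR)
#' and the adrenal gland (AG); AG produces cortisol (CORT), which drives
#' the glucocorticoid receptor (GCR) that feeds back negatively on AG.
#' The serotonin transporter (5HTT) clears 5HT and is blocked by the
#' SSRI input; Stress excites DR and AG, Dexamethasone activates GCR,
#' and Adrenalectomy removes AG.  The five-row truth table pairs the
#' Baseline, SSRI, Dexamethasone, Stress, and Adrenalectomy inputs with
#' their quantized desired outputs on DR, AG, 5HT, and CORT.
#'
#' @return List with `structure` (an `ms_structure`), `truth_table`
#'   (`ms_truth_table`), `tscs` (the demo's adjustable
#'   transmitter-system components: 5HT1AR->DR, 5HTT->5HT, GCR->AG),
#'   `adapt_regions` (units whose deviation from baseline defines the
#'   adaptation error; here DR and AG), and `level_units` (which units
#'   carry the monoamine/hormone levels used by therapeutic criteria).
#' @examples
#' demo <- build_demo_model()
#' class_counts(demo$structure)
#' @export
build_demo_model <- function() {
  units <- ms_units(
    name = c("SSRI", "Dexamethasone", "Stress", "Adrenalectomy",
             "DR", "AG", "5HT", "CORT", "5HTT", "5HT1AR", "GCR", "Bias"),
    role = c(rep("input", 4), rep("output", 4), rep("hidden", 3), "bias"),
    annotation = c("serotonin reuptake inhibitor (drug)",
                   "synthetic glucocorticoid (drug)",
                   "stressor (manipulation)",
                   "surgical adrenal removal (manipulation)",
                   "dorsal raphe nucleus", "adrenal gland",
                   "serotonin level", "cortisol level",
                   "serotonin transporter", "5HT1A autoreceptor",
                   "glucocorticoid receptor", "constant bias"))
  recv <- .receiving(units)
  mat <- matrix(0L, length(recv), nrow(units),
                dimnames = list(recv, units$name))
  edge <- function(to, from, v) mat[to, from] <<- as.integer(v)
  ## canonical: key monoamine-stress links (|2|)
  edge("5HT", "DR", +2); edge("CORT", "AG", +2)
  edge("DR", "5HT1AR", -2); edge("5HT", "5HTT", -2); edge("AG", "GCR", -2)
  ## structure: other known interactions (|1|)
  edge("5HT1AR", "5HT", +1); edge("5HTT", "SSRI", -1)
  edge("DR", "Stress", +1); edge("AG", "Stress", +1)
  edge("GCR", "CORT", +1); edge("GCR", "Dexamethasone", +1)
  edge("AG", "Adrenalectomy", -1); edge("AG", "5HT", +1)
  structure_mat <- ms_structure(mat, units)
  inputs <- matrix(0, 5, 4,
                   dimnames = list(NULL, c("SSRI", "Dexamethasone", "Stress",
                                           "Adrenalectomy")))
  inputs[2, "SSRI"] <- 1; inputs[3, "Dexamethasone"] <- 1
  inputs[4, "Stress"] <- 1; inputs[5, "Adrenalectomy"] <- 1
  targets <- matrix(NA_real_, 5, 4,
                    dimnames = list(NULL, c("DR", "AG", "5HT", "CORT")))
  targets[1, ] <- c(0.50, 0.50, 0.50, 0.50)
  targets[2, c("DR", "5HT", "CORT")] <- c(0.40, 0.60, 0.70)
  targets[3, c("5HT", "CORT")] <- c(0.60, 0.30)
  targets[4, ] <- c(0.60, 0.70, 0.60, 0.70)
  targets[5, c("AG", "CORT")] <- c(0.30, 0.30)
  tt <- ms_truth_table(inputs, targets,
                       note = c("Baseline", "SSRI", "Dexamethasone",
                                "Stress", "Adrenalectomy"))
  list(structure = structure_mat,
       truth_table = tt,
       tscs = ms_tsc_spec(from = c("5HT1AR", "5HTT", "GCR"),
                          to   = c("DR", "5HT", "AG"),
                          label = c("DR_5HT1AR", "5HT_5HTT", "AG_GCR")),
       adapt_regions = c("DR", "AG"),
       level_units = c(fht = "5HT", cort = "CORT"))
}

## Unit roster of the full-scale synthetic model: 40 inputs (drugs,
## hormones, manipulations), 23 outputs (regions, transmitters,
## hormones, metabolites), 38 hidden units (receptors, transporters,
## enzymes), and one constant bias sender, for 102 columns and 61 rows.
.synthetic_units <- function() {
  inputs <- c("SSRI", "Bupropion", "Olanzapine", "Asenapine", "Quetiapine",
              "Trazodone", "Mirtazapine", "Buspirone", "Pramipexole",
              "Reserpine", "MAOI", "Desipramine", "Ketamine", "Lithium",
              "GBR_12909", "WAY_100635", "RU_28362", "Org_34850",
              "CP_96345", "Antalarmin", "Oxytocin", "Dexamethasone",
              "Corticosterone", "Metyrapone", "Mifepristone", "Yohimbine",
              "Clonidine", "Propranolol", "Haloperidol", "Risperidone",
              "Aripiprazole", "Amphetamine", "Cocaine", "Tianeptine",
              "Agomelatine", "Vortioxetine", "Stress", "Adrenalectomy",
              "Hypophysectomy", "CRF_Infusion")
  outputs <- c("DR", "LC", "VTA", "PVN", "Pituitary", "Adrenal",
               "Amygdala", "PFC", "Hippocampus",
               "5HT", "NE", "DA", "CORT", "ACTH", "CRF", "Oxt",
               "5HIAA", "MHPG", "DOPAC", "HVA", "Galanin", "BDNF", "NPY")
  hidden <- c("5HT1AR", "5HT1BR", "5HT2AR", "5HT2CR", "5HT3R",
              "AR1", "AR2", "BR1", "D1R", "D2R", "D3R", "GCR", "MCR",
              "CRF1R", "CRF2R", "OxtR", "NMDAR", "AMPAR", "GABAAR",
              "MC2R", "V1BR", "5HTT", "NET", "DAT", "VMAT", "MAO_A",
              "MAO_B", "COMT", "TPH2", "TH", "DBH", "GAD", "TrkB",
              "Sigma1R", "H1R", "M1R", "AVP", "Glu")
  ms_units(c(inputs, outputs, hidden, "Bias"),
           c(rep("input", length(inputs)), rep("output", length(outputs)),
             rep("hidden", length(hidden)), "bias"))
}

## The 23 canonical connections of the synthetic model: the 10 adjustable
## TSCs, the region -> transmitter/hormone links, the HPA cascade, the
## transmitter -> receptor links, and the stress drive on the PVN.
.synthetic_canonical <- function() {
  data.frame(
    to = c("DR", "LC", "VTA", "5HT", "NE", "DA", "PVN", "Pituitary",
           "Adrenal", "Pituitary",
           "5HT", "NE", "DA", "CRF", "ACTH", "CORT",
           "CRF1R", "Adrenal", "GCR",
           "5HT1AR", "AR2", "D2R", "PVN"),
    from = c("5HT1AR", "AR2", "D2R", "5HTT", "NET", "DAT", "GCR", "GCR",
             "GCR", "CRF1R",
             "DR", "LC", "VTA", "PVN", "Pituitary", "Adrenal",
             "CRF", "ACTH", "CORT",
             "5HT", "NE", "DA", "Stress"),
    valence = c(-2L, -2L, -2L, -2L, -2L, -2L, -2L, -2L, -2L, +2L,
                +2L, +2L, +2L, +2L, +2L, +2L,
                +2L, +2L, +2L,
                +2L, +2L, +2L, +2L),
    stringsAsFactors = FALSE)
}

#' The ten adjustable transmitter-system components
#'
#' The TSC roster of the full-scale model: autoreceptors on the three
#' monoamine source regions, the three monoamine transporters, the
#' glucocorticoid receptors on the three HPA stations, and the CRF1
#' receptor on the pituitary.  Each resolves to one connection weight
#' whose magnitude adapts in 0.50 steps within [0, 10].
#'
#' @return An `ms_tsc_spec` of the 10 connections.
#' @export
fullscale_tscs <- function() {
  ms_tsc_spec(
    from = c("5HT1AR", "AR2", "D2R", "5HTT", "NET", "DAT",
             "GCR", "GCR", "GCR", "CRF1R"),
    to = c("DR", "LC", "VTA", "5HT", "NE", "DA",
           "PVN", "Pituitary", "Adrenal", "Pituitary"),
    label = c("DR_5HT1AR", "LC_AR2", "VTA_D2R", "5HT_5HTT", "NE_NET",
              "DA_DAT", "PVN_GCR", "Pituitary_GCR", "Adrenal_GCR",
              "Pituitary_CRF1R"))
}

#' Generate the full-scale synthetic structure matrix and truth table
#'
#' Emulates the dimensions and class structure of the complete model
#' without transcribing its biological content: 102 units (40 input, 23
#' output, 38 hidden, 1 bias) giving a 61 x 102 weight matrix (6222
#' weights); 23 canonical connections (including the 10 adjustable TSCs
#' and the region-to-transmitter links); 305 structure connections
#' placed at random with equiprobable valence, seeded so that every
#' output is reachable from some input through declared connections;
#' and a 66-row truth table of 41 single-input patterns (one all-zero
#' baseline plus one per input) and 25 combination patterns whose
#' targets combine the constituent single-pattern deviations from 0.50,
#' saturating at the 0.30/0.70 extremes and re-quantized to the 5-level
#' grid.  Identical seeds produce byte-identical files when written.
#'
#' @param seed Integer seed.
#' @return List with `structure`, `truth_table`, and `tscs`
#'   (= [fullscale_tscs()]).
#' @export
generate_synthetic_fullscale <- function(seed = 1L) {
  units <- .synthetic_units()
  recv <- .receiving(units)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mat <- matrix(0L, length(recv), nrow(units),
                dimnames = list(recv, units$name))
  can <- .synthetic_canonical()
  mat[cbind(can$to, can$from)] <- can$valence
  input_names <- units$name[units$role == "input"]
  output_names <- units$name[units$role == "output"]
  n_structure <- 305L
  ## seed coverage: connect each input to a receiving unit and keep
  ## adding random edges until every output unit is reachable from some
  ## input through canonical + structure connections
  add_edge <- function(to, from) {
    if (mat[to, from] == 0L) {
      mat[to, from] <<- sample(c(-1L, 1L), 1)
      TRUE
    } else FALSE
  }
  for (inp in input_names) {
    repeat if (add_edge(sample(recv, 1), inp)) break
  }
  repeat {
    unreachable <- setdiff(output_names, .reachable_from_inputs(mat, units))
    if (!length(unreachable)) break
    add_edge(sample(unreachable, 1), sample(input_names, 1))
  }
  while (sum(abs(mat) == 1L) < n_structure) {
    add_edge(sample(recv, 1), sample(units$name, 1))
  }
  structure_mat <- ms_structure(mat, units)

  ## truth table: baseline + 40 singles + 25 combinations
  n_in <- length(input_names); n_out <- length(output_names)
  single_in <- rbind(0, diag(n_in))
  colnames(single_in) <- input_names
  single_tg <- matrix(NA_real_, n_in + 1, n_out,
                      dimnames = list(NULL, output_names))
  single_tg[1, ] <- 0.50                      # baseline: no change anywhere
  for (i in seq_len(n_in)) {
    k <- sample(4:8, 1)
    which_out <- sample(output_names, k)
    single_tg[i + 1, which_out] <- sample(.ms_levels, k, replace = TRUE)
  }
  combos <- vector("list", 25)
  combo_in <- matrix(0, 25, n_in, dimnames = list(NULL, input_names))
  combo_tg <- matrix(NA_real_, 25, n_out, dimnames = list(NULL, output_names))
  for (j in seq_len(25)) {
    size <- sample(2:3, 1)
    members <- sample(seq_len(n_in), size)
    combo_in[j, members] <- 1
    dev <- colSums(single_tg[members + 1, , drop = FALSE] - 0.50,
                   na.rm = TRUE)
    touched <- colSums(!is.na(single_tg[members + 1, , drop = FALSE])) > 0
    lv <- clip(0.50 + dev[touched], 0.30, 0.70)
    combo_tg[j, touched] <- .ms_levels[
      vapply(lv, function(v) which.min(abs(v - .ms_levels)), 1L)]
  }
  tt <- ms_truth_table(rbind(single_in, combo_in),
                       rbind(single_tg, combo_tg),
                       note = c("baseline", input_names,
                                paste0("combination_", seq_len(25))))
  list(structure = structure_mat, truth_table = tt, tscs = fullscale_tscs())
}

## Units reachable from any input along non-zero structure-matrix entries.
.reachable_from_inputs <- function(mat, units) {
  frontier <- units$name[units$role == "input"]
  seen <- character(0)
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- rownames(mat)[rowSums(abs(mat[, frontier, drop = FALSE])) > 0]
    frontier <- setdiff(nxt, seen)
  }
  setdiff(seen, units$name[units$role == "input"])
}
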