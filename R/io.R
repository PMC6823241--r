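#' Construct a truth table
#'
#' A truth table is an ordered set of input/desired-output training
#' patterns.  Inputs are binary (a drug or manipulation present or
#' absent); desired outputs are quantized to five discrete levels
#' between 0.30 (maximal decrease) and 0.70 (maximal increase) around
#' the 0.50 baseline, and may be absent (no target for that output in
#' that pattern).
#'
#' @param inputs Numeric 0/1 matrix, one row per pattern, columns named
#'   by input units.
#' @param targets Numeric matrix, one row per pattern, columns named by
#'   output units; entries in \{0.30, 0.40, 0.50, 0.60, 0.70\} or `NA`
#'   for "no target".
#' @param note Optional character vector of per-pattern provenance notes.
#' @return An object of class `ms_truth_table`.
#' @export
ms_truth_table <- function(inputs, targets, note = NULL) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets))
    stop("`inputs` and `targets` must have one row per pattern", call. = FALSE)
  if (is.null(colnames(inputs)) || is.null(colnames(targets)))
    stop("`inputs` and `targets` need column names", call. = FALSE)
  if (!all(inputs %in% c(0, 1)))
    stop("truth-table inputs must be 0 or 1", call. = FALSE)
  lv <- targets[!is.na(targets)]
  bad <- lv[vapply(lv, function(v) all(abs(v - .ms_levels) > .ms_eps), TRUE)]
  if (length(bad))
    stop("desired-output levels must be in {0.30, 0.40, 0.50, 0.60, 0.70}; got ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(rowSums(!is.na(targets)) == 0))
    stop("every pattern must carry at least one target", call. = FALSE)
  structure(list(inputs = inputs, targets = targets,
                 note = note %||% rep(NA_character_, nrow(inputs))),
            class = "ms_truth_table")
}

#' @export
print.ms_truth_table <- function(x, ...) {
  sp <- split_patterns(x)
  cat("<ms_truth_table> ", nrow(x$inputs), " patterns (",
      nrow(sp$singles$inputs), " single, ",
      if (is.null(sp$combinations)) 0 else nrow(sp$combinations$inputs),
      " combination); ", ncol(x$inputs), " inputs, ",
      ncol(x$targets), " target columns\n", sep = "")
  invisible(x)
}

#' Split a truth table into single and combination patterns
#'
#' Patterns with at most one active input (including the all-zero
#' baseline pattern) are "single"; patterns with two or more active
#' inputs are "combination".  The split is the basis of the
#' generalization test used to tune pruning: train on singles, test on
#' combinations.
#'
#' @param table An `ms_truth_table`.
#' @return List with elements `singles` and `combinations` (the latter
#'   `NULL` when no combination patterns exist).
#' @export
split_patterns <- function(table) {
  stopifnot(inherits(table, "ms_truth_table"))
  k <- rowSums(table$inputs)
  take <- function(idx) {
    if (!length(idx)) return(NULL)
    ms_truth_table(table$inputs[idx, , drop = FALSE],
                   table$targets[idx, , drop = FALSE],
                   table$note[idx])
  }
  list(singles = take(which(k <= 1)), combinations = take(which(k >= 2)))
}

subset_patterns <- function(table, idx) {
  ms_truth_table(table$inputs[idx, , drop = FALSE],
                 table$targets[idx, , drop = FALSE], table$note[idx])
}

#' Read and write structure-matrix files
#'
#' Tab-separated carrier for the structure matrix: a header row of
#' sending-unit names, then one row per receiving unit whose first field
#' is the unit name followed by the integer class/valence entries
#' (-2..2).  Unit roles are reconstructed from the file: columns that
#' are not rows are input units (or the bias unit, recognized by the
#' name `Bias`); receiving units named in `output_units` are outputs,
#' the rest hidden.
#'
#' @param path File path.
#' @param output_units Character vector naming which receiving units are
#'   outputs (eligible to carry targets).  Default: all receiving units.
#' @return For the reader, an `ms_structure` (with unit table attached);
#'   the writer returns `path` invisibly.  A write followed by a read is
#'   the identity.
#' @export
read_structure_matrix <- function(path, output_units = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("structure file too short: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  send <- fields[[1]][-1]
  nf <- lengths(fields[-1])
  if (any(nf != length(send) + 1))
    stop("ragged structure file: row ", which(nf != length(send) + 1)[1] + 1,
         " has ", nf[nf != length(send) + 1][1], " fields, expected ",
         length(send) + 1, call. = FALSE)
  recv <- vapply(fields[-1], `[[`, "", 1)
  vals <- suppressWarnings(
    vapply(fields[-1], function(f) as.numeric(f[-1]), numeric(length(send))))
  mat <- t(matrix(vals, nrow = length(send),
                  dimnames = list(send, recv)))
  bad <- which(is.na(mat) | mat != round(mat) | abs(mat) > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "invalid structure entry at row '%s', column '%s' of %s",
      recv[bad[1, 1]], send[bad[1, 2]], path), call. = FALSE)
  inputs <- setdiff(send, recv)
  output_units <- output_units %||% recv
  unknown <- setdiff(output_units, recv)
  if (length(unknown))
    stop("output_units not among receiving units: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  role <- ifelse(send %in% recv,
                 ifelse(send %in% output_units, "output", "hidden"),
                 ifelse(send == "Bias", "bias", "input"))
  units <- ms_units(send, role)
  ms_structure(mat, units)
}

#' @rdname read_structure_matrix
#' @param structure An `ms_structure` to write.
#' @export
write_structure_matrix <- function(structure, path) {
  mat <- unclass(structure)
  lines <- c(paste(c("", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write truth-table files
#'
#' Comma-separated carrier for truth tables.  Columns named
#' `input:<unit>` hold the 0/1 input assignment, columns named
#' `target:<unit>` the quantized desired outputs (blank = no target);
#' an optional `note` column carries per-row provenance.
#'
#' @param path File path.
#' @return For the reader an `ms_truth_table`; the writer returns `path`
#'   invisibly.  Write-then-read is the identity.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- colnames(df)
  in_cols <- grep("^input:", cn)
  tg_cols <- grep("^target:", cn)
  other <- setdiff(seq_along(cn), c(in_cols, tg_cols, which(cn == "note")))
  if (length(other))
    stop("unknown truth-table column(s): ",
         paste(cn[other], collapse = ", "), call. = FALSE)
  if (!length(in_cols) || !length(tg_cols))
    stop("truth table needs input: and target: columns", call. = FALSE)
  inputs <- as.matrix(df[, in_cols, drop = FALSE])
  colnames(inputs) <- sub("^input:", "", cn[in_cols])
  inputs[is.na(inputs)] <- 0
  targets <- as.matrix(df[, tg_cols, drop = FALSE])
  colnames(targets) <- sub("^target:", "", cn[tg_cols])
  ms_truth_table(inputs, targets,
                 note = if ("note" %in% cn) as.character(df$note) else NULL)
}

#' @rdname read_truth_table
#' @param table An `ms_truth_table` to write.
#' @export
write_truth_table <- function(table, path) {
  fmt <- function(m, digits) {
    out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
    out[!is.na(m)] <- formatC(m[!is.na(m)], format = "f", digits = digits)
    out
  }
  df <- data.frame(fmt(table$inputs, 0), fmt(table$targets, 2),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(paste0("input:", colnames(table$inputs)),
                    paste0("target:", colnames(table$targets)))
  if (any(!is.na(table$note))) df$note <- ifelse(is.na(table$note), "", table$note)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a network to a single JSON archive
#'
#' Stores units, signs, magnitudes, connection classes, prune mask,
#' bounds, and the seeds used, with a format-version field, so a trained
#' model can be reloaded bit-exactly.
#'
#' @param network An `ms_network`.
#' @param path Destination file.
#' @return `path`, invisibly; `read_model()` returns the restored
#'   `ms_network`.
#' @export
write_model <- function(network, path) {
  payload <- list(
    format = "msadapt-model", version = 1L,
    units = network$units,
    recv = rownames(network$magnitude),
    send = colnames(network$magnitude),
    sign = network$sign, magnitude = network$magnitude,
    class = network$class, prune_mask = network$prune_mask,
    bounds = network$bounds, seed = network$seed,
    history = network$history)
  ## I(17) significant digits: doubles survive the round trip exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "msadapt-model"))
    stop("not an msadapt model archive: ", path, call. = FALSE)
  dn <- list(p$recv, p$send)
  net <- list(units = ms_units(p$units$name, p$units$role, p$units$annotation),
              sign = matrix(as.double(p$sign), length(p$recv),
                            dimnames = dn),
              magnitude = matrix(as.double(p$magnitude), length(p$recv),
                                 dimnames = dn),
              class = matrix(p$class, length(p$recv), dimnames = dn),
              prune_mask = matrix(p$prune_mask, length(p$recv), dimnames = dn),
              bounds = lapply(p$bounds, function(b) {
                b <- unlist(b); names(b) <- c("lower", "upper"); b
              }),
              seed = p$seed, history = p$history)
  class(net) <- "ms_network"
  net
}
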