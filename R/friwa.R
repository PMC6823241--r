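#' Full-range individual-weight adjustment (FRIWA) sweep
#'
#' A sensitivity analysis of single TSCs: starting from configurations
#' that are both adapted and therapeutic under the chronic input, each
#' adjustable TSC in turn is swept across its full magnitude range in
#' 0.50 steps (candidates \eqn{w_0 + k \cdot 0.50}, \eqn{k \ne 0},
#' within [0, 10]) while the other TSCs stay frozen.  A start whose ten
#' magnitudes sit on the 0.50 grid yields exactly 20 candidates per TSC
#' (200 per start); off-grid or near-boundary values yield fewer.  Each
#' candidate is settled and labeled: `excluded` (no longer adapted),
#' `resistant` (adapted and still therapeutic), or `sensitive` (adapted
#' but no longer therapeutic) -- a partition of all candidates.
#'
#' @param network A trained `ms_network`.
#' @param tscs An `ms_tsc_spec`.
#' @param start_offsets Integer matrix (starts x TSCs) of offset
#'   vectors, each verified adapted and therapeutic; typically the
#'   matching rows of an [evaluate_configurations()] result.
#' @param chronic_inputs Chronic input units (held at 1).
#' @param criteria An [ms_criteria()].
#' @param regions Passed to [evaluate_configurations()].
#' @param increment Magnitude step (default 0.50).
#' @param chunk Candidates per settle batch (memory/speed trade-off).
#' @return Object of class `ms_friwa`: list with `records` (data frame:
#'   start, swept TSC, step k, candidate magnitude, adaptation error,
#'   flags, label), `start_magnitudes` (starts x TSCs), `labels`, and
#'   the criteria used.
#' @export
friwa_sweep <- function(network, tscs, start_offsets, chronic_inputs,
                        criteria = ms_criteria(), regions = NULL,
                        increment = 0.5, chunk = 20000L) {
  rt <- resolve_tscs(network, tscs)
  start_offsets <- matrix(as.integer(start_offsets),
                          ncol = length(rt$base),
                          dimnames = list(NULL, rt$labels))
  n_tsc <- length(rt$base)
  start_mag <- sweep(start_offsets * increment, 2L, rt$base, `+`)
  if (any(start_mag < -.ms_eps | start_mag > 10 + .ms_eps))
    stop("start configuration drives a magnitude outside [0, 10]",
         call. = FALSE)
  start_mag <- clip(start_mag, 0, 10)
  ## verify the starts: each must be adapted and therapeutic
  cfg0 <- list(offsets = start_offsets, magnitudes = start_mag,
               rows = rt$rows, cols = rt$cols)
  chk <- evaluate_configurations(network, cfg0, chronic_inputs, criteria,
                                 regions = regions)
  bad <- which(!(chk$adapted & chk$therapeutic))
  if (length(bad))
    stop("start configuration(s) not adapted and therapeutic: index ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ## build the candidate roster
  cand <- vector("list", nrow(start_mag) * n_tsc)
  pos <- 0L
  for (s in seq_len(nrow(start_mag))) {
    for (j in seq_len(n_tsc)) {
      w0 <- start_mag[s, j]
      k <- seq(ceiling((0 - w0) / increment - .ms_eps),
               floor((10 - w0) / increment + .ms_eps))
      k <- k[k != 0]
      pos <- pos + 1L
      cand[[pos]] <- data.frame(start = s, tsc = j, k = k,
                                magnitude = w0 + k * increment)
    }
  }
  cand <- do.call(rbind, cand)
  ## evaluate in chunks; candidate c = start magnitudes with TSC j replaced
  values <- t(start_mag[cand$start, , drop = FALSE])
  values[cbind(cand$tsc, seq_len(nrow(cand)))] <- cand$magnitude
  records <- vector("list", ceiling(nrow(cand) / chunk))
  for (b in seq_along(records)) {
    idx <- ((b - 1L) * chunk + 1L):min(b * chunk, nrow(cand))
    cfg <- list(offsets = matrix(0L, length(idx), n_tsc,
                                 dimnames = list(NULL, rt$labels)),
                magnitudes = t(values[, idx, drop = FALSE]),
                rows = rt$rows, cols = rt$cols)
    rec <- evaluate_configurations(network, cfg, chronic_inputs, criteria,
                                   regions = regions)
    records[[b]] <- data.frame(cand[idx, ],
                               adaptation_error = rec$adaptation_error,
                               adapted = rec$adapted,
                               therapeutic = rec$therapeutic,
                               as.data.frame(rec)[, names(.level_units(network)),
                                                  drop = FALSE])
  }
  records <- do.call(rbind, records)
  records$label <- ifelse(!records$adapted, "excluded",
                          ifelse(records$therapeutic, "resistant",
                                 "sensitive"))
  rownames(records) <- NULL
  structure(list(records = records, start_magnitudes = start_mag,
                 labels = rt$labels, increment = increment,
                 criteria = criteria, chronic = chronic_inputs),
            class = "ms_friwa")
}

#' @export
print.ms_friwa <- function(x, ...) {
  tab <- table(factor(x$records$label,
                      levels = c("excluded", "resistant", "sensitive")))
  cat("<ms_friwa> ", nrow(x$start_magnitudes), " starts, ",
      nrow(x$records), " candidates: ", tab[["excluded"]], " excluded, ",
      tab[["resistant"]], " resistant, ", tab[["sensitive"]],
      " sensitive\n", sep = "")
  invisible(x)
}

## Post-sweep TSC values of every record: the start's magnitudes with
## the swept TSC replaced by its candidate value, and the swept entry
## set to NA so it is excluded from class statistics (its value was
## manipulated, not adapted).
friwa_value_matrix <- function(friwa) {
  v <- friwa$start_magnitudes[friwa$records$start, , drop = FALSE]
  v[cbind(seq_len(nrow(v)), friwa$records$tsc)] <- NA_real_
  colnames(v) <- friwa$labels
  v
}

#' Mean TSC magnitudes of resistant and sensitive configurations
#'
#' For each TSC and each class (resistant, sensitive), the mean
#' magnitude over the post-sweep configurations of that class,
#' excluding from each record the TSC that was itself swept.  An empty
#' class yields `NA` means and is flagged, never reported as zero.
#'
#' @param friwa An `ms_friwa` result.
#' @return Data frame: `tsc`, `resistant_mean`, `sensitive_mean`,
#'   `resistant_n`, `sensitive_n`, plus attribute `empty_classes`.
#' @export
summarize_tsc_means <- function(friwa) {
  v <- friwa_value_matrix(friwa)
  one <- function(cls) {
    sel <- friwa$records$label == cls
    if (!any(sel)) return(list(mean = rep(NA_real_, ncol(v)), n = 0L))
    list(mean = colMeans(v[sel, , drop = FALSE], na.rm = TRUE),
         n = sum(sel))
  }
  res <- one("resistant"); sen <- one("sensitive")
  out <- data.frame(tsc = friwa$labels,
                    resistant_mean = res$mean, sensitive_mean = sen$mean,
                    resistant_n = res$n, sensitive_n = sen$n,
                    stringsAsFactors = FALSE)
  attr(out, "empty_classes") <-
    c("resistant", "sensitive")[c(res$n, sen$n) == 0L]
  rownames(out) <- NULL
  out
}

#' Pairwise correlations between TSC magnitudes
#'
#' Pearson correlation between every pair of adjustable TSC magnitudes
#' over the resistant (or sensitive) post-sweep configurations of each
#' network, with swept values excluded pairwise.  A pair is "reported"
#' only when it is significant at `alpha` with the same correlation
#' sign in every supplied network; a constant column makes the
#' correlation undefined and the pair is flagged, never reported.
#'
#' @param friwas List of `ms_friwa` results, one per representative
#'   network (a single `ms_friwa` is accepted).
#' @param class `"resistant"` or `"sensitive"`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per TSC pair (C(n,2) rows): the
#'   per-network `r` and `p` columns, `undefined` flag, and `reported`.
#' @export
tsc_pairwise_correlations <- function(friwas, class = c("resistant",
                                                        "sensitive"),
                                      alpha = 0.05) {
  class <- match.arg(class)
  if (inherits(friwas, "ms_friwa")) friwas <- list(friwas)
  labels <- friwas[[1]]$labels
  pairs <- utils::combn(length(labels), 2)
  out <- data.frame(tsc1 = labels[pairs[1, ]], tsc2 = labels[pairs[2, ]],
                    stringsAsFactors = FALSE)
  rmat <- pmat <- matrix(NA_real_, ncol(pairs), length(friwas))
  for (m in seq_along(friwas)) {
    f <- friwas[[m]]
    v <- friwa_value_matrix(f)[f$records$label == class, , drop = FALSE]
    for (q in seq_len(ncol(pairs))) {
      x <- v[, pairs[1, q]]; y <- v[, pairs[2, q]]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 3 || stats::sd(x[keep]) == 0 ||
          stats::sd(y[keep]) == 0) next   # undefined: constant or too few
      ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
      rmat[q, m] <- ct$estimate; pmat[q, m] <- ct$p.value
    }
  }
  colnames(rmat) <- paste0("r_net", seq_along(friwas))
  colnames(pmat) <- paste0("p_net", seq_along(friwas))
  undefined <- rowSums(is.na(rmat)) > 0
  same_sign <- apply(rmat, 1, function(r)
    !anyNA(r) && (all(r > 0) || all(r < 0)))
  signif_all <- rowSums(pmat < alpha, na.rm = TRUE) == length(friwas) &
    !undefined
  cbind(out, rmat, pmat,
        data.frame(undefined = undefined,
                   reported = signif_all & same_sign))
}
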