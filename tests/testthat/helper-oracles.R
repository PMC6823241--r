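## Independent oracles.  Each reimplements the quantity it checks by a
## different route than the package (scalar iteration, finite
## differences, breadth-first closure, exhaustive path enumeration) so
## agreement is evidence, not tautology.

## Fixed point of x <- sigmoid(w * x) by plain scalar iteration.
scalar_fixed_point <- function(w, x0 = 0.5, tol = 1e-12, max_iter = 1e5) {
  x <- x0
  for (i in seq_len(max_iter)) {
    xn <- 1 / (1 + exp(-w * x))
    if (abs(xn - x) < tol) return(xn)
    x <- xn
  }
  x
}

## Central finite differences of the pattern error with respect to every
## unpruned magnitude.
fd_gradient <- function(network, pattern, h = 1e-5, n_iterations = 100) {
  E <- function(net) {
    st <- settle(net, pattern$inputs, n_iterations = n_iterations)
    tg <- pattern$targets[!is.na(pattern$targets)]
    sum((tg - st$activities[names(tg)])^2) / 2
  }
  g <- network$magnitude * 0
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(ncol(g))) {
      if (network$prune_mask[i, j]) next
      np <- network; np$magnitude[i, j] <- np$magnitude[i, j] + h
      nm <- network; nm$magnitude[i, j] <- nm$magnitude[i, j] - h
      g[i, j] <- (E(np) - E(nm)) / (2 * h)
    }
  }
  g
}

## Breadth-first closure of single +/- 1 offset steps under the
## magnitude bounds; returns the sorted set of offset keys.
bfs_offset_keys <- function(base, max_degree, increment = 0.5,
                            lower = 0, upper = 10) {
  key <- function(v) paste(v, collapse = ",")
  seen <- new.env(parent = emptyenv())
  origin <- rep(0L, length(base))
  assign(key(origin), origin, envir = seen)
  frontier <- list(origin)
  for (d in seq_len(max_degree)) {
    nxt <- list()
    for (v in frontier) {
      for (j in seq_along(v)) {
        for (s in c(-1L, 1L)) {
          v2 <- v; v2[j] <- v2[j] + s
          m <- base[j] + v2[j] * increment
          if (m < lower - 1e-9 || m > upper + 1e-9) next
          k <- key(v2)
          if (is.null(seen[[k]])) {
            assign(k, v2, envir = seen)
            nxt[[length(nxt) + 1L]] <- v2
          }
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  sort(ls(seen))
}

## Closed-form size of the L1 ball of radius d on the n-dimensional
## integer lattice: sum_k 2^k C(n,k) C(d,k).
lattice_count <- function(n, d) {
  sum(vapply(0:min(n, d), function(k)
    2^k * choose(n, k) * choose(d, k), 0))
}

## Exhaustive leads-to check by enumerating every maximal move sequence
## from the origin.  Independent successor computation from the
## transition system's offsets/base/increment fields.
oracle_leads_to <- function(ts, antecedent, consequent_vec) {
  idx <- stats::setNames(seq_len(nrow(ts$offsets)),
                         apply(ts$offsets, 1, paste, collapse = ","))
  succ <- function(i) {
    off <- ts$offsets[i, ]
    out <- integer(0)
    for (j in seq_along(off)) for (s in c(-1L, 1L)) {
      m <- ts$base[j] + (off[j] + s) * ts$increment
      if (m < -1e-9 || m > 10 + 1e-9) next
      o2 <- off; o2[j] <- o2[j] + s
      out <- c(out, idx[[paste(o2, collapse = ",")]])
    }
    out
  }
  avec <- ts$labels[, antecedent]
  cvec <- consequent_vec
  ok <- TRUE
  n_paths <- 0L
  walk <- function(path, r) {
    if (!ok) return()
    i <- path[length(path)]
    s <- if (r > 0L) succ(i) else integer(0)
    if (r == 0L || !length(s)) {      # maximal sequence: check it
      n_paths <<- n_paths + 1L
      for (p in seq_along(path)) {
        if (avec[path[p]] && !any(cvec[path[p:length(path)]])) {
          ok <<- FALSE
          return()
        }
      }
    } else {
      for (k in s) walk(c(path, k), r - 1L)
    }
  }
  origin <- idx[[paste(rep(0L, length(ts$base)), collapse = ",")]]
  walk(origin, as.integer(ts$budget))
  list(verdict = ok, n_paths = n_paths)
}

## Count the maximal paths of a transition system (to keep oracle use
## within tractable sizes).
count_maximal_paths <- function(ts) {
  oracle_leads_to(ts, colnames(ts$labels)[1],
                  rep(TRUE, nrow(ts$offsets)))$n_paths
}
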