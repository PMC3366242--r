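# Literal, loop-based transcriptions of the zoning and selection procedures.
# Deliberately naive (position-by-position scans, fixed-point merging) and
# written independently of the package implementation, so that agreement on
# random instances is evidence rather than tautology.

oracle_region <- function(xs, rs, bx, bs) {
  n <- length(xs)
  pi <- 0L
  for (u in seq_len(n)) if (rs[u] <= bs) pi <- u
  lo0 <- max(pi, 1L)
  if (pi + 1L <= n && xs[pi + 1L] <= bx) {
    j <- pi + 1L
    while (j < n && xs[j] < bx) j <- j + 1L
    c(lo0, j)
  } else if (xs[lo0] >= bx) {
    j <- lo0
    while (j > 1L && xs[j] > bx) j <- j - 1L
    c(j, max(min(pi + 1L, n), lo0))
  } else {
    c(lo0, max(min(pi + 1L, n), lo0))
  }
}

oracle_zones <- function(tt, cs) {
  n_a <- nrow(tt$t_scores)
  m <- ncol(tt$t_scores)
  cn <- cs$cn
  a <- matrix(0L, n_a, m)
  b <- matrix(0L, cn, m)
  for (p in seq_len(m)) {
    ord <- order(tt$t_scores[, p])
    xs <- tt$t_scores[ord, p]
    rs <- tt$t_ranks[ord, p]
    lo <- integer(cn)
    hi <- integer(cn)
    for (ej in seq_len(cn)) {
      r <- oracle_region(xs, rs, cs$scores[ej, p], cs$ranks[ej, p])
      lo[ej] <- r[1L]
      hi[ej] <- r[2L]
    }
    # fixed-point merging of regions that share at least one position
    comp <- seq_len(cn)
    repeat {
      changed <- FALSE
      for (i in seq_len(cn)) for (j in seq_len(cn)) {
        if (comp[i] != comp[j] && lo[i] <= hi[j] && lo[j] <= hi[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    cover <- integer(n_a)
    for (ej in seq_len(cn)) cover[lo[ej]:hi[ej]] <- comp[ej]
    run <- integer(n_a)
    cur <- 0L
    for (pos in seq_len(n_a)) {
      if (pos == 1L || cover[pos] != cover[pos - 1L]) cur <- cur + 1L
      run[pos] <- cur
    }
    a[ord, p] <- run
    for (ej in seq_len(cn)) b[ej, p] <- run[lo[ej]]
  }
  list(a_zones = a, b_zones = b)
}

oracle_select <- function(mm, cn) {
  n <- ncol(mm)
  cnb <- nrow(mm)
  sets <- vector("list", cnb)
  for (ej in seq_len(cnb)) {
    thr <- sort(mm[ej, ])[min(cn, n)]
    sets[[ej]] <- which(mm[ej, ] <= thr)
  }
  avg <- rep(Inf, n)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (ej in seq_len(cnb))
      if (i %in% sets[[ej]]) vals <- c(vals, mm[ej, i])
    cnt[i] <- length(vals)
    if (length(vals) > 0L) avg[i] <- sum(vals) / length(vals)
  }
  inset <- which(cnt >= 1L)
  f1 <- f2 <- f3 <- f4 <- rep(FALSE, n)
  if (length(inset)) {
    k3 <- min(ceiling(length(inset) / 3), length(inset))
    k4 <- min(ceiling(length(inset) / 4), length(inset))
    t1 <- sort(avg[inset])[k3]
    t2 <- sort(cnt[inset], decreasing = TRUE)[k3]
    t3 <- sort(avg[inset])[k4]
    t4 <- sort(cnt[inset], decreasing = TRUE)[k4]
    for (i in inset) {
      f1[i] <- avg[i] <= t1
      f2[i] <- cnt[i] >= t2
      f3[i] <- avg[i] <= t3
      f4[i] <- cnt[i] >= t4
    }
  }
  minm <- integer(n)
  for (i in seq_len(n)) minm[i] <- min(mm[, i])
  conds <- list(
    "2.1" = function(i) minm[i] == 0L,
    "2.2" = function(i) minm[i] == 1L,
    "2.3" = function(i) f1[i] && f2[i] && minm[i] == 2L,
    "2.4" = function(i) (f1[i] || f2[i]) && minm[i] == 2L,
    "2.5" = function(i) f3[i] && f4[i])
  sel <- integer(0)
  lab <- character(0)
  for (stp in names(conds)) {
    for (i in seq_len(n)) {
      if (!(i %in% sel) && conds[[stp]](i)) {
        sel <- c(sel, i)
        lab <- c(lab, stp)
      }
    }
    if (length(sel) >= cn) break
  }
  list(idx = sel, step = lab, short = length(sel) < cn)
}
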