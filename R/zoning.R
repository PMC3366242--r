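#' Locate one candidate's region along a score-ordered axis
#'
#' For one variable, the unknown individuals are sorted ascending by
#' transferred score. A candidate's rank (`bs`, on the known set's rank
#' scale) and score (`bx`) each point at a position on this axis; the region
#' spans the stretch between the two pointers. Concretely, `pi` is the last
#' position whose transferred rank is at most `bs`; then
#' \itemize{
#'   \item Case I (score pointer to the right): if the score at `pi + 1` is
#'     at most `bx`, the region extends right to the first position whose
#'     score reaches `bx`, giving `[pi, pi + k]`;
#'   \item Case II (score pointer to the left): if the score at `pi` is at
#'     least `bx`, the region extends left to the last position whose score
#'     is at most `bx`, giving `[pi - k', pi + 1]`;
#'   \item otherwise `bx` falls strictly between the scores at `pi` and
#'     `pi + 1` and the region is the degenerate stretch `[pi, pi + 1]`.
#' }
#' All positions are clamped to `[1, n_A]` (a rank pointer below every
#' transferred rank clamps to 1, above every one to `n_A`).
#'
#' @param t_scores_ordered transferred scores sorted ascending.
#' @param t_ranks_ordered transferred ranks in the same (score) order.
#' @param bx candidate score for this variable.
#' @param bs candidate rank for this variable.
#' @return A list `list(lo, hi)` of 1-based inclusive positions on the
#'   score-ordered axis, `1 <= lo <= hi <= n_A`.
#' @export
find_candidate_region <- function(t_scores_ordered, t_ranks_ordered, bx, bs) {
  n <- length(t_scores_ordered)
  if (n < 1L)
    stop("empty unknown set")
  stopifnot(length(t_ranks_ordered) == n, is.finite(bx), is.finite(bs))
  below <- which(t_ranks_ordered <= bs)
  pi <- if (length(below)) max(below) else 0L
  lo0 <- max(pi, 1L)
  pos <- seq_len(n)
  if (pi + 1L <= n && t_scores_ordered[pi + 1L] <= bx) {
    # Case I: extend right to the first position at or above bx
    at_or_above <- which(t_scores_ordered >= bx & pos >= pi + 1L)
    hi <- if (length(at_or_above)) min(at_or_above) else n
    list(lo = lo0, hi = hi)
  } else if (t_scores_ordered[lo0] >= bx) {
    # Case II: extend left to the last position at or below bx
    at_or_below <- which(t_scores_ordered <= bx & pos <= lo0)
    lo <- if (length(at_or_below)) max(at_or_below) else 1L
    list(lo = lo, hi = max(min(pi + 1L, n), lo0))
  } else {
    list(lo = lo0, hi = max(min(pi + 1L, n), lo0))
  }
}

#' Merge candidate regions and number the zones of one variable
#'
#' Regions sharing at least one position are merged transitively into a
#' single covered run (adjacent-but-disjoint regions stay distinct). The axis
#' `1..n_A` then decomposes into maximal runs -- covered runs and the
#' uncovered gaps between or around them -- and the runs are numbered
#' `1, 2, ...` left to right with no gaps in the label sequence, so every
#' position gets exactly one zone label.
#'
#' @param regions list of regions (each a `list(lo, hi)` as returned by
#'   [find_candidate_region()]) for one variable.
#' @param n_a number of positions on the axis.
#' @return List with `labels` (integer zone label per position) and
#'   `candidate_label` (per input region, the label of the merged run that
#'   contains it).
#' @examples
#' assign_zone_numbers(list(list(lo = 1, hi = 2), list(lo = 5, hi = 6)), 6)
#' # labels 1 1 2 2 3 3; candidate labels 1, 3 (the gap is zone 2)
#' @export
assign_zone_numbers <- function(regions, n_a) {
  stopifnot(length(regions) >= 1L, n_a >= 1L)
  lo <- vapply(regions, function(r) as.integer(r$lo), integer(1L))
  hi <- vapply(regions, function(r) as.integer(r$hi), integer(1L))
  if (any(lo < 1L | hi > n_a | lo > hi))
    stop("regions must satisfy 1 <= lo <= hi <= n_a")
  # sweep over regions sorted by lo, merging on overlap (>= 1 shared position)
  ord <- order(lo, hi)
  comp_of <- integer(length(regions))
  comp_lo <- integer(0)
  comp_hi <- integer(0)
  cur <- 0L
  for (r in ord) {
    if (cur == 0L || lo[r] > comp_hi[cur]) {
      cur <- cur + 1L
      comp_lo[cur] <- lo[r]
      comp_hi[cur] <- hi[r]
    } else {
      comp_hi[cur] <- max(comp_hi[cur], hi[r])
    }
    comp_of[r] <- cur
  }
  # decompose the axis into runs: covered components and uncovered gaps
  labels <- integer(n_a)
  comp_run <- integer(cur)
  nxt <- 1L
  run <- 0L
  for (cc in seq_len(cur)) {
    if (nxt < comp_lo[cc]) {
      run <- run + 1L
      labels[nxt:(comp_lo[cc] - 1L)] <- run
    }
    run <- run + 1L
    labels[comp_lo[cc]:comp_hi[cc]] <- run
    comp_run[cc] <- run
    nxt <- comp_hi[cc] + 1L
  }
  if (nxt <= n_a) {
    run <- run + 1L
    labels[nxt:n_a] <- run
  }
  list(labels = labels, candidate_label = comp_run[comp_of])
}

#' Build the zone table for an unknown set against a candidate set
#'
#' For each variable: the unknown individuals are sorted ascending by
#' transferred score (ties by input order), each candidate's region is
#' located with [find_candidate_region()], the regions are merged and the
#' runs numbered with [assign_zone_numbers()], and the position labels are
#' mapped back to individuals. Each candidate inherits the label of the
#' merged run containing its own region, so unknown individuals and
#' candidates live on the same per-variable zone labelling and their zone
#' vectors are directly comparable.
#'
#' @param tt a `przn_transfer` (see [transfer_table()]).
#' @param cs a `przn_candidates` (see [select_validation_candidates()]).
#' @return An object of class `przn_zones`: list with `a_zones` (`n_A x m`
#'   integer matrix of unknown-set zone labels, rows named by id) and
#'   `b_zones` (`cn x m` candidate zone labels).
#' @export
build_zone_table <- function(tt, cs) {
  stopifnot(inherits(tt, "przn_transfer"), inherits(cs, "przn_candidates"))
  if (!identical(tt$variable_names, colnames(cs$scores)))
    stop("transferred table and candidate set must share the same variables")
  n_a <- length(tt$ids)
  m <- length(tt$variable_names)
  a_zones <- matrix(0L, n_a, m, dimnames = list(tt$ids, tt$variable_names))
  b_zones <- matrix(0L, cs$cn, m,
                    dimnames = list(cs$ids, tt$variable_names))
  for (p in seq_len(m)) {
    ord <- order(tt$t_scores[, p])  # stable: ties keep input order
    xs <- tt$t_scores[ord, p]
    rs <- tt$t_ranks[ord, p]
    regions <- lapply(seq_len(cs$cn), function(ej)
      find_candidate_region(xs, rs, cs$scores[ej, p], cs$ranks[ej, p]))
    zn <- assign_zone_numbers(regions, n_a)
    a_zones[ord, p] <- zn$labels
    b_zones[, p] <- zn$candidate_label
  }
  structure(list(a_zones = a_zones, b_zones = b_zones),
            class = "przn_zones")
}

#' Per-variable zone map for inspection
#'
#' Debug view of one variable's zoning: each unknown individual in score
#' order with its transferred score, transferred rank and zone label.
#'
#' @param tt a `przn_transfer`.
#' @param zones a `przn_zones` built from `tt`.
#' @param variable variable name or index.
#' @return A `data.frame` with columns `position`, `object_id`, `t_score`,
#'   `t_rank`, `zone`.
#' @export
zone_map <- function(tt, zones, variable = 1L) {
  stopifnot(inherits(tt, "przn_transfer"), inherits(zones, "przn_zones"))
  p <- if (is.character(variable))
    match(variable, tt$variable_names) else as.integer(variable)
  if (is.na(p) || p < 1L || p > length(tt$variable_names))
    stop("unknown variable: ", variable)
  ord <- order(tt$t_scores[, p])
  data.frame(position = seq_along(ord),
             object_id = tt$ids[ord],
             t_score = tt$t_scores[ord, p],
             t_rank = tt$t_ranks[ord, p],
             zone = zones$a_zones[ord, p],
             row.names = NULL, stringsAsFactors = FALSE)
}
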