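#' Zone-distance matrix between candidates and unknown individuals
#'
#' The Manhattan distance between zone label vectors:
#' `M[ej, i] = sum_p |Ac[i, p] - Bc[ej, p]|`. A zero entry means the unknown
#' individual's profile falls in exactly the same zone as the candidate's on
#' every variable.
#'
#' @param z a `przn_zones` (see [build_zone_table()]).
#' @return Integer `cn x n_A` matrix, rows named by candidate id, columns by
#'   unknown id.
#' @export
compute_m_matrix <- function(z) {
  stopifnot(inherits(z, "przn_zones"))
  cn <- nrow(z$b_zones)
  mm <- matrix(0L, cn, nrow(z$a_zones),
               dimnames = list(rownames(z$b_zones), rownames(z$a_zones)))
  for (ej in seq_len(cn))
    mm[ej, ] <- as.integer(rowSums(abs(
      sweep(z$a_zones, 2L, z$b_zones[ej, ]))))
  mm
}

#' Nearest sets and eligibility filters from the zone-distance matrix
#'
#' For each candidate `ej`, the nearest set `S_ej` contains every unknown
#' individual whose distance is at most the `cn`-th smallest value in row
#' `ej`; ties at that value are all included, so the set size `W_ej` can
#' exceed `cn`. Each individual then gets two statistics over the sets it
#' belongs to: the mean distance `avg_m` (an infinity sentinel when it
#' belongs to none, which makes it ineligible for F1/F3) and the membership
#' count `count_m`. Among the `U` individuals appearing in at least one set,
#' filter F1 marks the `ceiling(U/3)` smallest `avg_m` and F2 the
#' `ceiling(U/3)` largest `count_m` (ties at the cutoff value included);
#' F3/F4 are the same with `ceiling(U/4)`.
#'
#' @param mm zone-distance matrix from [compute_m_matrix()].
#' @param cn candidate count (selection target).
#' @return An object of class `przn_filters`: list with `sets` (per-candidate
#'   integer index vectors), `w` (set sizes), `avg_m`, `count_m`, and logical
#'   vectors `f1`..`f4` over unknown individuals.
#' @export
build_filter_state <- function(mm, cn) {
  stopifnot(is.matrix(mm), cn >= 1L)
  n_a <- ncol(mm)
  thr <- apply(mm, 1L, function(r) sort(r)[min(cn, length(r))])
  member <- mm <= thr  # thr recycles row-wise down the columns
  sets <- lapply(seq_len(nrow(mm)), function(ej) which(member[ej, ]))
  count_m <- colSums(member)
  total_m <- colSums(mm * member)
  avg_m <- ifelse(count_m > 0L, total_m / pmax(count_m, 1L), Inf)
  u <- count_m >= 1L
  n_u <- sum(u)
  cut_smallest <- function(x, k) {
    out <- rep(FALSE, n_a)
    if (n_u > 0L)
      out[u] <- x[u] <= sort(x[u])[min(k, n_u)]
    out
  }
  cut_largest <- function(x, k) {
    out <- rep(FALSE, n_a)
    if (n_u > 0L)
      out[u] <- x[u] >= sort(x[u], decreasing = TRUE)[min(k, n_u)]
    out
  }
  k3 <- ceiling(n_u / 3)
  k4 <- ceiling(n_u / 4)
  structure(list(sets = sets,
                 w = lengths(sets),
                 avg_m = avg_m,
                 count_m = count_m,
                 f1 = cut_smallest(avg_m, k3),
                 f2 = cut_largest(count_m, k3),
                 f3 = cut_smallest(avg_m, k4),
                 f4 = cut_largest(count_m, k4)),
            class = "przn_filters")
}

#' Select predicted low performers by the zone-distance cascade
#'
#' Admission proceeds in five steps, stopping at the first step after which
#' at least `cn` individuals are selected (later steps never run):
#' \describe{
#'   \item{2.1}{every individual with a zero distance to some candidate;}
#'   \item{2.2}{every individual whose smallest distance is exactly 1;}
#'   \item{2.3}{individuals passing both F1 and F2 whose smallest distance
#'     is 2;}
#'   \item{2.4}{individuals passing F1 or F2 whose smallest distance is 2;}
#'   \item{2.5}{individuals passing both F3 and F4 (no distance constraint).}
#' }
#' The distance condition in steps 2.2--2.4 reads "the smallest distance
#' over candidates", mirroring the reading forced in step 2.1; the
#' alternative reading (some candidate at distance exactly 2 regardless of
#' the minimum) differs only on matrices where an individual's smallest
#' distance is below 2 yet it still passes both filters, and is not
#' implemented. Within a step, individuals are admitted in input order;
#' already-admitted individuals are skipped. The selection may end smaller
#' than `cn` when step 2.5 exhausts -- that is reported, not an error.
#'
#' @param mm zone-distance matrix from [compute_m_matrix()].
#' @param fs filter state from [build_filter_state()].
#' @param cn selection target (the candidate count).
#' @param ids unknown-individual labels; defaults to the column names of
#'   `mm`.
#' @return An object of class `przn_selection`: list with `selected_ids`,
#'   `admit_step` (parallel character vector, values `"2.1"`..`"2.5"`),
#'   `target_count`, `short` (TRUE when fewer than `cn` were selected) and
#'   `details`, a per-individual `data.frame` (`object_id`, `selected`,
#'   `admit_step`, `min_m`, `avg_m`, `count_m`, `f1`..`f4`) suitable for a
#'   report CSV.
#' @export
select_predicted <- function(mm, fs, cn, ids = colnames(mm)) {
  stopifnot(is.matrix(mm), inherits(fs, "przn_filters"), cn >= 1L)
  n_a <- ncol(mm)
  if (is.null(ids))
    ids <- as.character(seq_len(n_a))
  min_m <- apply(mm, 2L, min)
  steps <- list("2.1" = which(min_m == 0L),
                "2.2" = which(min_m == 1L),
                "2.3" = which(fs$f1 & fs$f2 & min_m == 2L),
                "2.4" = which((fs$f1 | fs$f2) & min_m == 2L),
                "2.5" = which(fs$f3 & fs$f4))
  selected <- logical(n_a)
  admit_step <- rep(NA_character_, n_a)
  picked <- integer(0)
  for (lab in names(steps)) {
    new <- steps[[lab]][!selected[steps[[lab]]]]
    selected[new] <- TRUE
    admit_step[new] <- lab
    picked <- c(picked, new)
    if (sum(selected) >= cn)
      break
  }
  structure(list(selected_ids = ids[picked],
                 admit_step = admit_step[picked],
                 target_count = as.integer(cn),
                 short = length(picked) < cn,
                 details = data.frame(object_id = ids,
                                      selected = selected,
                                      admit_step = admit_step,
                                      min_m = min_m,
                                      avg_m = fs$avg_m,
                                      count_m = fs$count_m,
                                      f1 = fs$f1, f2 = fs$f2,
                                      f3 = fs$f3, f4 = fs$f4,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE)),
            class = "przn_selection")
}

#' @export
print.przn_selection <- function(x, ...) {
  cat(sprintf("<przn_selection> %d of %d targeted selected%s\n",
              length(x$selected_ids), x$target_count,
              if (x$short) " (short: cascade exhausted)" else ""))
  if (length(x$selected_ids)) {
    tab <- table(x$admit_step)
    cat("  by step:",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full zone-based prediction pipeline
#'
#' Candidate extraction from the known set, rank/score transfer of the
#' unknown set, zoning, zone distances and the selection cascade, in one
#' call. Any validation variable on the unknown set is ignored here -- it is
#' only ever used to evaluate a selection afterwards.
#'
#' @param known `przn_dataset` with validation (the known cohort).
#' @param unknown `przn_dataset` sharing the known set's variables.
#' @param fraction candidate fraction, see
#'   [select_validation_candidates()].
#' @return A `przn_selection` with the intermediate objects attached as
#'   `candidates`, `transfer` and `zones`.
#' @examples
#' spec <- flock_spec(n = 40, seed = 7)
#' known <- generate_flock(spec)$stages[["14wk"]]
#' unknown <- generate_flock(flock_spec(n = 40, seed = 8))$stages[["14wk"]]
#' run_prezone(known, unknown)
#' @export
run_prezone <- function(known, unknown, fraction = 0.1) {
  cs <- select_validation_candidates(known, fraction)
  tt <- transfer_table(unknown, known)
  zt <- build_zone_table(tt, cs)
  mm <- compute_m_matrix(zt)
  fs <- build_filter_state(mm, cs$cn)
  sel <- select_predicted(mm, fs, cs$cn, ids = unknown$ids)
  sel$candidates <- cs
  sel$transfer <- tt
  sel$zones <- zt
  sel
}
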