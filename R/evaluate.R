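# Half-up (away-from-zero at .5) rounding; the printed selection metrics use
# it, unlike base round()'s banker's rounding.
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Egg-productivity improvement of a selection
#'
#' The improvement attributed to culling: the mean egg number of the birds
#' left after selection, relative to the original flock mean, as a
#' percentage rounded half-up to one decimal. The divisor stays the
#' original (pre-selection) flock mean at every stage of a continuous
#' selection.
#'
#' @param avg_remaining mean egg number of the never-selected birds.
#' @param baseline_avg original flock mean egg number; must be positive.
#' @return Percentage, one decimal.
#' @examples
#' compute_improvement(97.172, 94.57) # 2.8
#' compute_improvement(89.9, 85.1)    # 5.6
#' @export
compute_improvement <- function(avg_remaining, baseline_avg) {
  if (!is.numeric(baseline_avg) || baseline_avg <= 0)
    stop("'baseline_avg' must be positive")
  round_half_up(100 * (avg_remaining - baseline_avg) / baseline_avg, 1L)
}

#' Under-average rate of a selection
#'
#' Selection accuracy proxy: how many of the selected birds laid strictly
#' fewer eggs than the original flock mean, and that count as an integer
#' percentage (half-up) of the selection size.
#'
#' @param selected_eggs egg counts of the selected birds (non-empty).
#' @param baseline_avg original flock mean egg number.
#' @return List with `count` and `percent` (integer).
#' @examples
#' under_average_rate(c(rep(80, 15), rep(90, 4)), 85.1) # 15 of 19 = 79%
#' @export
under_average_rate <- function(selected_eggs, baseline_avg) {
  if (length(selected_eggs) < 1L)
    stop("empty selection")
  count <- sum(selected_eggs < baseline_avg)
  list(count = as.integer(count),
       percent = as.integer(round_half_up(100 * count /
                                            length(selected_eggs))))
}

#' Run one selection stage
#'
#' Runs either the zone method or the regression baseline of a single
#' (known, unknown) stage and, when the unknown set carries a validation
#' variable, evaluates the selection. The unknown set's validation is used
#' only for evaluation, never for selection. Multiple known batches are
#' pooled with [dataset_union()] before candidate extraction (union mode).
#'
#' @param known a `przn_dataset` with validation, or a list of them (union
#'   mode).
#' @param unknown `przn_dataset` sharing the known variables.
#' @param fraction candidate fraction (default 0.1).
#' @param method `"prezone"` or `"regression"`.
#' @param n_select selection size for the regression baseline; when `NULL`
#'   (default) the zone method is run first and its selection size is used,
#'   pairing the two methods the way they are compared.
#' @param baseline_avg original flock mean used for evaluation; defaults to
#'   the unknown set's own mean validation value.
#' @return An object of class `przn_stage`: list with `method`,
#'   `selected_ids`, `n_selected`, `selection` (the `przn_selection`, or the
#'   paired one for regression), `model` (`przn_ols` or `NULL`) and `report`
#'   (one-row `data.frame` with `n_selected`, `avg_remaining`,
#'   `baseline_avg`, `improvement_pct`, `n_under_avg`, `under_avg_pct`; or
#'   `NULL` without validation).
#' @export
run_stage <- function(known, unknown, fraction = 0.1,
                      method = c("prezone", "regression"),
                      n_select = NULL, baseline_avg = NULL) {
  method <- match.arg(method)
  if (is.list(known) && !inherits(known, "przn_dataset"))
    known <- dataset_union(known)
  if (!identical(known$variable_names, unknown$variable_names))
    stop("known and unknown datasets must share the same variables")
  model <- NULL
  selection <- NULL
  if (method == "prezone") {
    selection <- run_prezone(known, unknown, fraction)
    ids <- selection$selected_ids
  } else {
    model <- fit_ols(known)
    if (is.null(n_select)) {
      selection <- run_prezone(known, unknown, fraction)
      n_select <- length(selection$selected_ids)
    }
    ids <- select_lowest(predict_eggs(model, unknown), n_select)
  }
  report <- NULL
  if (!is.null(unknown$validation) && length(ids) >= 1L) {
    eggs <- unknown$validation
    names(eggs) <- unknown$ids
    if (is.null(baseline_avg))
      baseline_avg <- mean(eggs)
    remaining <- eggs[setdiff(unknown$ids, ids)]
    uar <- under_average_rate(eggs[ids], baseline_avg)
    report <- data.frame(
      n_selected = length(ids),
      avg_remaining = mean(remaining),
      baseline_avg = baseline_avg,
      improvement_pct = compute_improvement(mean(remaining), baseline_avg),
      n_under_avg = uar$count,
      under_avg_pct = uar$percent)
  }
  structure(list(method = method, selected_ids = ids,
                 n_selected = length(ids), selection = selection,
                 model = model, report = report),
            class = "przn_stage")
}

#' @export
print.przn_stage <- function(x, ...) {
  cat(sprintf("<przn_stage> method %s, %d selected\n",
              x$method, x$n_selected))
  if (!is.null(x$report))
    print(x$report, row.names = FALSE)
  invisible(x)
}

#' Continuous multi-stage selection
#'
#' Runs the stages of a plan in order, removing every bird selected at one
#' stage from the unknown set before the next stage runs (continuous
#' selection). Reporting follows the selection tables' convention: selected
#' counts are cumulative; the average egg number is the mean over the birds
#' never selected so far; the improvement divisor is the original
#' (stage-0) flock mean throughout; the under-average statistics are over
#' the cumulative selected set.
#'
#' @param stages list of stages, each a list with elements `known` (a
#'   `przn_dataset` with validation or a list of them for union mode),
#'   `unknown` (a `przn_dataset` with validation, the same individuals at
#'   every stage) and optionally `label`.
#' @param fraction candidate fraction.
#' @param method `"prezone"`, `"regression"`, or `"both"`. With `"both"`
#'   the regression baseline is paired stage-by-stage to the zone method's
#'   selection size. With `"regression"` alone, `n_select` must give the
#'   per-stage selection sizes.
#' @param n_select integer vector of per-stage selection sizes for a
#'   standalone regression run; ignored otherwise.
#' @return A `data.frame` of class `przn_report`, one row per (method,
#'   stage): `stage`, `method`, `n_selected` (cumulative),
#'   `avg_remaining`, `improvement_pct`, `n_under_avg`, `under_avg_pct`,
#'   with the original flock mean in attribute `baseline_avg` and the
#'   per-stage selected ids in attribute `selections`.
#' @export
run_continuous <- function(stages, fraction = 0.1,
                           method = c("prezone", "regression", "both"),
                           n_select = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(stages), length(stages) >= 1L)
  first <- stages[[1L]]$unknown
  if (is.null(first$validation))
    stop("the unknown flock needs validation (egg counts) to be evaluated")
  ids0 <- first$ids
  eggs0 <- first$validation
  names(eggs0) <- ids0
  for (s in stages)
    if (!setequal(s$unknown$ids, ids0))
      stop("unknown datasets at successive stages must cover the same ",
           "individuals")
  baseline <- mean(eggs0)
  labels <- vapply(seq_along(stages), function(t) {
    lb <- stages[[t]]$label
    if (is.null(lb)) paste0("stage", t) else as.character(lb)
  }, character(1L))
  methods <- if (method == "both") c("prezone", "regression") else method
  if (identical(method, "regression") && is.null(n_select))
    stop("a standalone regression run needs per-stage 'n_select' ",
         "(the zone method's selection sizes)")

  rows <- list()
  selections <- list()
  paired_sizes <- rep(NA_integer_, length(stages))
  for (meth in methods) {
    cum_sel <- character(0)
    for (t in seq_along(stages)) {
      unk <- stages[[t]]$unknown
      unk_t <- unk[setdiff(unk$ids, cum_sel)]
      nsel_t <- if (meth == "regression") {
        if (method == "both") paired_sizes[t] else
          as.integer(rep_len(n_select, length(stages))[t])
      } else NULL
      st <- run_stage(stages[[t]]$known, unk_t, fraction = fraction,
                      method = meth, n_select = nsel_t,
                      baseline_avg = baseline)
      if (meth == "prezone")
        paired_sizes[t] <- st$n_selected
      cum_sel <- c(cum_sel, st$selected_ids)
      remaining <- eggs0[setdiff(ids0, cum_sel)]
      uar <- under_average_rate(eggs0[cum_sel], baseline)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = labels[t],
        method = meth,
        n_selected = length(cum_sel),
        avg_remaining = mean(remaining),
        improvement_pct = compute_improvement(mean(remaining), baseline),
        n_under_avg = uar$count,
        under_avg_pct = uar$percent,
        stringsAsFactors = FALSE)
      selections[[paste(meth, labels[t], sep = ".")]] <- st$selected_ids
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_avg") <- baseline
  attr(out, "selections") <- selections
  class(out) <- c("przn_report", "data.frame")
  out
}

#' @export
print.przn_report <- function(x, ...) {
  cat(sprintf("Continuous selection report (original flock mean %.4g)\n",
              attr(x, "baseline_avg")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
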