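#' Specification of a synthetic flock
#'
#' Describes a flock of laying hens sampled at one or more stages. Defaults
#' mirror a real country-chicken batch: 60 hens, serum panels at 8 and 14
#' weeks with apolipoprotein A-I around 2.75 +/- 0.89 and 2.16 +/- 0.31
#' mg/mL, X protein and apo VLDL-II at their correspondingly small levels,
#' and a flock mean of 85.1 eggs per hen over the laying period. Egg counts
#' get a standard deviation of 20 -- a realistic between-hen spread for a
#' 24-week laying window in a randomly bred flock.
#'
#' Biomarker concentrations are drawn from normals truncated at zero;
#' realized biomarker-egg correlations are constrained to `max_abs_corr` in
#' magnitude by per-variable rejection resampling, emulating panels that
#' carry no usable linear signal. A detectable non-linear signature can be
#' planted: hens in the lowest egg decile have each biomarker mean shifted
#' by `signature_effect` standard deviations.
#'
#' @param n flock size.
#' @param stages named list of per-stage parameter tables, each a
#'   `data.frame` with columns `variable`, `mean`, `sd` (all SDs positive).
#' @param egg_mean,egg_sd moments of the egg-count distribution (rounded
#'   normal clipped at zero).
#' @param max_abs_corr bound on the realized absolute biomarker-egg
#'   correlation, in `[0, 1)`.
#' @param signature_effect shift, in SD units, applied to the biomarker
#'   means of lowest-decile layers; 0 plants nothing. Default 2, the
#'   planted-signature study condition.
#' @param missing_rate probability that a biomarker cell is blanked to
#'   `NA`, in `[0, 1)`.
#' @param seed integer seed making the flock reproducible.
#' @return An object of class `przn_flock_spec` (a validated list of the
#'   above fields).
#' @export
flock_spec <- function(n = 60,
                       stages = list(
                         "8wk" = data.frame(
                           variable = c("apoA1", "Xprotein", "apoVLDL2"),
                           mean = c(2.752, 0.169, 0.026),
                           sd = c(0.894, 0.087, 0.033)),
                         "14wk" = data.frame(
                           variable = c("apoA1", "Xprotein", "apoVLDL2"),
                           mean = c(2.156, 0.416, 0.024),
                           sd = c(0.311, 0.216, 0.031))),
                       egg_mean = 85.1, egg_sd = 20,
                       max_abs_corr = 0.25,
                       signature_effect = 2,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n >= 2, length(stages) >= 1L, egg_mean >= 0, egg_sd > 0,
            max_abs_corr >= 0, max_abs_corr < 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(stages)) || any(!nzchar(names(stages))))
    stop("'stages' must be a named list (stage labels)")
  for (st in stages) {
    stopifnot(is.data.frame(st),
              all(c("variable", "mean", "sd") %in% names(st)))
    if (any(st$sd <= 0))
      stop("all biomarker SDs must be positive")
  }
  structure(list(n = as.integer(n), stages = stages,
                 egg_mean = egg_mean, egg_sd = egg_sd,
                 max_abs_corr = max_abs_corr,
                 signature_effect = signature_effect,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "przn_flock_spec")
}

# Normal truncated at zero via the inverse CDF, one draw per bird; the draw
# count is fixed, keeping flocks reproducible inside rejection loops.
rtrunc0 <- function(n, mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Generate a synthetic flock
#'
#' Draws egg counts once (shared by all stages -- they are the same birds)
#' and one biomarker panel per stage according to a [flock_spec()]. Each
#' biomarker column is redrawn, up to `max_tries` times, until its realized
#' correlation with the egg counts is within the spec's bound; a spec whose
#' bound cannot be met within the budget raises an infeasible-spec error.
#' Identical seeds give identical flocks.
#'
#' @param spec a `przn_flock_spec`.
#' @param seed overrides `spec$seed` when given.
#' @param max_tries rejection-resampling budget per biomarker column.
#' @return List with `stages` (named list of [prezone_dataset()]s, each
#'   carrying the shared egg counts as validation), `eggs` (integer vector)
#'   and `low_decile` (logical, which birds carry the planted signature).
#' @export
generate_flock <- function(spec, seed = spec$seed, max_tries = 200L) {
  stopifnot(inherits(spec, "przn_flock_spec"))
  set.seed(seed)
  n <- spec$n
  eggs <- pmax(0, round(stats::rnorm(n, spec$egg_mean, spec$egg_sd)))
  eggs <- as.integer(eggs)
  low <- rank(eggs, ties.method = "first") <= ceiling(n / 10)
  ids <- sprintf("bird_%03d", seq_len(n))
  check_corr <- stats::sd(eggs) > 0
  stages <- lapply(names(spec$stages), function(lab) {
    st <- spec$stages[[lab]]
    scores <- matrix(0, n, nrow(st),
                     dimnames = list(ids, st$variable))
    for (p in seq_len(nrow(st))) {
      mu <- rep(st$mean[p], n)
      mu[low] <- mu[low] + spec$signature_effect * st$sd[p]
      for (try in seq_len(max_tries)) {
        x <- rtrunc0(n, mu, st$sd[p])
        if (!check_corr || abs(stats::cor(x, eggs)) <= spec$max_abs_corr)
          break
        if (try == max_tries)
          stop("infeasible spec: could not keep |cor(", st$variable[p],
               ", eggs)| <= ", spec$max_abs_corr, " within ", max_tries,
               " redraws")
      }
      scores[, p] <- x
    }
    if (spec$missing_rate > 0)
      scores[stats::runif(length(scores)) < spec$missing_rate] <- NA_real_
    prezone_dataset(scores, ids = ids, stage = lab, validation = eggs)
  })
  names(stages) <- names(spec$stages)
  list(stages = stages, eggs = eggs, low_decile = low)
}
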