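#' Fit the first-order multiple linear regression baseline
#'
#' Ordinary least squares of the validation variable (egg number) on all
#' biomarker variables of the known set, the comparator the zone method is
#' judged against. Reports the intercept, one slope per variable, and the
#' overall F-test p-value of all slopes being zero (per-coefficient tests
#' are not reported).
#'
#' @param known `przn_dataset` with validation and complete scores.
#' @return An object of class `przn_ols`: list with `intercept`,
#'   `coefficients` (named by variable), `overall_p`, `n_fit`,
#'   `variable_names` and the underlying `lm` fit as `fit`.
#' @export
fit_ols <- function(known) {
  stopifnot(inherits(known, "przn_dataset"))
  if (is.null(known$validation))
    stop("the known dataset has no validation variable to regress on")
  n <- length(known$ids)
  m <- length(known$variable_names)
  if (n <= m + 1L)
    stop("need more than m + 1 = ", m + 1L,
         " individuals to fit the regression, got ", n)
  df <- as.data.frame(known$scores)
  df$.egg <- as.numeric(known$validation)
  fit <- stats::lm(.egg ~ ., data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs))
    stop("singular design: collinear biomarker variables (",
         paste(names(coefs)[is.na(coefs)], collapse = ", "), ")")
  fstat <- suppressWarnings(summary(fit))$fstatistic  # quiet on perfect fits
  overall_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  slopes <- coefs[-1L]
  names(slopes) <- known$variable_names
  structure(list(intercept = unname(coefs[1L]),
                 coefficients = slopes,
                 overall_p = overall_p,
                 n_fit = n,
                 variable_names = known$variable_names,
                 fit = fit),
            class = "przn_ols")
}

#' @export
print.przn_ols <- function(x, digits = 3, ...) {
  terms <- sprintf("%s %s*%s",
                   ifelse(x$coefficients < 0, "-", "+"),
                   format(abs(x$coefficients), digits = digits,
                          trim = TRUE),
                   x$variable_names)
  cat("egg =", format(x$intercept, digits = digits),
      paste(terms, collapse = " "), "\n")
  cat(sprintf("n = %d, overall F-test P-value = %s\n",
              x$n_fit, format(x$overall_p, digits = digits)))
  invisible(x)
}

#' Predict egg numbers for an unknown dataset
#'
#' Applies the fitted linear equation: intercept plus the dot product of the
#' slopes with each individual's biomarker scores. The unknown set must
#' carry the same variables, in the same order, as the fitting set.
#'
#' @param model a `przn_ols` from [fit_ols()].
#' @param unknown `przn_dataset` with complete scores.
#' @return Named numeric vector of predictions, one per unknown individual.
#' @export
predict_eggs <- function(model, unknown) {
  stopifnot(inherits(model, "przn_ols"), inherits(unknown, "przn_dataset"))
  if (!identical(unknown$variable_names, model$variable_names))
    stop("unknown set variables do not match the fitted model (",
         paste(model$variable_names, collapse = ", "), ")")
  drop(model$intercept + unknown$scores %*% model$coefficients)
}

#' Select the individuals with the lowest predicted values
#'
#' Exactly `count` ids are returned (the regression baseline is paired to
#' the zone method's selection size); boundary ties are broken by input
#' order.
#'
#' @param predictions named numeric vector (names are individual ids).
#' @param count number to select, `1 <= count <= length(predictions)`.
#' @return Character vector of `count` ids, ascending by predicted value.
#' @export
select_lowest <- function(predictions, count) {
  n <- length(predictions)
  if (count < 1L || count > n)
    stop("'count' must lie in 1..", n)
  ids <- names(predictions)
  if (is.null(ids))
    ids <- as.character(seq_len(n))
  ids[order(predictions, seq_len(n))[seq_len(count)]]
}
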