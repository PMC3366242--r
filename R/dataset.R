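#' Construct a biomarker dataset
#'
#' A dataset holds one batch of individuals sampled at one stage: a numeric
#' score matrix (individuals x biomarker variables, e.g. serum concentrations
#' of apolipoprotein A-I, X protein, apo VLDL-II and vitellogenin) plus an
#' optional validation variable -- here, the total egg number per hen over the
#' laying period -- used both to pick low-performing templates in a known
#' cohort and to evaluate a selection afterwards.
#'
#' @param scores numeric matrix, one row per individual and one column per
#'   biomarker variable. `NA` marks a missing record; every non-missing entry
#'   must be finite.
#' @param ids character vector of unique individual labels; defaults to the
#'   row names of `scores` (or `obj1`, `obj2`, ... when absent).
#' @param variable_names character vector of variable labels; defaults to the
#'   column names of `scores`.
#' @param stage free-text sampling-stage label, e.g. `"14wk"`.
#' @param validation optional vector of non-negative whole-number counts, one
#'   per individual (total eggs laid).
#' @return An object of class `przn_dataset`: a list with elements `ids`,
#'   `scores` (matrix with `ids`/`variable_names` as dimnames),
#'   `variable_names`, `stage` and `validation` (integer or `NULL`).
#' @examples
#' x <- matrix(c(1.2, 2.1, 0.7, 0.41, 0.95, 0.33), nrow = 3,
#'             dimnames = list(c("b1", "b2", "b3"), c("apoA1", "Xprotein")))
#' d <- prezone_dataset(x, stage = "14wk", validation = c(90, 101, 84))
#' summarize_dataset(d)
#' @seealso [read_dataset()], [summarize_dataset()]
#' @export
prezone_dataset <- function(scores, ids = rownames(scores),
                            variable_names = colnames(scores),
                            stage = "", validation = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores)
  m <- ncol(scores)
  if (n < 2L)
    stop("a dataset needs at least 2 individuals, got ", n)
  if (m < 1L)
    stop("a dataset needs at least 1 variable")
  if (is.null(ids))
    ids <- paste0("obj", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n)
    stop("'ids' needs one label per row of 'scores'")
  if (anyDuplicated(ids))
    stop("duplicated individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(variable_names))
    variable_names <- paste0("x", seq_len(m))
  variable_names <- as.character(variable_names)
  if (length(variable_names) != m)
    stop("'variable_names' needs one label per column of 'scores'")
  if (any(is.nan(scores)) || any(is.infinite(scores)))
    stop("scores must be finite where present (NA marks a missing record)")
  if (!is.null(validation)) {
    if (length(validation) != n)
      stop("validation needs one value per individual")
    if (anyNA(validation))
      stop("validation must be complete (no NA)")
    if (any(validation < 0))
      stop("validation counts must be non-negative")
    if (any(abs(validation - round(validation)) > 1e-8))
      stop("validation counts must be whole numbers")
    validation <- as.integer(round(validation))
  }
  dimnames(scores) <- list(ids, variable_names)
  structure(list(ids = ids, scores = scores,
                 variable_names = variable_names,
                 stage = stage, validation = validation),
            class = "przn_dataset")
}

#' @export
print.przn_dataset <- function(x, ...) {
  cat(sprintf("<przn_dataset> %d individuals x %d variables%s%s\n",
              length(x$ids), length(x$variable_names),
              if (nzchar(x$stage)) paste0(", stage ", x$stage) else "",
              if (!is.null(x$validation)) ", with validation" else ""))
  cat("  variables:", paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset by individuals
#'
#' @param x a `przn_dataset`.
#' @param i integer or logical index, or character ids.
#' @param ... ignored.
#' @return A `przn_dataset` with the selected individuals (at least 2 must
#'   remain).
#' @export
`[.przn_dataset` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$ids)
    if (anyNA(idx))
      stop("unknown ids: ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  prezone_dataset(x$scores[i, , drop = FALSE],
                  ids = x$ids[i],
                  variable_names = x$variable_names,
                  stage = x$stage,
                  validation = if (!is.null(x$validation)) x$validation[i])
}

#' Read a delimited biomarker table
#'
#' Reads a CSV/TSV with the individual id in the first column, a header row of
#' variable names, and optionally one validation column (egg counts). Empty
#' cells (or literal `NA`) mark missing records; how they are handled is set
#' by `missing`: with `"drop_object"` every individual with any missing
#' biomarker or validation cell is removed (and reported via a message naming
#' the dropped ids), with `"error"` any missing cell aborts.
#'
#' @param path path to the file. Field separator defaults to tab for
#'   `.tsv`/`.txt`, comma otherwise; override with `sep`.
#' @param validation_column name of the validation (egg-count) column, or
#'   `NULL` when the file has none.
#' @param missing missing-record policy, `"drop_object"` (default) or
#'   `"error"`.
#' @param sep field separator; `NULL` to infer from the file extension.
#' @param stage stage label stored on the dataset.
#' @return A [prezone_dataset()].
#' @export
read_dataset <- function(path, validation_column = NULL,
                         missing = c("drop_object", "error"),
                         sep = NULL, stage = "") {
  missing <- match.arg(missing)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("", "NA"), comment.char = "")
  if (ncol(raw) < 2L)
    stop("expected an id column plus at least one variable column in ", path)
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]

  parse_col <- function(chr, colname) {
    num <- suppressWarnings(as.numeric(chr))
    bad <- which(!is.na(chr) & is.na(num))
    if (length(bad))
      stop(sprintf("cannot parse '%s' as a number (row %d, column '%s')",
                   chr[bad[1L]], bad[1L], colname))
    num
  }

  validation <- NULL
  if (!is.null(validation_column)) {
    if (!validation_column %in% names(body))
      stop("validation column '", validation_column, "' not found in ", path)
    validation <- parse_col(body[[validation_column]], validation_column)
    body <- body[, setdiff(names(body), validation_column), drop = FALSE]
    if (ncol(body) < 1L)
      stop("no biomarker columns left after removing the validation column")
  }
  scores <- do.call(cbind, lapply(names(body),
                                  function(cl) parse_col(body[[cl]], cl)))
  colnames(scores) <- names(body)

  incomplete <- apply(is.na(scores), 1L, any)
  if (!is.null(validation))
    incomplete <- incomplete | is.na(validation)
  if (any(incomplete)) {
    if (missing == "error")
      stop("missing cells for: ", paste(ids[incomplete], collapse = ", "))
    message("read_dataset: dropping ", sum(incomplete),
            " incomplete individual(s): ",
            paste(ids[incomplete], collapse = ", "))
    keep <- !incomplete
    ids <- ids[keep]
    scores <- scores[keep, , drop = FALSE]
    if (!is.null(validation))
      validation <- validation[keep]
  }
  if (nrow(scores) < 2L)
    stop("fewer than 2 complete individuals remain in ", path)
  prezone_dataset(scores, ids = ids, stage = stage, validation = validation)
}

#' Write a dataset back to a delimited table
#'
#' Inverse of [read_dataset()]: first column `id`, then the validation column
#' (when present, under `name` `"eggs"` unless overridden), then the biomarker
#' columns. Numeric values are written with full double precision so that a
#' read -> write -> read round trip preserves them.
#'
#' @param d a `przn_dataset`.
#' @param path output path; separator inferred from the extension as in
#'   [read_dataset()] unless `sep` is given.
#' @param validation_name column name for the validation variable.
#' @param sep field separator, `NULL` to infer.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, validation_name = "eggs", sep = NULL) {
  stopifnot(inherits(d, "przn_dataset"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- data.frame(id = d$ids, stringsAsFactors = FALSE)
  if (!is.null(d$validation))
    out[[validation_name]] <- d$validation
  for (p in seq_along(d$variable_names))
    out[[d$variable_names[p]]] <-
      vapply(d$scores[, p], function(v)
        if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE),
        character(1L))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Per-variable mean and standard deviation
#'
#' Sample moments of each biomarker variable, in input column order. The
#' standard deviation uses the sample (n-1) convention -- the same convention
#' the rank/score transfer uses, so the two stay consistent. Missing records
#' are excluded variable-wise.
#'
#' @param d a `przn_dataset`.
#' @return A `data.frame` with columns `variable`, `mean`, `sd`.
#' @export
summarize_dataset <- function(d) {
  stopifnot(inherits(d, "przn_dataset"))
  data.frame(variable = d$variable_names,
             mean = apply(d$scores, 2L, mean, na.rm = TRUE),
             sd = apply(d$scores, 2L, stats::sd, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concatenate known batches into one union dataset
#'
#' Union-mode selection pools two (or more) known batches into a single known
#' set before candidate extraction, ranking and zoning. Individual ids are
#' kept as-is when globally unique, otherwise prefixed with the batch label
#' (list name or running number) to disambiguate. All batches must share the
#' same variables, in the same order, and either all or none may carry a
#' validation variable.
#'
#' @param datasets list of `przn_dataset` objects.
#' @return A single `przn_dataset`.
#' @export
dataset_union <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (length(datasets) == 1L)
    return(datasets[[1L]])
  vn <- datasets[[1L]]$variable_names
  for (d in datasets) {
    stopifnot(inherits(d, "przn_dataset"))
    if (!identical(d$variable_names, vn))
      stop("all batches in a union must share the same variables")
  }
  has_val <- vapply(datasets, function(d) !is.null(d$validation), logical(1L))
  if (any(has_val) && !all(has_val))
    stop("either all or none of the union batches may carry validation")
  labels <- names(datasets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- paste0("batch", seq_along(datasets))
  ids <- unlist(lapply(datasets, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(ids))
    ids <- unlist(mapply(function(d, lb) paste0(lb, ":", d$ids),
                         datasets, labels, SIMPLIFY = FALSE),
                  use.names = FALSE)
  prezone_dataset(do.call(rbind, lapply(datasets, `[[`, "scores")),
                  ids = ids,
                  variable_names = vn,
                  stage = datasets[[1L]]$stage,
                  validation = if (all(has_val))
                    unlist(lapply(datasets, `[[`, "validation"),
                           use.names = FALSE))
}
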