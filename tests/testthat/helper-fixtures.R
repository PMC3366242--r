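# Small builders shared across test files.

make_ds <- function(scores, eggs = NULL, stage = "", ids = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("v", seq_len(ncol(scores)))
  prezone_dataset(scores, ids = ids, stage = stage, validation = eggs)
}

# A random (unknown, known) pair small enough for the brute-force oracles.
# Scores are rounded to 2 decimals so that ties occur and exercise the
# stable tie-breaks; egg counts are distinct so the candidate count is
# exactly the requested cn.
random_instance <- function(seed, max_n_a = 12L, max_m = 3L, max_cn = 4L) {
  set.seed(seed)
  m <- sample.int(max_m, 1L)
  n_a <- sample(4:max_n_a, 1L)
  n_b <- sample(4:(max_n_a + 2L), 1L)
  cn <- sample.int(min(max_cn, n_b), 1L)
  vn <- paste0("v", seq_len(m))
  a <- prezone_dataset(
    matrix(round(stats::runif(n_a * m), 2), n_a, m,
           dimnames = list(NULL, vn)))
  b <- prezone_dataset(
    matrix(round(stats::runif(n_b * m), 2), n_b, m,
           dimnames = list(NULL, vn)),
    validation = sample.int(1000L, n_b))
  list(a = a, b = b, fraction = (cn - 0.5) / n_b, cn = cn)
}

# A known dataset with continuous (almost surely distinct) scores and
# distinct egg counts, for self-prediction checks.
random_known <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:30, 1L)
  if (is.null(m)) m <- sample.int(3L, 1L)
  prezone_dataset(
    matrix(stats::runif(n * m), n, m,
           dimnames = list(NULL, paste0("v", seq_len(m)))),
    validation = sample.int(500L, n))
}

strip_validation <- function(d) {
  prezone_dataset(d$scores, ids = d$ids, stage = d$stage)
}
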