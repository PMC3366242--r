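test_that("improvement and under-average metrics follow half-up rounding", {
  expect_equal(compute_improvement(97.172, 94.57), 2.8)
  expect_equal(compute_improvement(85.1, 85.1), 0)
  expect_equal(compute_improvement(89.9, 85.1), 5.6)
  expect_equal(compute_improvement(94.375, 94.57), -0.2)
  expect_error(compute_improvement(90, 0), "positive")

  expect_identical(under_average_rate(c(80, 80, 90), 85)$count, 2L)
  r <- under_average_rate(c(rep(80, 17), rep(99, 8)), 94.57)
  expect_identical(r$count, 17L)
  expect_identical(r$percent, 68L)
  expect_identical(under_average_rate(c(90, 91), 85)$percent, 0L)
  expect_error(under_average_rate(numeric(0), 85), "empty")
})

test_that("removing only under-average birds strictly improves the flock mean", {
  set.seed(20)
  for (s in 1:15) {
    eggs <- sample(50:130, 30, replace = TRUE)
    base <- mean(eggs)
    under <- which(eggs < base)
    cut <- sample(under, sample(1:5, 1))
    expect_gt(mean(eggs[-cut]), base)
    expect_gte(compute_improvement(mean(eggs[-cut]), base), 0)
  }
})

test_that("a stage run pairs the regression size to the zone selection", {
  set.seed(101)
  known <- generate_flock(flock_spec(n = 40, seed = 101))$stages[["14wk"]]
  unknown <- generate_flock(flock_spec(n = 35, seed = 202))$stages[["14wk"]]
  pz <- run_stage(known, unknown, method = "prezone")
  rg <- run_stage(known, unknown, method = "regression")
  expect_identical(rg$n_selected, pz$n_selected)
  expect_identical(rg$report$n_selected, pz$report$n_selected)
  expect_s3_class(rg$model, "przn_ols")
  expect_identical(pz$report$baseline_avg, mean(unknown$validation))
})

test_that("self-prediction through run_stage selects every candidate", {
  b <- random_known(77, n = 25, m = 2)
  st <- run_stage(b, strip_validation(b), method = "prezone")
  expect_true(all(st$selection$candidates$ids %in% st$selected_ids))
  expect_null(st$report)  # no validation on the unknown set
})

test_that("a union of two identical known batches keeps the candidate membership", {
  b <- make_ds(matrix(runif(12), 6, 2), eggs = c(40, 10, 30, 20, 60, 50),
               ids = paste0("k", 1:6))
  single <- select_validation_candidates(b, 0.5)
  un <- dataset_union(list(one = b, two = b))
  both <- select_validation_candidates(un, 0.5)
  expect_identical(both$cn, 2L * single$cn)
  expect_setequal(sub("^(one|two):", "", both$ids),
                  single$ids)
})

test_that("continuous selection removes selected birds and reports cumulatively", {
  # regression route with forced sizes: hand-checkable trimmed means
  set.seed(55)
  eggs <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  x <- matrix(c(eggs / 10, runif(10)), 10, 2,
              dimnames = list(NULL, c("sig", "noise")))
  unknown <- make_ds(x, eggs = eggs, ids = paste0("u", 1:10))
  known <- make_ds(matrix(c(1:12 / 2, runif(12)), 12, 2,
                          dimnames = list(NULL, c("sig", "noise"))),
                   eggs = round(1:12 * 8), ids = paste0("k", 1:12))
  stages <- list(list(known = known, unknown = unknown, label = "s1"),
                 list(known = known, unknown = unknown, label = "s2"))
  rep <- run_continuous(stages, method = "regression", n_select = c(3, 2))
  expect_identical(rep$n_selected, c(3L, 5L))
  # predictions are monotone in the signal column, so the 3 then next 2
  # lowest-egg birds go: remaining means are closed-form trimmed means
  expect_equal(rep$avg_remaining, c(mean(eggs[4:10]), mean(eggs[6:10])))
  expect_equal(rep$improvement_pct,
               compute_improvement(c(mean(eggs[4:10]), mean(eggs[6:10])),
                                   mean(eggs)))
  expect_identical(rep$n_under_avg, c(3L, 5L))
  expect_identical(rep$under_avg_pct, c(100L, 100L))
  sels <- attr(rep, "selections")
  expect_identical(sort(unique(unlist(sels))), paste0("u", 1:5))
  expect_error(run_continuous(stages, method = "regression"), "n_select")
})

test_that("a three-stage zone run is cumulative, partitioned and deterministic", {
  spec_known <- flock_spec(n = 40, stages = flock_spec()$stages[1],
                           seed = 7)
  spec_unknown <- flock_spec(n = 36, stages = flock_spec()$stages[1],
                             seed = 8)
  known <- generate_flock(spec_known)$stages[[1]]
  unknown <- generate_flock(spec_unknown)$stages[[1]]
  stages <- lapply(1:3, function(t)
    list(known = known, unknown = unknown, label = paste0("t", t)))
  r1 <- run_continuous(stages, method = "prezone")
  r2 <- run_continuous(stages, method = "prezone")
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$n_selected))
  sels <- attr(r1, "selections")
  all_sel <- unique(unlist(sels))
  expect_identical(anyDuplicated(unlist(sels)), 0L)
  expect_identical(r1$n_selected[3], length(all_sel))
  expect_identical(length(setdiff(unknown$ids, all_sel)) + length(all_sel),
                   length(unknown$ids))

  mismatched <- stages
  mismatched[[2]]$unknown <- unknown[1:20]
  expect_error(run_continuous(mismatched, method = "prezone"),
               "same\\s+individuals")
})
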