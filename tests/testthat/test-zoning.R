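test_that("candidate regions follow the rank and score pointers", {
  xs <- c(1, 2, 3, 4)
  rs <- c(1, 2, 3, 4)
  # rank pointer at 1, score pointer right of position 3: rightward stretch
  expect_identical(find_candidate_region(xs, rs, bx = 3.5, bs = 1),
                   list(lo = 1L, hi = 4L))
  # rank pointer at 3, score pointer left of position 2: leftward stretch
  # down to the last position at or below the candidate score
  expect_identical(find_candidate_region(xs, rs, bx = 1.5, bs = 3),
                   list(lo = 1L, hi = 4L))
  # both pointers beyond the top object clamp to the top position
  expect_identical(find_candidate_region(xs, rs, bx = 9, bs = 9),
                   list(lo = 4L, hi = 4L))
  # both pointers below the bottom object clamp to position 1
  expect_identical(find_candidate_region(xs, rs, bx = 0.5, bs = 0.5),
                   list(lo = 1L, hi = 1L))
  # candidate score strictly between adjacent scores: degenerate stretch
  expect_identical(find_candidate_region(xs, rs, bx = 2.5, bs = 2),
                   list(lo = 2L, hi = 3L))
  expect_error(find_candidate_region(numeric(0), numeric(0), 1, 1),
               "empty")
})

test_that("zone numbering merges overlaps and numbers gaps as zones", {
  r <- function(lo, hi) list(lo = lo, hi = hi)
  one <- assign_zone_numbers(list(r(1, 3)), 3)
  expect_identical(one$labels, rep(1L, 3))
  expect_identical(one$candidate_label, 1L)

  gap <- assign_zone_numbers(list(r(1, 2), r(5, 6)), 6)
  expect_identical(gap$labels, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(gap$candidate_label, c(1L, 3L))

  merged <- assign_zone_numbers(list(r(1, 3), r(3, 5)), 6)
  expect_identical(merged$labels, c(1L, 1L, 1L, 1L, 1L, 2L))
  expect_identical(merged$candidate_label, c(1L, 1L))

  # adjacency without a shared position does not merge
  adj <- assign_zone_numbers(list(r(1, 2), r(3, 4)), 4)
  expect_identical(adj$labels, c(1L, 1L, 2L, 2L))
  expect_identical(adj$candidate_label, c(1L, 2L))

  # terminal uncovered stretches are runs of their own
  term <- assign_zone_numbers(list(r(3, 4)), 6)
  expect_identical(term$labels, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(assign_zone_numbers(list(r(0, 2)), 4), "1 <= lo")
})

test_that("zone labels are contiguous runs numbered left to right", {
  for (s in 1:60) {
    inst <- random_instance(s)
    cs <- select_validation_candidates(inst$b, inst$fraction)
    tt <- transfer_table(inst$a, inst$b)
    zt <- build_zone_table(tt, cs)
    for (p in seq_along(inst$a$variable_names)) {
      lab <- unname(zt$a_zones[order(tt$t_scores[, p]), p])
      expect_identical(lab[1], 1L)
      expect_true(all(diff(lab) %in% c(0L, 1L)))
    }
    expect_true(all(zt$b_zones >= 1))
  }
})

test_that("zoning ignores object input order when scores are untied", {
  set.seed(99)
  a <- make_ds(matrix(runif(14), 7, 2), ids = paste0("u", 1:7))
  b <- make_ds(matrix(runif(12), 6, 2), eggs = sample(100, 6))
  cs <- select_validation_candidates(b, 0.4)
  z1 <- build_zone_table(transfer_table(a, b), cs)
  perm <- sample(7)
  z2 <- build_zone_table(transfer_table(a[perm], b), cs)
  expect_identical(z2$a_zones[a$ids[perm], ], z1$a_zones[a$ids[perm], ])
  expect_identical(z2$b_zones, z1$b_zones)
})

test_that("candidate processing order does not change the zone table", {
  for (s in 1:30) {
    inst <- random_instance(s)
    cs <- select_validation_candidates(inst$b, inst$fraction)
    if (cs$cn < 2) next
    tt <- transfer_table(inst$a, inst$b)
    z1 <- build_zone_table(tt, cs)
    rev_cs <- cs
    flip <- rev(seq_len(cs$cn))
    rev_cs$ids <- cs$ids[flip]
    rev_cs$scores <- cs$scores[flip, , drop = FALSE]
    rev_cs$ranks <- cs$ranks[flip, , drop = FALSE]
    rev_cs$validation <- cs$validation[flip]
    z2 <- build_zone_table(tt, rev_cs)
    expect_identical(z2$a_zones, z1$a_zones)
    expect_identical(unname(z2$b_zones[flip, , drop = FALSE]),
                     unname(z1$b_zones))
  }
})

test_that("a single candidate on one variable yields at most three zones", {
  set.seed(5)
  a <- make_ds(matrix(runif(9), 9, 1))
  b <- make_ds(matrix(runif(8), 8, 1), eggs = sample(50, 8))
  cs <- select_validation_candidates(b, 0.1)
  expect_identical(cs$cn, 1L)
  zt <- build_zone_table(transfer_table(a, b), cs)
  expect_lte(length(unique(zt$a_zones[, 1])), 3L)
})

test_that("with an identity transfer each candidate lands in its own zone", {
  for (s in c(3, 17, 29)) {
    b <- random_known(s, n = 6, m = 2)
    cs <- select_validation_candidates(b, 0.5)
    tt <- transfer_table(strip_validation(b), b)
    zt <- build_zone_table(tt, cs)
    for (ej in seq_len(cs$cn))
      expect_identical(unname(zt$a_zones[cs$ids[ej], ]),
                       unname(zt$b_zones[ej, ]))
  }
})

test_that("zoning matches the brute-force transcription on random instances", {
  for (s in 1:200) {
    inst <- random_instance(s)
    cs <- select_validation_candidates(inst$b, inst$fraction)
    tt <- transfer_table(inst$a, inst$b)
    zt <- build_zone_table(tt, cs)
    oz <- oracle_zones(tt, cs)
    expect_identical(unname(zt$a_zones), oz$a_zones)
    expect_identical(unname(zt$b_zones), oz$b_zones)
  }
})

test_that("the zone map exposes positions, scores, ranks and zones", {
  set.seed(1)
  a <- make_ds(matrix(runif(10), 5, 2))
  b <- make_ds(matrix(runif(10), 5, 2), eggs = sample(50, 5))
  tt <- transfer_table(a, b)
  zt <- build_zone_table(tt, select_validation_candidates(b, 0.2))
  zm <- zone_map(tt, zt, "v1")
  expect_identical(names(zm),
                   c("position", "object_id", "t_score", "t_rank", "zone"))
  expect_false(is.unsorted(zm$t_score))
  expect_identical(zm$zone, unname(zt$a_zones[zm$object_id, 1L]))
})
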