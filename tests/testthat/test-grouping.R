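test_that("counter updates follow the record taxonomy", {
  k3 <- new_group(3)
  g <- update_group(k3, make_super(1, "M", 50, is_new = TRUE, is_md = TRUE,
                                   is_ss = TRUE))
  expect_equal(g$msavr, rep(1L, 4))
  expect_equal(g$n, rep(3L, 4))  # position already reserved
  g <- update_group(k3, make_super(1, "M", 50, is_new = TRUE, is_md = TRUE,
                                   is_ss = TRUE), remaining = TRUE)
  expect_equal(g$n, rep(4L, 4))  # leftover additions grow the denominators
  g <- update_group(k3, make_super(1, "M", 50, is_new = TRUE, is_md = FALSE,
                                   is_ss = TRUE))
  expect_equal(g$msavr, c(0L, 1L, 0L, 1L))
  expect_equal(g$n, c(3L, 4L, 3L, 4L))
  g <- update_group(k3, make_super(1, "M", 50, is_new = FALSE, is_md = TRUE,
                                   is_ss = TRUE))
  expect_equal(g$msavr, c(0L, 0L, 1L, 1L))
  expect_equal(g$n, c(3L, 3L, 4L, 4L))
  g <- update_group(k3, make_super(1, "M", 50, is_new = FALSE, is_md = FALSE,
                                   is_ss = FALSE))
  expect_equal(g$msavr, rep(0L, 4))
  expect_equal(g$n, rep(3L, 4))
})

test_that("the substantial-symptoms screen compares counter ratios to alpha", {
  g <- new_group(3)
  ss_seed <- make_super(1, "M", 50, is_ss = TRUE)
  expect_false(judge_alpha(g, ss_seed, alpha = 1/4))  # 1/3 > 1/4
  expect_true(judge_alpha(g, ss_seed, alpha = 1/3))
  expect_true(judge_alpha(g, ss_seed, alpha = 1))
  expect_true(judge_alpha(g, make_super(2, "M", 50, is_ss = FALSE), alpha = 1/4))
  # as a leftover the same record fits exactly at 1/4
  expect_true(judge_alpha(g, ss_seed, alpha = 1/4, remaining = TRUE))
})

test_that("grouping the toy quarter 2 yields a full clean partition", {
  raw <- toy_quarters()
  led <- update_ledger(new_ledger(toy_sch),
                       merge_super_records(raw[[1]], toy_sch), 1L, toy_sch)
  sr <- merge_super_records(raw[[2]], toy_sch) |>
    tag_history(led) |>
    tag_md(unique(raw[[3]]$CaseID)) |>
    classify_ss(toy_sch) |>
    ear_cover(led, toy_sch)
  set.seed(11)
  parts <- build_groups(sr, toy_sch, k = 3, theta = 1/3, alpha = 1/4)
  expect_gt(length(parts$groups), 0L)
  # every record lands in exactly one group or the suppressed set
  placed <- c(unlist(lapply(parts$groups, function(g) g$members$CaseID)),
              parts$suppressed$CaseID)
  expect_setequal(placed, sr$CaseID)
  expect_equal(length(placed), nrow(sr))
  for (g in parts$groups) {
    expect_gte(sum(g$members$is_new & g$members$is_md), 3L)
  }
})

test_that("an unreachable k suppresses everything with a warning", {
  # against the quarter-1 history, quarter 2 holds 10 new-and-discontinuing
  # records, so k = 11 can never be met
  led <- update_ledger(new_ledger(toy_sch),
                       merge_super_records(toy_quarters()[[1]], toy_sch),
                       1L, toy_sch)
  sr <- classify_ss(merge_super_records(toy_quarters()[[2]], toy_sch), toy_sch) |>
    tag_history(led) |>
    tag_md(unique(toy_quarters()[[3]]$CaseID))
  expect_equal(sum(sr$is_new & sr$is_md), 10L)
  set.seed(1)
  expect_warning(parts <- build_groups(sr, toy_sch, k = 11), "suppressed")
  expect_length(parts$groups, 0L)
  expect_equal(nrow(parts$suppressed), nrow(sr))
})

test_that("identical input and seed give identical releases", {
  raw <- toy_quarters()
  a <- anonymize_series(raw, toy_sch, k = 3, seed = 5)
  b <- anonymize_series(raw, toy_sch, k = 3, seed = 5)
  expect_identical(a$releases, b$releases)
})

test_that("published tuples cover the raw values they stand for", {
  raw <- toy_quarters()
  fit <- anonymize_series(raw, toy_sch, k = 3, seed = 3)
  for (q in 1:3) {
    rel <- fit$releases[[q]]
    for (i in seq_len(nrow(rel))) {
      r <- raw[[q]][raw[[q]]$CaseID == rel$CaseID[i], ]
      for (j in seq_len(nrow(r))) {
        expect_true(qia_covers(as.list(rel[i, c("Sex", "Age")]),
                               list(Sex = r$Sex[j], Age = r$Age[j]), toy_sch))
      }
    }
  }
  # returning cases additionally cover their earliest published raw values
  rel3 <- fit$releases[[3]]
  for (id in intersect(c(13L, 15L), rel3$CaseID)) {
    if (id %in% fit$releases[[2]]$CaseID) {
      r2 <- raw[[2]][raw[[2]]$CaseID == id, ]
      i <- which(rel3$CaseID == id)
      expect_true(qia_covers(as.list(rel3[i, c("Sex", "Age")]),
                             list(Sex = r2$Sex[1], Age = r2$Age[1]), toy_sch))
    }
  }
})

test_that("fast grouping core agrees with the reference operations", {
  sim <- generate_cohort(cohort_spec(), seed = 8)
  fit <- anonymize_series(sim$quarters, sim$schema, k = 3, seed = 8)
  for (q in seq_along(fit$groups)) {
    for (g in fit$groups[[q]]) {
      ref <- new_group(3)
      for (i in seq_len(nrow(g$members))) {
        rec <- g$members[i, ]
        if (g$remaining[i]) {
          # leftover admissions passed the screen at admission time
          expect_true(judge_alpha(ref, rec, alpha = 1/4, remaining = TRUE))
        }
        ref <- update_group(ref, rec, remaining = g$remaining[i])
      }
      expect_identical(ref$msavr, g$msavr)
      expect_identical(ref$n, g$n)
    }
  }
})

test_that("the baseline mode reproduces the discontinuation vulnerability", {
  raw <- toy_quarters()
  fit <- anonymize_series(raw, toy_sch, k = 3, mode = "legacy", seed = 42)
  aud <- audit_series(raw, fit$releases, toy_sch)
  expect_gt(aud$overall$DIR, 0)
})
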