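test_that("the per-value cap floors the view size times the threshold", {
  expect_equal(eta(4, 1/3), 1L)
  expect_equal(eta(3, 1/3), 1L)
  expect_equal(eta(5, 0.5), 2L)
  # during grouping the in-progress view is padded up to the reserved k
  expect_equal(eta(1, 1/3, k = 3), 1L)
  expect_equal(eta(0, 1/3, k = 3), 1L)
})

test_that("per-value risk follows the capped harmonic form", {
  expect_equal(pr_value(1, 1), 1)
  expect_equal(pr_value(2, 1), Inf)
  expect_equal(pr_value(1, 3), 1/3)
  expect_equal(pr_value(0, 2), 0)
  # nondecreasing in sigma, nonincreasing in eta
  for (e in 1:4) expect_true(all(diff(pr_value(0:e, e)) > 0))
  expect_true(all(diff(pr_value(2, 2:6)) < 0))
})

test_that("record risk sums per-value risks on the hypothetical union", {
  g <- new_group(3)
  # theta = 2/3, k = 3: cap 2 -> a fresh two-code record scores 1 + 1/2 + 1/2
  cand <- make_super(5, "M", 50, adr = c("a", "b"))
  expect_equal(privacy_risk(g, cand, theta = 2/3, schema = toy_sch), 2)
  # an empty sensitive set is the empty sum
  none <- make_super(6, "M", 50, adr = character(0))
  expect_equal(privacy_risk(g, none, theta = 1/3, schema = toy_sch), 1)
  # exceeding a cap is an infinite risk
  g2 <- update_group(g, make_super(1, "M", 50, adr = "a"))
  expect_equal(privacy_risk(g2, cand, theta = 1/3, schema = toy_sch), Inf)
})

test_that("information-loss increments follow the certainty-penalty oracle", {
  il_oracle <- function(ages, sexes) {
    length(ages) * ((max(ages) - min(ages)) / 100 +
                      as.numeric(length(unique(sexes)) > 1))
  }
  g <- new_group(3)
  single <- make_super(1, "M", 47)
  expect_equal(delta_il(g, single, toy_sch), 0)  # degenerate spans cost nothing

  g3 <- Reduce(update_group, list(make_super(1, "M", 46), make_super(2, "M", 48),
                                  make_super(3, "M", 50)), init = new_group(3))
  expect_equal(delta_il(g3, make_super(4, "M", 47), toy_sch),
               il_oracle(c(46, 48, 50, 47), "M") - il_oracle(c(46, 48, 50), "M"))
  expect_equal(delta_il(g3, make_super(4, "M", 47), toy_sch), 0.04)
  # an opposite-sex record flips the categorical penalty from 0 to 1
  expect_equal(delta_il(g3, make_super(4, "F", 48), toy_sch),
               il_oracle(c(46, 48, 50, 48), c("M", "F")) - il_oracle(c(46, 48, 50), "M"))
  expect_true(delta_il(g3, make_super(4, "F", 48), toy_sch) >= 4)
})

test_that("the admission score multiplies loss by risk", {
  g3 <- Reduce(update_group, list(make_super(1, "M", 46, adr = "a"),
                                  make_super(2, "M", 48, adr = "b"),
                                  make_super(3, "M", 50, adr = "c")),
               init = new_group(3))
  cand <- make_super(4, "M", 47, adr = "d")
  expect_equal(delta_pril(g3, cand, theta = 1/3, schema = toy_sch),
               delta_il(g3, cand, toy_sch) *
                 privacy_risk(g3, cand, theta = 1/3, schema = toy_sch))
  # infinite risk dominates any loss
  dup <- make_super(4, "M", 47, adr = "a")
  expect_equal(delta_pril(g3, dup, theta = 1/3, schema = toy_sch), Inf)
  # an in-span admission still pays the newcomer's own span penalty
  same <- make_super(4, "M", 48, adr = "d")
  expect_equal(delta_pril(g3, same, theta = 1/3, schema = toy_sch), 0.04 * 2)
  # zero widening with finite risk scores zero (degenerate spans throughout)
  gd <- Reduce(update_group, list(make_super(1, "M", 48, adr = "a"),
                                  make_super(2, "M", 48, adr = "b")),
               init = new_group(3))
  expect_equal(delta_pril(gd, make_super(3, "M", 48, adr = "c"),
                          theta = 1/3, schema = toy_sch), 0)
})

test_that("seed distance normalizes midpoints and counts category mismatches", {
  a <- make_super(1, "M", 46)
  expect_equal(qia_distance(a, a, toy_sch), 0)
  expect_equal(qia_distance(a, make_super(2, "F", 46), toy_sch), 1)
  expect_equal(qia_distance(make_super(1, "M", 40), make_super(2, "M", 50), toy_sch),
               0.1)
})

test_that("earliest-appearance cover widens old records only, idempotently", {
  led <- update_ledger(new_ledger(toy_sch), make_super(13, "F", 39), 2L, toy_sch)
  old <- make_super(13, "F", 40, is_new = FALSE)
  cov <- ear_cover(old, led, toy_sch)
  expect_equal(c(cov$Age_lo, cov$Age_hi), c(39, 40))
  expect_identical(ear_cover(cov, led, toy_sch), cov)
  # n-records and already-consistent o-records are untouched
  new_rec <- make_super(99, "F", 50, is_new = TRUE)
  expect_identical(ear_cover(new_rec, led, toy_sch), new_rec)
  same <- make_super(13, "F", 39, is_new = FALSE)
  expect_equal(ear_cover(same, led, toy_sch)$Age_hi, 39)
  # an o-record the ledger has never seen is an error
  stray <- make_super(77, "F", 39, is_new = FALSE)
  expect_error(ear_cover(stray, led, toy_sch), "absent from the history ledger")
})

test_that("group generalization is the minimal covering tuple", {
  members <- dplyr::bind_rows(make_super(1, "M", 50), make_super(11, "M", 50),
                              make_super(12, "M", 53), make_super(14, "M", 48))
  cells <- generalize_group(members, toy_sch)
  expect_equal(unname(cells["Sex"]), "M")
  expect_equal(unname(cells["Age"]), "[48-53]")
  mixed <- dplyr::bind_rows(make_super(1, "M", 40), make_super(2, "F", 45))
  expect_equal(unname(generalize_group(mixed, toy_sch)["Sex"]), "*")
  one <- make_super(9, "F", 40, age_hi = 42)
  expect_equal(unname(generalize_group(one, toy_sch)["Age"]), "[40-42]")
  # minimality: shrinking either bound uncovers a member
  shrunk_lo <- list(Sex = "M", Age = "[49-53]")
  shrunk_hi <- list(Sex = "M", Age = "[48-52]")
  covers_all <- function(tuple) {
    all(vapply(seq_len(nrow(members)), function(i) {
      qia_covers(tuple, list(Sex = members$Sex[i], Age = members$Age_lo[i]), toy_sch)
    }, logical(1)))
  }
  expect_true(covers_all(as.list(cells)))
  expect_false(covers_all(shrunk_lo))
  expect_false(covers_all(shrunk_hi))
})
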