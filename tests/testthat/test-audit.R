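test_that("candidate sets are the covering rows of the release", {
  rel2 <- toy_release_ktheta()[[2]]
  expect_setequal(candidate_set(rel2, list(Sex = "F", Age = 39), toy_sch)$CaseID,
                  c(13, 15, 18))
  expect_setequal(candidate_set(rel2, list(Sex = "M", Age = 47), toy_sch)$CaseID,
                  c(16, 17, 21))
  # an all-suppressed group covers any target
  rel <- tibble::tibble(CaseID = 1:3, Sex = "*", Age = "*",
                        ADR = c("a", "b", "c"), Group = 1L)
  expect_setequal(candidate_set(rel, list(Sex = "F", Age = 7), toy_sch)$CaseID, 1:3)
})

test_that("exclusion sets implement the four attack predicates", {
  rel <- toy_release_ktheta()
  # known-new, known-discontinuing (F, 39) in quarter 2: the worked example
  exc <- exclusions(rel, 2, list(qia = list(Sex = "F", Age = 39), is_new = TRUE,
                                 discontinues = TRUE),
                    c(13L, 15L, 18L), toy_sch)
  expect_setequal(exc$MD, c(13, 15))
  expect_length(exc$L, 0L)
  effective <- setdiff(c(13L, 15L, 18L), unique(unlist(exc)))
  expect_identical(effective, 18L)
  # soundness of MD: each excluded candidate really is republished next quarter
  expect_true(all(exc$MD %in% rel[[3]]$CaseID))

  # a known-new target in quarter-2 group 4 excludes the returning case 3
  exc4 <- exclusions(rel, 2, list(qia = list(Sex = "F", Age = 40), is_new = TRUE,
                                  discontinues = FALSE),
                     c(3L, 20L, 19L, 22L), toy_sch)
  expect_identical(exc4$L, 3L)
  expect_true(3L %in% rel[[1]]$CaseID)  # soundness of L

  # with a single release and no extra knowledge nothing is excludable
  exc1 <- exclusions(rel[1], 1, list(qia = list(Sex = "M", Age = 50)),
                     c(1L, 7L, 3L, 5L), toy_sch)
  expect_true(all(lengths(exc1) == 0L))
})

test_that("backward/forward exclusions test coverage of the known values", {
  rel <- toy_release_ktheta()
  # candidate 1 is republished as M [48-53] in quarter 2, which does not cover
  # age 46: a backward/forward-style mismatch for a (M, 46) target in quarter 1
  exc <- exclusions(rel, 1, list(qia = list(Sex = "M", Age = 46)),
                    c(1L, 7L, 3L, 5L), toy_sch)
  expect_true(1L %in% exc$F)
  expect_false(3L %in% exc$F)  # 3 reappears as * [40-46], which covers (M, 46)
})

test_that("the full-model printed release audits clean in quarter 2", {
  aud <- audit_series(toy_quarters(), toy_release_ktheta_alpha(), toy_sch,
                      k = 3, theta = 1/3, alpha = 1/4)
  q2 <- dplyr::filter(tidy(aud), quarter == 2)
  expect_equal(nrow(q2), 3L)
  expect_false(any(q2$dig | q2$dsg | q2$ssg))
  expect_gte(min(q2$min_effective), 3)
})

test_that("the baseline printed release is flagged under the MD-attack", {
  aud <- audit_series(toy_quarters(), toy_release_ktheta(), toy_sch)
  q2 <- dplyr::filter(tidy(aud), quarter == 2)
  expect_true(any(q2$dig))
  expect_equal(q2$min_effective[q2$group == 2], 1)  # the worked example's group
  expect_true(q2$ssg[q2$group == 3])                # the all-substantial group
  expect_gt(aud$overall$DIR, 0)
})

test_that("extra adversary knowledge never enlarges candidate sets", {
  aud_all <- audit_series(toy_quarters(), toy_release_ktheta(), toy_sch)
  aud_bfl <- audit_series(toy_quarters(), toy_release_ktheta(), toy_sch,
                          attacks = c("B", "F", "L"))
  both <- dplyr::inner_join(tidy(aud_all), tidy(aud_bfl),
                            by = c("quarter", "group"), suffix = c("_all", "_bfl"))
  expect_true(all(both$min_effective_all <= both$min_effective_bfl))
})

test_that("information loss averages the certainty penalties", {
  # quarter-1 baseline: Sex exact (0) and width-4 age intervals over domain 100
  expect_equal(nil(toy_release_ktheta()[[1]], toy_sch), mean(c(rep(0, 7), rep(0.04, 7))))
  sup <- tibble::tibble(CaseID = 1:3, Sex = "*", Age = "*", ADR = "a", Group = 1L)
  expect_equal(nil(sup, toy_sch), 1)
  exact <- tibble::tibble(CaseID = 1:3, Sex = c("M", "F", "M"),
                          Age = c("50", "40", "39"), ADR = "a", Group = 1L)
  expect_equal(nil(exact, toy_sch), 0)
})
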