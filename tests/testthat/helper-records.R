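# Small builders used across the tests.

toy_sch <- toy_schema()

# a super-record row in span representation, toy schema
make_super <- function(caseid, sex, age_lo, age_hi = age_lo, adr = "x",
                       is_new = TRUE, is_md = TRUE, is_ss = FALSE) {
  tibble::tibble(
    CaseID = as.integer(caseid), n_reports = 1L,
    Sex = sex, Age_lo = age_lo, Age_hi = age_hi,
    ADR = list(unique(adr)),
    is_new = is_new, is_md = is_md, is_ss = is_ss
  )
}

# a raw report row, toy schema
make_report <- function(caseid, sex, age, adr) {
  tibble::tibble(CaseID = as.integer(caseid), Sex = sex, Age = age,
                 ADR = list(unique(adr)))
}

# random generalized tuple (text dialect) for property tests
random_tuple <- function() {
  sex <- sample(c("M", "F", "*"), 1L)
  a <- sort(sample(0:100, 2L, replace = TRUE))
  age <- if (a[1] == a[2]) as.character(a[1]) else sprintf("[%d-%d]", a[1], a[2])
  list(Sex = sex, Age = age)
}
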