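#' Specify a synthetic multi-quarter reporting cohort
#'
#' The generator emulates the structural features the anonymizer relies on:
#' persistent CaseIDs with follow-up reports in consecutive quarters, a fresh
#' influx of new cases each quarter, slow drift of numeric quasi-identifiers
#' across follow-ups (so the earliest-appearance cover is exercised), and a
#' heavy-tailed per-record count of distinct sensitive codes (so
#' substantial-symptoms records arise).  Defaults are sized to the worked
#' example's scale — a few quarters of a few dozen reports — so a full
#' anonymize-and-audit round runs in well under a second.
#'
#' @param quarters Number of quarters.
#' @param new_cases New cases entering each quarter.
#' @param continuation Probability that an active case files a follow-up
#'   report in the next quarter (a case that lapses never returns).
#' @param sex_prob Probabilities of the two `Sex` levels `M`, `F`.
#' @param age_range Integer range new cases' ages are drawn from (within the
#'   schema domain \[0, 100\]).
#' @param age_drift Maximum per-quarter age increment of a continuing case
#'   (drawn uniformly from `0:age_drift`).
#' @param n_codes Size of the sensitive-code vocabulary.
#' @param count_prob Geometric tail parameter of the per-record distinct-code
#'   count, `1 + rgeom(count_prob)`; smaller values give heavier tails and
#'   more substantial-symptoms records.
#' @param dup_prob Probability that a case files two reports in one quarter
#'   (exercising super-record merging).
#' @return A `cohort_spec` list (with the matching [toy_schema()] attached).
#' @examples
#' generate_cohort(cohort_spec(quarters = 2, new_cases = 10), seed = 1)$quarters[[1]]
#' @export
cohort_spec <- function(quarters = 3, new_cases = 25, continuation = 0.3,
                        sex_prob = c(M = 0.5, F = 0.5), age_range = c(18, 85),
                        age_drift = 1, n_codes = 40, count_prob = 0.5,
                        dup_prob = 0.05) {
  stopifnot(quarters >= 1, new_cases >= 0,
            continuation >= 0, continuation <= 1,
            dup_prob >= 0, dup_prob <= 1,
            count_prob > 0, count_prob <= 1,
            age_range[1] <= age_range[2], n_codes >= 1)
  structure(
    list(quarters = as.integer(quarters), new_cases = as.integer(new_cases),
         continuation = continuation, sex_prob = sex_prob,
         age_range = as.integer(age_range), age_drift = as.integer(age_drift),
         n_codes = as.integer(n_codes), count_prob = count_prob,
         dup_prob = dup_prob, schema = toy_schema()),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; identical spec and seed give identical
#'   output.
#' @return A list: `quarters` (raw quarter tibbles in [read_quarter()]
#'   layout), `truth` (per CaseID and quarter the ground-truth `is_new` and
#'   `is_md` labels, the latter judged against the next quarter's CaseID set
#'   and `NA` for the terminal quarter), `schema`, and `spec`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  codes <- sprintf("adr%03d", seq_len(spec$n_codes))
  next_id <- 1L
  active <- tibble(CaseID = integer(0), Sex = character(0), Age = integer(0))
  quarters <- list()
  for (q in seq_len(spec$quarters)) {
    if (spec$new_cases == 0L && nrow(active) == 0L) {
      abort("degenerate spec: no cases to report in quarter ")
    }
    fresh <- tibble(
      CaseID = seq.int(next_id, length.out = spec$new_cases),
      Sex = sample(names(spec$sex_prob), spec$new_cases, replace = TRUE,
                   prob = spec$sex_prob),
      Age = sample(seq(spec$age_range[1], spec$age_range[2]), spec$new_cases,
                   replace = TRUE)
    )
    next_id <- next_id + spec$new_cases
    current <- bind_rows(active, fresh)
    reports <- current
    dup <- runif(nrow(current)) < spec$dup_prob
    if (any(dup)) reports <- bind_rows(reports, current[dup, ])
    reports <- arrange(reports, .data$CaseID)
    n_codes_per <- pmin(1L + rgeom(nrow(reports), spec$count_prob), spec$n_codes)
    reports$ADR <- map(n_codes_per, function(m) sample(codes, m))
    quarters[[q]] <- reports
    # survival and drift into the next quarter
    keep <- runif(nrow(current)) < spec$continuation
    active <- current[keep, , drop = FALSE]
    if (nrow(active) > 0L && spec$age_drift > 0L) {
      active$Age <- pmin(active$Age +
                           sample(0:spec$age_drift, nrow(active), replace = TRUE),
                         100L)
    }
  }
  ids_per_quarter <- map(quarters, ~ unique(.x$CaseID))
  truth <- bind_rows(map(seq_len(spec$quarters), function(q) {
    ids <- ids_per_quarter[[q]]
    seen_before <- if (q == 1L) integer(0) else
      unique(unlist(ids_per_quarter[seq_len(q - 1L)]))
    tibble(
      CaseID = ids, quarter = q,
      is_new = !ids %in% seen_before,
      is_md = if (q == spec$quarters) NA else !ids %in% ids_per_quarter[[q + 1L]]
    )
  }))
  list(quarters = quarters, truth = truth, schema = spec$schema, spec = spec)
}
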