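# Super-records and the record taxonomy: each case's reports within a quarter
# are merged into one super-record, which is then flagged as new/old (n/o),
# medication-discontinuing (md/nmd) and substantial-symptoms (ss/nss).

#' Merge a quarter's reports into super-records
#'
#' All reports sharing a CaseID within one quarter are combined: the sensitive
#' code sets are unioned and the required QIA span becomes the minimal
#' generalized tuple covering every member report (per numeric attribute the
#' min-max envelope; per categorical attribute the common label, or
#' suppression when reports disagree).
#'
#' @param quarter A raw quarter tibble ([read_quarter()] layout).
#' @param schema A [qia_schema()].
#' @return A tibble with one row per CaseID (first-appearance order):
#'   `CaseID`, `n_reports`, span columns (`<attr>_lo`/`<attr>_hi` for numeric
#'   attributes, `<attr>` for categorical ones with `NA` = suppressed), and
#'   the sensitive list-columns.
#' @examples
#' sr <- merge_super_records(toy_quarters()[[2]], toy_schema())
#' nrow(sr)  # 14 distinct cases
#' @export
merge_super_records <- function(quarter, schema) {
  quarter <- as_tibble(quarter)
  if (!"CaseID" %in% names(quarter)) abort("quarter needs a CaseID column")
  ids <- unique(quarter$CaseID)
  rows <- map(ids, function(id) {
    sub <- quarter[quarter$CaseID == id, , drop = FALSE]
    out <- list(CaseID = as.integer(id), n_reports = nrow(sub))
    for (nm in qia_names(schema)) {
      if (attr_kind(schema, nm) == "numeric") {
        out[[paste0(nm, "_lo")]] <- min(as.numeric(sub[[nm]]))
        out[[paste0(nm, "_hi")]] <- max(as.numeric(sub[[nm]]))
      } else {
        labs <- unique(as.character(sub[[nm]]))
        out[[nm]] <- if (length(labs) == 1L && !anyNA(labs)) labs else NA_character_
      }
    }
    out <- as_tibble(out)
    for (sa in schema$sensitive) {
      vals <- sub[[sa]]
      if (!is.list(vals)) vals <- map(as.character(vals), function(s) {
        codes <- trimws(strsplit(s, schema$sa_sep, fixed = TRUE)[[1L]])
        unique(codes[nzchar(codes)])
      })
      out[[sa]] <- list(unique(unlist(vals)))
    }
    out
  })
  bind_rows(rows)
}

#' Raw-history ledger of published cases
#'
#' The publisher keeps, per CaseID, the quarter of its first published
#' appearance and the minimal span covering its raw QIA values in that
#' quarter.  The ledger drives the n/o taxonomy ([tag_history()]) and the
#' earliest-appearance cover ([ear_cover()]), and is updated only with the
#' cases actually published (suppressed records stay "unseen").
#'
#' @param schema A [qia_schema()].
#' @param ledger A ledger tibble.
#' @param supers Super-records of the quarter just published (only the
#'   published ones).
#' @param quarter Quarter index of that publication.
#' @return A tibble `CaseID`, `first_quarter`, span columns.
#' @export
new_ledger <- function(schema) {
  cols <- c(list(CaseID = integer(0), first_quarter = integer(0)),
            setNames(map(span_cols(schema), function(cl) {
              if (grepl("_(lo|hi)$", cl)) numeric(0) else character(0)
            }), span_cols(schema)))
  as_tibble(cols)
}

#' @rdname new_ledger
#' @export
update_ledger <- function(ledger, supers, quarter, schema) {
  fresh <- supers[!supers$CaseID %in% ledger$CaseID,
                  c("CaseID", span_cols(schema)), drop = FALSE]
  if (nrow(fresh) == 0L) return(ledger)
  fresh$first_quarter <- as.integer(quarter)
  bind_rows(ledger, fresh[, names(ledger)])
}

#' Flag new records against the publication history
#'
#' A super-record is an n-record when its CaseID has never appeared in a
#' previously released table, an o-record otherwise.
#'
#' @param supers Super-records ([merge_super_records()]).
#' @param ledger History ledger ([new_ledger()]); an empty ledger marks every
#'   record new.
#' @return `supers` with a logical `is_new` column.
#' @export
tag_history <- function(supers, ledger) {
  supers$is_new <- !supers$CaseID %in% ledger$CaseID
  supers
}

#' Flag medication-discontinuation records
#'
#' A super-record is an md-record when its CaseID will not appear in the next
#' quarter.  The caller supplies the next quarter's CaseID set (the publisher
#' buffers one period of lookahead); for a terminal quarter with no lookahead
#' pass `NULL`, which conservatively marks every record discontinuing
#' (`terminal = "md"`) or none (`terminal = "nmd"`).
#'
#' @param supers Super-records.
#' @param next_caseids Integer CaseIDs of the following quarter, or `NULL`.
#' @param terminal Convention when `next_caseids` is `NULL`.
#' @return `supers` with a logical `is_md` column.
#' @export
tag_md <- function(supers, next_caseids, terminal = c("md", "nmd")) {
  terminal <- match.arg(terminal)
  supers$is_md <- if (is.null(next_caseids)) {
    rep(terminal == "md", nrow(supers))
  } else {
    !supers$CaseID %in% next_caseids
  }
  supers
}

#' Flag substantial-symptoms records
#'
#' Per sensitive attribute the threshold is the quarter's mean plus population
#' standard deviation of the per-record distinct-code counts; a record is an
#' ss-record when the count for *any* sensitive attribute reaches its
#' threshold.  When every record carries the same count the deviation is zero
#' and the literal rule marks every record substantial; a warning is emitted.
#'
#' @param supers Super-records of one quarter.
#' @param schema A [qia_schema()].
#' @return `classify_ss()`: `supers` with a logical `is_ss` column (the rule
#'   table attached as attribute `ss_rule`); `ss_thresholds()`: a tibble
#'   `attribute`, `mean`, `sd`, `threshold`.
#' @examples
#' sr <- merge_super_records(toy_quarters()[[2]], toy_schema())
#' classify_ss(sr, toy_schema())$CaseID[classify_ss(sr, toy_schema())$is_ss]
#' @export
classify_ss <- function(supers, schema) {
  if (nrow(supers) == 0L) abort("classify_ss needs at least one record")
  rule <- ss_thresholds(supers, schema)
  is_ss <- rep(FALSE, nrow(supers))
  for (i in seq_len(nrow(rule))) {
    counts <- lengths(supers[[rule$attribute[i]]])
    is_ss <- is_ss | counts >= rule$threshold[i]
  }
  if (any(rule$sd == 0)) {
    warn("zero spread in sensitive-value counts: every record meets the substantial-symptoms threshold")
  }
  supers$is_ss <- is_ss
  attr(supers, "ss_rule") <- rule
  supers
}

#' @rdname classify_ss
#' @export
ss_thresholds <- function(supers, schema) {
  rows <- map(schema$sensitive, function(sa) {
    counts <- lengths(supers[[sa]])
    m <- mean(counts)
    s <- sqrt(mean((counts - m)^2))  # population SD: deterministic for N = 1
    tibble(attribute = sa, mean = m, sd = s, threshold = m + s)
  })
  bind_rows(rows)
}

# taxonomy helpers
rec_is_nmd <- function(supers) supers$is_new & supers$is_md
rec_class <- function(is_new, is_md) {
  dplyr::case_when(
    is_new & is_md ~ "n&md",
    is_new & !is_md ~ "n&nmd",
    !is_new & is_md ~ "o&md",
    TRUE ~ "o&nmd"
  )
}
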