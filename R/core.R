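# Scoring mathematics of the anonymizer: the per-value admission cap, the
# privacy risk of adding a record to a group, the certainty-penalty
# information loss, their product, the seed-selection distance, the
# earliest-appearance cover, and group generalization.

#' Largest admissible count of one sensitive value in a group
#'
#' With `gv1_size` new-and-discontinuing members and per-value threshold
#' `theta_v`, a group may contain at most `floor(gv1_size * theta_v)` records
#' carrying the value: the value's frequency then stays below `theta_v` in
#' every adversary view, because the new-and-discontinuing view is the
#' smallest.  During grouping the view is still being grown to `k` reserved
#' positions, so passing `k` uses `max(gv1_size, k)` as the effective view
#' size; leave `k = NULL` for the audit-time form based on the actual view.
#'
#' @param gv1_size Number of new-and-discontinuing members (>= 0).
#' @param theta_v Per-value probability threshold in (0, 1].
#' @param k Reserved view size during grouping, or `NULL`.
#' @return Integer cap (vectorized over `theta_v`).
#' @examples
#' eta(4, 1/3)  # 1
#' eta(5, 0.5)  # 2
#' @export
eta <- function(gv1_size, theta_v, k = NULL) {
  base <- if (is.null(k)) gv1_size else max(gv1_size, k)
  as.integer(floor(base * theta_v))
}

#' Privacy risk of one sensitive value
#'
#' `sigma / (eta - sigma + 1)` while the value count `sigma` does not exceed
#' its cap `eta`; infinite once it would.  Nondecreasing in `sigma`,
#' nonincreasing in `eta`.
#'
#' @param sigma Occurrences of the value among group members (set semantics:
#'   a member counts at most once per value).
#' @param eta Cap from [eta()].
#' @return Nonnegative number, possibly `Inf` (vectorized).
#' @examples
#' pr_value(1, 1)  # 1
#' pr_value(2, 1)  # Inf
#' @export
pr_value <- function(sigma, eta) {
  ifelse(sigma > eta, Inf, sigma / (eta - sigma + 1))
}

# per-value member counts over a list of sensitive code sets
sigma_counts <- function(sa_sets, values) {
  if (length(values) == 0L) return(integer(0))
  tab <- table(factor(unlist(map(sa_sets, unique)), levels = values))
  as.integer(tab)
}

# resolve per-value thresholds: scalar theta, or a named vector with optional
# unnamed/".default" fallback
theta_for <- function(values, theta) {
  if (length(theta) == 1L && is.null(names(theta))) {
    return(rep(as.numeric(theta), length(values)))
  }
  default <- if (".default" %in% names(theta)) theta[[".default"]] else NA_real_
  out <- map_dbl(values, function(v) {
    if (v %in% names(theta)) as.numeric(theta[[v]]) else default
  })
  if (anyNA(out)) abort("theta has no threshold (and no .default) for some value")
  out
}

#' Privacy risk of adding a candidate to a group
#'
#' One plus the per-value risks of every sensitive value the candidate
#' carries, evaluated on the hypothetical group including the candidate;
#' infinite as soon as any value would exceed its cap, in which case the
#' candidate is inadmissible.
#'
#' @param group A `ppms_group` (see [new_group()]).
#' @param candidate One super-record row (with taxonomy flags).
#' @param theta Scalar threshold in (0, 1], or a named per-value vector (use
#'   name `".default"` for the fallback).
#' @param schema A [qia_schema()].
#' @param mode `"ppms"` counts the new-and-discontinuing view, `"legacy"` the
#'   new-record view (the baseline without discontinuation handling).
#' @return Nonnegative number >= 1, or `Inf`.
#' @export
privacy_risk <- function(group, candidate, theta, schema, mode = "ppms") {
  members <- bind_rows(group$members, candidate)
  gv1 <- count_view_size(members, mode)
  values <- unique(unlist(map(schema$sensitive, function(sa) candidate[[sa]][[1L]])))
  if (length(values) == 0L) return(1)
  all_sets <- map(seq_len(nrow(members)), function(i) {
    unlist(map(schema$sensitive, function(sa) members[[sa]][[i]]))
  })
  sig <- sigma_counts(all_sets, values)
  caps <- map_int(theta_for(values, theta), function(th) eta(gv1, th, k = group$k))
  risks <- pr_value(sig, caps)
  if (any(is.infinite(risks))) return(Inf)
  1 + sum(risks)
}

# size of the view that must reach k: n&md records (ppms) or n records (legacy)
count_view_size <- function(members, mode) {
  if (is.null(members) || nrow(members) == 0L) return(0L)
  if (mode == "legacy") sum(members$is_new) else sum(members$is_new & members$is_md)
}

# information loss of a member set: |G| * sum over QIAs of the normalized
# certainty penalty of the minimal tuple covering all members' required spans
group_il <- function(members, schema) {
  if (is.null(members) || nrow(members) == 0L) return(0)
  span <- merge_spans(members, schema)
  nrow(members) * sum(as.numeric(span_ncp(span, schema)[1L, ]))
}

# minimal span covering all rows of a span table
merge_spans <- function(spans, schema) {
  out <- list()
  for (nm in qia_names(schema)) {
    if (attr_kind(schema, nm) == "numeric") {
      out[[paste0(nm, "_lo")]] <- min(spans[[paste0(nm, "_lo")]])
      out[[paste0(nm, "_hi")]] <- max(spans[[paste0(nm, "_hi")]])
    } else {
      labs <- unique(spans[[nm]])
      out[[nm]] <- if (length(labs) == 1L && !anyNA(labs)) labs else NA_character_
    }
  }
  as_tibble(out)
}

#' Information-loss increment of adding a candidate
#'
#' `delta_il()` is the certainty-penalty information loss of the group with
#' the candidate minus without it (never negative); `delta_pril()` multiplies
#' it by the privacy risk, the greedy admission score: infinite iff the
#' candidate is inadmissible, and zero when the candidate widens nothing.
#'
#' @inheritParams privacy_risk
#' @return Nonnegative number; `delta_pril()` may be `Inf`.
#' @export
delta_il <- function(group, candidate, schema) {
  group_il(bind_rows(group$members, candidate), schema) -
    group_il(group$members, schema)
}

#' @rdname delta_il
#' @export
delta_pril <- function(group, candidate, theta, schema, mode = "ppms") {
  pr <- privacy_risk(group, candidate, theta, schema, mode)
  if (is.infinite(pr)) return(Inf)
  delta_il(group, candidate, schema) * pr
}

#' Distance between two records' QIA spans
#'
#' L1 distance of the numeric span midpoints, normalized by each attribute's
#' domain width, plus a 0/1 mismatch indicator per categorical attribute.
#' Used to pick the next seed record "farthest" from the last-added one.
#'
#' @param a,b Super-record rows (span representation).
#' @param schema A [qia_schema()].
#' @return Nonnegative number.
#' @examples
#' sr <- merge_super_records(toy_quarters()[[1]], toy_schema())
#' qia_distance(sr[1, ], sr[5, ], toy_schema())
#' @export
qia_distance <- function(a, b, schema) {
  d <- 0
  for (nm in qia_names(schema)) {
    if (attr_kind(schema, nm) == "numeric") {
      lo <- paste0(nm, "_lo"); hi <- paste0(nm, "_hi")
      mid_a <- (a[[lo]][1L] + a[[hi]][1L]) / 2
      mid_b <- (b[[lo]][1L] + b[[hi]][1L]) / 2
      d <- d + abs(mid_a - mid_b) / domain_width(schema, nm)
    } else {
      d <- d + as.numeric(!identical(a[[nm]][1L], b[[nm]][1L]))
    }
  }
  d
}

#' Earliest-appearance cover for returning cases
#'
#' An old record's published tuple must stay consistent with its earliest
#' published appearance, or an adversary comparing releases could exclude it
#' (forward/backward attacks).  The required span of every o-record is
#' widened to also cover the raw span recorded in the ledger at the case's
#' first publication; n-records are untouched.  Idempotent.
#'
#' @param supers Super-records with `is_new` flags.
#' @param ledger History ledger ([new_ledger()]).
#' @param schema A [qia_schema()].
#' @return `supers` with widened span columns.
#' @export
ear_cover <- function(supers, ledger, schema) {
  old <- which(!supers$is_new)
  if (length(old) == 0L) return(supers)
  miss <- setdiff(supers$CaseID[old], ledger$CaseID)
  if (length(miss) > 0L) {
    abort(paste0("o-record CaseID(s) absent from the history ledger: ",
                 paste(miss, collapse = ", ")))
  }
  idx <- match(supers$CaseID[old], ledger$CaseID)
  for (nm in qia_names(schema)) {
    if (attr_kind(schema, nm) == "numeric") {
      lo <- paste0(nm, "_lo"); hi <- paste0(nm, "_hi")
      supers[[lo]][old] <- pmin(supers[[lo]][old], ledger[[lo]][idx])
      supers[[hi]][old] <- pmax(supers[[hi]][old], ledger[[hi]][idx])
    } else {
      cur <- supers[[nm]][old]
      earlier <- ledger[[nm]][idx]
      same <- !is.na(cur) & !is.na(earlier) & cur == earlier
      supers[[nm]][old] <- ifelse(same, cur, NA_character_)
    }
  }
  supers
}

#' Generalize a completed group
#'
#' The minimal tuple covering every member's required span: per numeric
#' attribute the min-max interval, per categorical attribute the common label
#' or `"*"`.  Shrinking any numeric bound would uncover some member.
#'
#' @param members Member super-records (span representation), non-empty.
#' @param schema A [qia_schema()].
#' @return Named character vector of release-dialect cells, one per QIA.
#' @examples
#' sr <- merge_super_records(toy_quarters()[[1]], toy_schema())
#' generalize_group(sr[1:4, ], toy_schema())
#' @export
generalize_group <- function(members, schema) {
  if (is.null(members) || nrow(members) == 0L) abort("cannot generalize an empty group")
  span_to_text(merge_spans(members, schema), schema)
}
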