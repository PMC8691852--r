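# Adversary simulation and security/utility metrics.  The auditor replays the
# backward (B), forward (F), latest (L) and medication-discontinuation (MD)
# candidate-exclusion attacks against a release series, instantiating a
# worst-case target from every published record, and summarizes the findings
# as the DIR / DSR / SSGR security ratios and the NIL utility penalty.

#' Candidate records for a target's quasi-identifiers
#'
#' All rows of one release whose published (generalized) tuple covers the
#' target's raw QIA values — the adversary's starting candidate set.
#'
#' @param release A release tibble ([read_release()] layout).
#' @param target_qia Named list / one-row data frame of the target's raw QIA
#'   values (or spans), e.g. `list(Sex = "F", Age = 39)`.
#' @param schema A [qia_schema()].
#' @return Tibble `CaseID`, `Group` of the covering rows.
#' @examples
#' candidate_set(toy_release_ktheta()[[2]], list(Sex = "F", Age = 39), toy_schema())
#' @export
candidate_set <- function(release, target_qia, schema) {
  spans <- release_spans(release, schema)
  tq <- tuple_to_span(target_qia, schema)
  hit <- map_lgl(seq_len(nrow(spans)), function(i) {
    all(spans_cover(spans[i, ], tq, schema))
  })
  spans[hit, c("CaseID", "Group")]
}

#' Exclusion sets of the four linkage attacks
#'
#' Given a candidate CaseID set inside quarter `quarter`, computes which
#' candidates the adversary can strike out: `B` — candidates whose row in an
#' earlier release fails to cover the target's raw QIA; `F` — likewise over
#' later releases; `L` — candidates already published before the target's
#' first appearance (usable only when the target is known to be new); `MD` —
#' candidates republished in the next quarter (usable only when the target is
#' known to discontinue).
#'
#' @param releases List of release tibbles, quarter 1 first.
#' @param quarter Quarter index the candidates come from.
#' @param target A list: `qia` (raw values the adversary knows — by
#'   convention the case's earliest raw values), `is_new` (known first
#'   appearance?), `discontinues` (known absent from the next quarter?).
#' @param candidates Integer CaseIDs of the candidate set.
#' @param schema A [qia_schema()].
#' @param attacks Which attacks the adversary wields.
#' @return Named list of integer CaseID vectors `B`, `F`, `L`, `MD`.
#' @examples
#' rel <- toy_release_ktheta()
#' exclusions(rel, 2, list(qia = list(Sex = "F", Age = 39), is_new = TRUE,
#'                         discontinues = TRUE),
#'            c(13L, 15L, 18L), toy_schema())
#' @export
exclusions <- function(releases, quarter, target, candidates, schema,
                       attacks = c("B", "F", "L", "MD")) {
  exclusions_impl(map(releases, release_spans, schema = schema),
                  quarter, target, candidates, schema, attacks)
}

exclusions_impl <- function(spans, quarter, target, candidates, schema,
                            attacks) {
  tq <- tuple_to_span(target$qia, schema)
  covers_in <- function(q, id) {
    # TRUE when the candidate is absent from release q or its row there covers
    s <- spans[[q]]
    i <- match(id, s$CaseID)
    if (is.na(i)) return(TRUE)
    all(spans_cover(s[i, ], tq, schema))
  }
  B <- F_ <- L <- MD <- integer(0)
  if ("B" %in% attacks && quarter > 1L) {
    B <- candidates[map_lgl(candidates, function(id) {
      any(!map_lgl(seq_len(quarter - 1L), covers_in, id = id))
    })]
  }
  if ("F" %in% attacks && quarter < length(spans)) {
    F_ <- candidates[map_lgl(candidates, function(id) {
      any(!map_lgl(seq(quarter + 1L, length(spans)), covers_in, id = id))
    })]
  }
  if ("L" %in% attacks && isTRUE(target$is_new) && quarter > 1L) {
    earlier <- unique(unlist(map(spans[seq_len(quarter - 1L)], `[[`, "CaseID")))
    L <- intersect(candidates, earlier)
  }
  if ("MD" %in% attacks && isTRUE(target$discontinues) &&
      quarter < length(spans)) {
    MD <- intersect(candidates, spans[[quarter + 1L]]$CaseID)
  }
  list(B = B, F = F_, L = L, MD = MD)
}

#' Audit a release series against the five attacks
#'
#' For every group of every release the auditor instantiates a worst-case
#' target from each member record: the adversary knows the member's earliest
#' raw QIA values, may know it is new (when it is), and may know it
#' discontinues (when it does and a next release exists).  It then computes
#' the post-exclusion candidate count and value frequencies per target, the
#' four adversary views, and the per-group findings:
#'
#' * *dangerous identity group* (DIG) — some target's post-exclusion
#'   candidate count falls below `k`;
#' * *dangerous sensitivity group* (DSG) — some sensitive value's frequency
#'   among some target's post-exclusion candidates exceeds its threshold;
#' * *substantial-symptoms group* (SSG) — the group's ss-record frequency
#'   exceeds `alpha` (the per-view frequencies are also reported).
#'
#' DIR / DSR / SSGR are the fractions of flagged groups; NIL is the mean
#' normalized certainty penalty of the published cells.
#'
#' @param raw List of raw quarter tibbles (to recover raw values, taxonomy
#'   and the substantial-symptoms rule), quarter 1 first.
#' @param releases List of release tibbles, aligned with `raw`.
#' @param schema A [qia_schema()].
#' @param k,theta,alpha The thresholds audited against.
#' @param attacks Attacks the adversary wields (subset of B, F, L, MD).
#' @param terminal_md Allow the discontinuation attack in the final quarter
#'   (treating every final-quarter case as discontinuing)?  Default `FALSE`:
#'   with no later release the knowledge cannot exist.
#' @return A `ppms_audit` object; [tidy()] gives the per-group findings,
#'   [glance()] the pooled ratios, [autoplot()] a per-quarter chart.
#' @examples
#' aud <- audit_series(toy_quarters(), toy_release_ktheta_alpha(), toy_schema())
#' glance(aud)
#' @export
audit_series <- function(raw, releases, schema, k = 3, theta = 1/3,
                         alpha = 1/4, attacks = c("B", "F", "L", "MD"),
                         terminal_md = FALSE) {
  stopifnot(length(raw) == length(releases))
  nq <- length(releases)
  spans <- map(releases, release_spans, schema = schema)
  pub_ids <- map(releases, `[[`, "CaseID")
  first_pub <- list()
  for (q in seq_len(nq)) {
    for (id in pub_ids[[q]]) {
      key <- as.character(id)
      if (is.null(first_pub[[key]])) first_pub[[key]] <- q
    }
  }
  # per-quarter super-records of the raw data: earliest raw spans + ss flags
  supers <- map(raw, function(qd) merge_super_records(qd, schema))
  supers <- map(supers, classify_ss, schema = schema)

  findings <- list()
  for (q in seq_len(nq)) {
    sp <- spans[[q]]
    sup <- supers[[q]]
    miss <- setdiff(sp$CaseID, sup$CaseID)
    if (length(miss) > 0L) {
      abort(paste0("release quarter ", q, " contains CaseID(s) absent from the raw quarter: ",
                   paste(miss, collapse = ", ")))
    }
    for (g in sort(unique(sp$Group))) {
      rows <- sp[sp$Group == g, ]
      ids <- rows$CaseID
      info <- tibble(
        CaseID = ids,
        is_new = map_int(ids, ~ first_pub[[as.character(.x)]]) == q,
        is_md = if (q < nq) !ids %in% pub_ids[[q + 1L]] else
          rep(terminal_md, length(ids)),
        is_ss = sup$is_ss[match(ids, sup$CaseID)]
      )
      gv <- c(sum(info$is_new & info$is_md), sum(info$is_new),
              sum(info$is_md), nrow(info))
      md_knowable <- q < nq || terminal_md

      # worst-case per-member targets: post-exclusion candidate counts and
      # value frequencies
      eff_counts <- numeric(0)
      dsg <- FALSE
      max_eff_value_freq <- 0
      for (i in seq_along(ids)) {
        id <- ids[i]
        fq <- first_pub[[as.character(id)]]
        known <- earliest_known_span(id, fq, supers, schema)
        if (!all(spans_cover(rows[i, ], known, schema))) next  # not locatable here
        target <- list(qia = known,
                       is_new = info$is_new[i],
                       discontinues = md_knowable && info$is_md[i])
        exc <- exclusions_impl(spans, q, target, ids, schema, attacks)
        eff <- setdiff(ids, unique(unlist(exc)))
        eff_counts <- c(eff_counts, length(eff))
        if (length(eff) > 0L) {
          eff_sets <- map(match(eff, ids), function(j) {
            unlist(map(schema$sensitive, function(sa) rows[[sa]][[j]]))
          })
          vals <- unique(unlist(eff_sets))
          if (length(vals) > 0L) {
            freq <- sigma_counts(eff_sets, vals) / length(eff)
            max_eff_value_freq <- max(max_eff_value_freq, max(freq))
            if (any(freq > theta_for(vals, theta))) dsg <- TRUE
          }
        }
      }
      # per-view value and ss frequencies
      view_members <- list(which(info$is_new & info$is_md), which(info$is_new),
                           which(info$is_md), seq_len(nrow(info)))
      view_stats <- map(view_members, function(ix) {
        if (length(ix) == 0L) return(list(value = 0, ss = 0, theta_excess = -Inf))
        sets <- map(ix, function(j) {
          unlist(map(schema$sensitive, function(sa) rows[[sa]][[j]]))
        })
        vals <- unique(unlist(sets))
        vf <- if (length(vals) == 0L) 0 else max(sigma_counts(sets, vals) / length(ix))
        te <- if (length(vals) == 0L) -Inf else
          max(sigma_counts(sets, vals) / length(ix) - theta_for(vals, theta))
        list(value = vf, ss = sum(info$is_ss[ix]) / length(ix), theta_excess = te)
      })
      audited_views <- if (md_knowable) 1:4 else c(2L, 4L)
      findings[[length(findings) + 1L]] <- tibble(
        quarter = q, group = g, size = nrow(info),
        gv1 = gv[1L], gv2 = gv[2L], gv3 = gv[3L], gv4 = gv[4L],
        min_effective = if (length(eff_counts) == 0L) NA_real_ else min(eff_counts),
        max_eff_value_freq = max_eff_value_freq,
        group_ss_freq = sum(info$is_ss) / nrow(info),
        max_view_ss_freq = max(map_dbl(view_stats[audited_views], "ss")),
        max_view_value_freq = max(map_dbl(view_stats[audited_views], "value")),
        dig = length(eff_counts) > 0L && min(eff_counts) < k,
        dsg = dsg,
        ssg = sum(info$is_ss) / nrow(info) > alpha
      )
    }
  }
  groups <- bind_rows(findings)
  summary <- groups |>
    group_by(.data$quarter) |>
    summarise(n_groups = n(), dir = mean(.data$dig), dsr = mean(.data$dsg),
              ssgr = mean(.data$ssg), .groups = "drop") |>
    mutate(nil = map_dbl(.data$quarter, ~ nil(releases[[.x]], schema)))
  structure(
    list(groups = groups, summary = summary,
         overall = list(
           DIR = mean(groups$dig), DSR = mean(groups$dsg),
           SSGR = mean(groups$ssg),
           NIL = mean(summary$nil)),
         params = list(k = k, theta = theta, alpha = alpha, attacks = attacks,
                       terminal_md = terminal_md)),
    class = "ppms_audit"
  )
}

# the target's known QIA values: minimal span over the case's raw reports in
# its first published quarter
earliest_known_span <- function(id, first_quarter, supers, schema) {
  sup <- supers[[first_quarter]]
  i <- match(id, sup$CaseID)
  if (is.na(i)) {
    abort(paste0("CaseID ", id, " not found in raw quarter ", first_quarter))
  }
  sup[i, span_cols(schema), drop = FALSE]
}

#' @export
print.ppms_audit <- function(x, ...) {
  cat("<ppms_audit>\n")
  print(x$summary)
  cat(sprintf("  pooled: DIR = %.3f, DSR = %.3f, SSGR = %.3f, mean NIL = %.4f\n",
              x$overall$DIR, x$overall$DSR, x$overall$SSGR, x$overall$NIL))
  invisible(x)
}

#' Normalized information loss of a release
#'
#' Mean over published rows and QIA attributes of the normalized certainty
#' penalty: interval width over domain width for numeric attributes, 0 for an
#' exact category and 1 for a suppressed one.  0 on an ungeneralized release,
#' 1 on a fully suppressed one.
#'
#' @param release A release tibble.
#' @param schema A [qia_schema()].
#' @return A number in \[0, 1\] (`NaN` for an empty release).
#' @examples
#' nil(toy_release_ktheta()[[1]], toy_schema())
#' @export
nil <- function(release, schema) {
  if (nrow(release) == 0L) return(NaN)
  spans <- release_spans(release, schema)
  mean(as.matrix(span_ncp(spans, schema)))
}
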