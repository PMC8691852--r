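# broom-style accessors and ggplot2 autoplot methods for the two result types.

#' Tidy an anonymization result
#'
#' @param x A `ppms_anonymization` from [anonymize_series()].
#' @param ... Unused.
#' @return All published rows in one tibble with a leading `quarter` column.
#' @method tidy ppms_anonymization
#' @export
tidy.ppms_anonymization <- function(x, ...) {
  bind_rows(imap(x$releases, ~ mutate(.x, quarter = .y, .before = 1L)))
}

#' @rdname tidy.ppms_anonymization
#' @return `glance()`: one row per run — quarters, records in/out, groups,
#'   suppressed count, mean normalized information loss.
#' @method glance ppms_anonymization
#' @export
glance.ppms_anonymization <- function(x, ...) {
  nils <- map_dbl(x$releases, nil, schema = x$schema)
  tibble(
    quarters = length(x$releases),
    records_in = sum(map_int(x$supers, nrow)),
    records_published = sum(map_int(x$releases, nrow)),
    n_groups = sum(lengths(x$groups)),
    n_suppressed = nrow(x$suppressed),
    mean_nil = mean(nils, na.rm = TRUE),
    k = x$params$k,
    alpha = x$params$alpha,
    mode = x$params$mode
  )
}

#' @rdname tidy.ppms_anonymization
#' @param object A `ppms_anonymization`.
#' @return `autoplot()`: a per-quarter bar chart of group counts with the
#'   normalized information loss overlaid as a line.
#' @method autoplot ppms_anonymization
#' @export
autoplot.ppms_anonymization <- function(object, ...) {
  df <- tibble(
    quarter = seq_along(object$releases),
    groups = lengths(object$groups),
    nil = map_dbl(object$releases, nil, schema = object$schema)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quarter))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$groups), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$nil * max(df$groups), group = 1),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$nil * max(df$groups)),
                        colour = "firebrick") +
    ggplot2::scale_y_continuous(
      "groups",
      sec.axis = ggplot2::sec_axis(~ . / max(df$groups), name = "NIL")
    ) +
    ggplot2::labs(x = "quarter") +
    ggplot2::theme_minimal()
}

#' Tidy an audit report
#'
#' @param x A `ppms_audit` from [audit_series()].
#' @param ... Unused.
#' @return The per-group findings tibble: view sizes, post-exclusion
#'   candidate minima, value and ss frequencies, and the DIG/DSG/SSG flags.
#' @method tidy ppms_audit
#' @export
tidy.ppms_audit <- function(x, ...) x$groups

#' @rdname tidy.ppms_audit
#' @return `glance()`: one row with the pooled `dir`, `dsr`, `ssgr`, mean
#'   `nil` and the audited thresholds.
#' @method glance ppms_audit
#' @export
glance.ppms_audit <- function(x, ...) {
  tibble(
    n_groups = nrow(x$groups),
    dir = x$overall$DIR,
    dsr = x$overall$DSR,
    ssgr = x$overall$SSGR,
    nil = x$overall$NIL,
    k = x$params$k,
    alpha = x$params$alpha
  )
}

#' @rdname tidy.ppms_audit
#' @param object A `ppms_audit`.
#' @return `autoplot()`: per-quarter DIR/DSR/SSGR bars.
#' @method autoplot ppms_audit
#' @export
autoplot.ppms_audit <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("dir", "dsr", "ssgr"), names_to = "metric",
                        values_to = "ratio")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quarter), y = .data$ratio,
                                   fill = toupper(.data$metric))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "quarter", y = "ratio of flagged groups", fill = NULL) +
    ggplot2::theme_minimal()
}
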