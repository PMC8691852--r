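# Generalized QIA values: an exact category, full suppression ("*"), or a
# closed numeric interval "[lo-hi]".  Raw numeric values are modeled as the
# degenerate interval [v, v] so a single covering relation serves raw and
# generalized data alike.

gen_interval <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (is.na(lo) || is.na(hi) || lo > hi) abort("interval needs lo <= hi")
  structure(list(kind = "interval", lo = lo, hi = hi), class = "gen_value")
}

gen_category <- function(label) {
  structure(list(kind = "category", label = as.character(label)),
            class = "gen_value")
}

gen_suppressed <- function() {
  structure(list(kind = "suppressed"), class = "gen_value")
}

#' @export
print.gen_value <- function(x, ...) {
  cat("<gen_value> ", format_gen_value(x), "\n", sep = "")
  invisible(x)
}

#' Parse and format generalized attribute values
#'
#' The release dialect writes a numeric interval as `"[lo-hi]"` (ASCII hyphen
#' emitted; an en dash is accepted on input), suppression as `"*"`, and an
#' exact value as a bare token.  A bare numeric token parses to the degenerate
#' interval `[v, v]`; for a numeric attribute `"*"` parses to the full-domain
#' interval (numeric attributes are generalized only by intervals).
#'
#' @param text Cell text, e.g. `"[46-50]"`, `"*"`, `"M"`, `"39"`.
#' @param attribute Attribute name (a column of `schema`).
#' @param schema A [qia_schema()].
#' @param value A parsed generalized value (as returned by `parse_gen_value()`).
#'
#' @return `parse_gen_value()` returns a `gen_value`; `format_gen_value()`
#'   returns the canonical cell text.  The two round-trip.
#' @examples
#' sch <- toy_schema()
#' parse_gen_value("[46-50]", "Age", sch)
#' format_gen_value(parse_gen_value("*", "Sex", sch))
#' @export
parse_gen_value <- function(text, attribute, schema) {
  a <- schema$attributes[[attribute]]
  if (is.null(a)) abort(paste0("unknown attribute: ", attribute))
  text <- trimws(as.character(text))
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort(paste0("empty cell for attribute ", attribute))
  }
  # accept en dash (–) as the interval separator
  norm <- gsub("–", "-", text)
  if (norm == "*") {
    if (a$kind == "numeric") return(gen_interval(a$lo, a$hi))
    return(gen_suppressed())
  }
  m <- regmatches(norm, regexec(
    "^\\[\\s*(-?[0-9.]+)\\s*-\\s*(-?[0-9.]+)\\s*\\]$", norm))[[1L]]
  if (length(m) == 3L) {
    if (a$kind != "numeric") {
      abort(paste0("interval syntax is invalid for categorical attribute ",
                   attribute, ": ", text))
    }
    lo <- suppressWarnings(as.numeric(m[2L]))
    hi <- suppressWarnings(as.numeric(m[3L]))
    if (is.na(lo) || is.na(hi)) abort(paste0("malformed interval: ", text))
    if (lo > hi) abort(paste0("interval lo > hi: ", text))
    if (lo < a$lo || hi > a$hi) {
      abort(sprintf("interval %s outside the %s domain [%g, %g]",
                    text, attribute, a$lo, a$hi))
    }
    return(gen_interval(lo, hi))
  }
  if (grepl("^\\[", norm) || grepl("\\]$", norm)) {
    abort(paste0("malformed bracket syntax: ", text))
  }
  if (a$kind == "numeric") {
    v <- suppressWarnings(as.numeric(norm))
    if (is.na(v)) abort(paste0("non-numeric value for ", attribute, ": ", text))
    if (v < a$lo || v > a$hi) {
      abort(sprintf("value %s outside the %s domain [%g, %g]",
                    text, attribute, a$lo, a$hi))
    }
    return(gen_interval(v, v))
  }
  if (!text %in% a$levels) {
    abort(sprintf("'%s' is not a level of %s", text, attribute))
  }
  gen_category(text)
}

#' @rdname parse_gen_value
#' @export
format_gen_value <- function(value) {
  stopifnot(inherits(value, "gen_value"))
  switch(value$kind,
    suppressed = "*",
    category = value$label,
    interval = if (value$lo == value$hi) {
      format(value$lo, trim = TRUE, scientific = FALSE)
    } else {
      sprintf("[%s-%s]",
              format(value$lo, trim = TRUE, scientific = FALSE),
              format(value$hi, trim = TRUE, scientific = FALSE))
    }
  )
}

#' Does one generalized tuple cover another?
#'
#' Per attribute: suppression covers everything; a category covers only the
#' same category; an interval covers any sub-interval or point.  A tuple
#' covers another iff it covers it on every attribute.  Raw values are
#' admitted on either side (a raw numeric value is the degenerate interval).
#'
#' @param outer,inner Named lists / one-row data frames whose elements are
#'   cell text in the release dialect or raw values, keyed by QIA name.
#' @param schema A [qia_schema()].
#' @return Logical scalar.
#' @examples
#' sch <- toy_schema()
#' qia_covers(list(Sex = "M", Age = "[46-50]"), list(Sex = "M", Age = 50), sch)
#' qia_covers(list(Sex = "M", Age = "[46-50]"), list(Sex = "F", Age = 48), sch)
#' @export
qia_covers <- function(outer, inner, schema) {
  os <- tuple_to_span(outer, schema)
  is <- tuple_to_span(inner, schema)
  all(spans_cover(os, is, schema))
}

# ---- internal span machinery -------------------------------------------------
# A "span row" is a one-row tibble (or plain list) with, per numeric attribute
# A, columns A_lo/A_hi and, per categorical attribute A, a character column A
# where NA means suppressed.

tuple_to_span <- function(tuple, schema) {
  tuple <- as.list(tuple)
  if (all(span_cols(schema) %in% names(tuple))) {
    return(as_tibble(tuple[span_cols(schema)]))  # already in span form
  }
  out <- list()
  for (nm in qia_names(schema)) {
    if (!nm %in% names(tuple)) {
      abort(paste0("tuple is missing attribute ", nm))
    }
    cell <- tuple[[nm]]
    gv <- if (inherits(cell, "gen_value")) cell else {
      parse_gen_value(as.character(cell), nm, schema)
    }
    if (attr_kind(schema, nm) == "numeric") {
      out[[paste0(nm, "_lo")]] <- gv$lo
      out[[paste0(nm, "_hi")]] <- gv$hi
    } else {
      out[[nm]] <- if (gv$kind == "suppressed") NA_character_ else gv$label
    }
  }
  as_tibble(out)
}

# vectorized: does the single span row `outer` cover each row of `inner`?
spans_cover <- function(outer, inner, schema) {
  res <- rep(TRUE, nrow(inner))
  for (nm in qia_names(schema)) {
    if (attr_kind(schema, nm) == "numeric") {
      lo <- paste0(nm, "_lo"); hi <- paste0(nm, "_hi")
      res <- res & outer[[lo]][1L] <= inner[[lo]] & outer[[hi]][1L] >= inner[[hi]]
    } else {
      o <- outer[[nm]][1L]
      res <- res & (is.na(o) | (!is.na(inner[[nm]]) & o == inner[[nm]]))
    }
  }
  res
}

# format one span row back into release-dialect text cells (named character)
span_to_text <- function(span, schema) {
  out <- character(0)
  for (nm in qia_names(schema)) {
    gv <- if (attr_kind(schema, nm) == "numeric") {
      gen_interval(span[[paste0(nm, "_lo")]][1L], span[[paste0(nm, "_hi")]][1L])
    } else if (is.na(span[[nm]][1L])) gen_suppressed() else gen_category(span[[nm]][1L])
    out[nm] <- format_gen_value(gv)
  }
  out
}

# per-row normalized certainty penalty of a span table; returns a matrix-like
# tibble with one ncp column per QIA attribute
span_ncp <- function(spans, schema) {
  out <- list()
  for (nm in qia_names(schema)) {
    if (attr_kind(schema, nm) == "numeric") {
      w <- domain_width(schema, nm)
      out[[nm]] <- (spans[[paste0(nm, "_hi")]] - spans[[paste0(nm, "_lo")]]) / w
    } else {
      out[[nm]] <- ifelse(is.na(spans[[nm]]), 1, 0)
    }
  }
  as_tibble(out)
}
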