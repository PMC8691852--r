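#' Describe a quasi-identifier attribute
#'
#' A quasi-identification attribute (QIA) is a column that is individually
#' non-identifying but jointly linkable (Sex, Age, Weight, ...).  Numeric
#' attributes carry a closed domain `[min, max]` used to normalize interval
#' widths; categorical attributes carry a finite level set and are generalized
#' only by full suppression (`"*"`).
#'
#' @param name Column name in the raw and released tables.
#' @param min,max Closed numeric domain bounds, `min < max`.
#' @param units Optional unit label (documentation only).
#' @param levels Non-empty character vector of admissible categories.
#'
#' @return A list describing one attribute, for use in [qia_schema()].
#' @examples
#' qia_numeric("Age", 0, 100, units = "years")
#' qia_categorical("Sex", c("M", "F"))
#' @export
qia_numeric <- function(name, min, max, units = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(min) || !is.numeric(max) || length(min) != 1L ||
      length(max) != 1L || !(min < max)) {
    abort("numeric attribute domain must satisfy min < max")
  }
  structure(
    list(name = name, kind = "numeric", lo = as.numeric(min),
         hi = as.numeric(max), units = units),
    class = "qia_attribute"
  )
}

#' @rdname qia_numeric
#' @export
qia_categorical <- function(name, levels) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) == 0L || anyDuplicated(levels) || any(!nzchar(levels))) {
    abort("categorical attribute needs a non-empty set of distinct levels")
  }
  if ("*" %in% levels) abort("'*' is reserved for suppression")
  structure(
    list(name = name, kind = "categorical", levels = levels),
    class = "qia_attribute"
  )
}

#' Build a table schema for quarterly report data
#'
#' The schema names the quasi-identifier attributes (in column order), the
#' multivalued sensitive attributes (e.g. ADR code lists), and the separator
#' used to join sensitive codes inside one table cell.
#'
#' @param ... Attribute descriptors from [qia_numeric()] / [qia_categorical()].
#' @param sensitive Character vector of sensitive-attribute column names.
#' @param sa_sep Separator joining sensitive codes within a cell.
#'
#' @return An object of class `qia_schema`.
#' @examples
#' qia_schema(
#'   qia_categorical("Sex", c("M", "F")),
#'   qia_numeric("Age", 0, 100),
#'   sensitive = "ADR"
#' )
#' @export
qia_schema <- function(..., sensitive = "ADR", sa_sep = ",") {
  attrs <- list(...)
  if (length(attrs) == 1L && is.list(attrs[[1L]]) &&
      !inherits(attrs[[1L]], "qia_attribute")) {
    attrs <- attrs[[1L]]
  }
  if (length(attrs) == 0L) abort("schema needs at least one QIA attribute")
  ok <- map_lgl(attrs, inherits, "qia_attribute")
  if (!all(ok)) abort("attributes must be built with qia_numeric()/qia_categorical()")
  nms <- map_chr(attrs, "name")
  sensitive <- as.character(sensitive)
  all_names <- c(nms, sensitive)
  if (anyDuplicated(all_names)) abort("attribute names must be unique")
  reserved <- c("CaseID", "Group", "caseid", "group", "quarter")
  if (any(all_names %in% reserved)) {
    abort(paste0("attribute names may not use the reserved names: ",
                 paste(reserved, collapse = ", ")))
  }
  if (any(grepl("_(lo|hi)$", nms))) {
    abort("QIA names ending in '_lo'/'_hi' collide with internal span columns")
  }
  if (length(sensitive) == 0L) abort("at least one sensitive attribute is required")
  structure(
    list(attributes = setNames(attrs, nms), sensitive = sensitive,
         sa_sep = sa_sep),
    class = "qia_schema"
  )
}

#' @export
print.qia_schema <- function(x, ...) {
  cat("<qia_schema>\n")
  for (a in x$attributes) {
    if (a$kind == "numeric") {
      cat(sprintf("  %s: numeric [%g, %g]%s\n", a$name, a$lo, a$hi,
                  if (is.null(a$units)) "" else paste0(" ", a$units)))
    } else {
      cat(sprintf("  %s: categorical {%s}\n", a$name,
                  paste(a$levels, collapse = ", ")))
    }
  }
  cat("  sensitive:", paste(x$sensitive, collapse = ", "),
      sprintf("(separator %s)\n", dQuote(x$sa_sep)))
  invisible(x)
}

#' Toy two-attribute schema used by the bundled worked example
#'
#' Sex in {M, F}; Age with domain \[0, 100\] years (the toy tables never state
#' a domain, so a conventional human age range is used; override by building
#' your own [qia_schema()]); a single multivalued sensitive attribute `ADR`.
#'
#' @param age_domain Closed Age domain, default `c(0, 100)`.
#' @return A `qia_schema`.
#' @examples
#' toy_schema()
#' @export
toy_schema <- function(age_domain = c(0, 100)) {
  qia_schema(
    qia_categorical("Sex", c("M", "F")),
    qia_numeric("Age", age_domain[1], age_domain[2], units = "years"),
    sensitive = "ADR"
  )
}

# ---- internal schema helpers -------------------------------------------------

qia_names <- function(schema) names(schema$attributes)

numeric_attrs <- function(schema) {
  names(keep(schema$attributes, ~ .x$kind == "numeric"))
}

categorical_attrs <- function(schema) {
  names(keep(schema$attributes, ~ .x$kind == "categorical"))
}

attr_kind <- function(schema, name) schema$attributes[[name]]$kind

domain_width <- function(schema, name) {
  a <- schema$attributes[[name]]
  a$hi - a$lo
}

# span columns: numeric attr A -> A_lo, A_hi; categorical A -> A (NA = "*")
span_cols <- function(schema) {
  unlist(map(schema$attributes, function(a) {
    if (a$kind == "numeric") paste0(a$name, c("_lo", "_hi")) else a$name
  }), use.names = FALSE)
}
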