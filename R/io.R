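#' Read raw quarterly report tables
#'
#' A raw quarter is a delimited text file with a header row
#' `CaseID,<QIA...>,<SA...>`: one row per report, raw QIA values, and each
#' sensitive cell holding one or more codes joined by the schema's separator.
#'
#' @param path,paths File path(s); `read_quarters()` returns the quarters in
#'   the order given (quarter 1 first).
#' @param schema A [qia_schema()].
#' @return A tibble with columns `CaseID` (integer), the typed QIA columns,
#'   and one list-column of character code vectors per sensitive attribute.
#'   `read_quarters()` returns a list of such tibbles.
#' @examples
#' q2 <- toy_quarters()[[2]]
#' nrow(q2)
#' @export
read_quarter <- function(path, schema) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("CaseID", qia_names(schema), schema$sensitive)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")))
  }
  tidy_quarter(raw[need], schema, where = path)
}

#' @rdname read_quarter
#' @export
read_quarters <- function(paths, schema) {
  map(paths, read_quarter, schema = schema)
}

# validate/type a raw quarter given as character columns or a user tibble
tidy_quarter <- function(df, schema, where = "quarter") {
  df <- as_tibble(df)
  out <- tibble(CaseID = as.integer(df$CaseID))
  if (anyNA(out$CaseID) || any(out$CaseID <= 0L)) {
    abort(paste0(where, ": CaseID must be a positive integer"))
  }
  for (nm in qia_names(schema)) {
    a <- schema$attributes[[nm]]
    if (a$kind == "numeric") {
      v <- as.numeric(df[[nm]])
      bad <- which(is.na(v) | v < a$lo | v > a$hi)
      if (length(bad) > 0L) {
        abort(sprintf("%s: row %d has %s value outside domain [%g, %g]",
                      where, bad[1L], nm, a$lo, a$hi))
      }
      out[[nm]] <- v
    } else {
      v <- as.character(df[[nm]])
      bad <- which(!v %in% a$levels)
      if (length(bad) > 0L) {
        abort(sprintf("%s: row %d has invalid %s level '%s'",
                      where, bad[1L], nm, v[bad[1L]]))
      }
      out[[nm]] <- v
    }
  }
  for (sa in schema$sensitive) {
    cells <- as.character(df[[sa]])
    if (anyNA(cells) || any(!nzchar(trimws(cells)))) {
      abort(paste0(where, ": empty ", sa, " cell"))
    }
    out[[sa]] <- map(cells, function(s) {
      codes <- trimws(strsplit(s, schema$sa_sep, fixed = TRUE)[[1L]])
      unique(codes[nzchar(codes)])
    })
  }
  out
}

#' Read and write published releases
#'
#' A release file is the raw layout plus a `Group` column, with QIA cells in
#' the generalized dialect (`"[lo-hi]"`, `"*"`, exact category).  Within a
#' group every row must carry the identical generalized tuple.
#'
#' @param path,paths File path(s), quarter 1 first for `read_release_series()`.
#' @param schema A [qia_schema()].
#' @param release A release tibble as returned by `read_release()` or
#'   [anonymize_series()].
#' @return `read_release()` returns a tibble `CaseID`, generalized QIA text
#'   columns (canonicalized to the ASCII dialect), sensitive text columns,
#'   `Group` (integer); row order is preserved.
#' @examples
#' rel <- toy_release_ktheta()[[2]]
#' dplyr::count(rel, Group)
#' @export
read_release <- function(path, schema) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("CaseID", qia_names(schema), schema$sensitive, "Group")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")))
  }
  out <- raw[need]
  out$CaseID <- as.integer(out$CaseID)
  out$Group <- as.integer(out$Group)
  if (anyNA(out$CaseID) || anyNA(out$Group)) {
    abort(paste0(path, ": CaseID and Group must be integers"))
  }
  if (anyDuplicated(out$CaseID)) {
    abort(paste0(path, ": duplicate CaseID within one release"))
  }
  # canonicalize and validate every generalized cell, naming the row on error
  for (nm in qia_names(schema)) {
    out[[nm]] <- map_chr(seq_len(nrow(out)), function(i) {
      tryCatch(format_gen_value(parse_gen_value(out[[nm]][i], nm, schema)),
               error = function(e) {
                 abort(sprintf("%s: row %d (CaseID %s): %s",
                               path, i, out$CaseID[i], conditionMessage(e)))
               })
    })
  }
  check_group_consistency(out, schema, where = path)
  as_tibble(out)
}

#' @rdname read_release
#' @export
read_release_series <- function(paths, schema) {
  map(paths, read_release, schema = schema)
}

#' @rdname read_release
#' @export
write_release <- function(release, path) {
  readr::write_csv(release, path, progress = FALSE)
  invisible(path)
}

check_group_consistency <- function(release, schema, where = "release") {
  qn <- qia_names(schema)
  bad <- release |>
    group_by(.data$Group) |>
    summarise(n_tuples = n_distinct(across(all_of(qn))), .groups = "drop") |>
    filter(.data$n_tuples > 1L)
  if (nrow(bad) > 0L) {
    abort(sprintf("%s: group %d mixes distinct generalized tuples",
                  where, bad$Group[1L]))
  }
  invisible(release)
}

# parse a release into span representation: CaseID, Group, span cols, sa list-cols
release_spans <- function(release, schema) {
  spans <- map(seq_len(nrow(release)), function(i) {
    tuple_to_span(as.list(release[i, qia_names(schema)]), schema)
  })
  spans <- bind_rows(spans)
  out <- bind_cols(tibble(CaseID = release$CaseID, Group = release$Group), spans)
  for (sa in schema$sensitive) {
    out[[sa]] <- map(release[[sa]], function(s) {
      codes <- trimws(strsplit(as.character(s), schema$sa_sep, fixed = TRUE)[[1L]])
      unique(codes[nzchar(codes)])
    })
  }
  out
}

# join sensitive list-columns back into delimited text cells
sa_to_text <- function(x, sep) map_chr(x, paste, collapse = sep)
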