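# MDBASE-style data layer: per-liner record schema with controlled
# vocabularies, row-level validation, multi-file merge with collision
# detection, and predicate filtering.

SCHEMA_VERSION <- "1.0"

VOCAB <- list(
  joint = c("THR", "TKR"),
  crosslinking = c("none", "HXL"),
  thermal_treatment = c("none", "annealed", "remelted", "unknown"),
  sterilization = c("HCHO", "gIRR", "EtO", "gas_plasma", "unknown"),
  failure_reason = c("wear", "mechanical", "infection", "other")
)

INDEX_COLUMNS <- c(
  "OI(max,U)", "OI(max,W)", "OI(max,UW)",
  "OI(ave,U)", "OI(ave,W)", "OI(ave,UW)",
  "VI(ave,U)", "VI(ave,W)", "VI(ave,UW)",
  "CI(max,U)", "CI(max,W)", "CI(max,UW)",
  "CI(ave,U)", "CI(ave,W)", "CI(ave,UW)"
)

HV_COLUMNS <- c("HV(max,U)", "HV(max,W)", "HV(max,UW)",
                "HV(ave,U)", "HV(ave,W)", "HV(ave,UW)")

#' Per-liner record schema of the retrieval database
#'
#' Column set of the standardized data-entry template: identification,
#' anonymized patient data, manufacturer (material) data, surgical data,
#' the 15 standardized IR indexes and the 6 per-liner Vickers hardness
#' values. The mandatory columns must be present in every template file;
#' all others may be empty.
#'
#' @return Data frame with columns `column`, `type` and `mandatory`.
#' @export
retrieval_schema <- function() {
  base <- data.frame(
    column = c("liner_id", "country", "joint", "implantation_year",
               "in_vivo_months", "patient_age_at_implant", "patient_bmi",
               "patient_weight", "crosslinking", "radiation_dose",
               "thermal_treatment", "sterilization", "failure_reason"),
    type = c("character", "character", "enum", "numeric", "numeric",
             "numeric", "numeric", "numeric", "enum", "numeric", "enum",
             "enum", "enum"),
    mandatory = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  extra <- data.frame(column = c(INDEX_COLUMNS, HV_COLUMNS),
                      type = "numeric", mandatory = FALSE,
                      stringsAsFactors = FALSE)
  rbind(base, extra)
}

# numeric sanity ranges (min, max); NA fields are allowed unless mandatory
NUMERIC_RANGES <- list(
  implantation_year = c(1950, 2035),
  in_vivo_months = c(0, 720),
  patient_age_at_implant = c(0, 120),
  patient_bmi = c(10, 80),
  patient_weight = c(20, 250),
  radiation_dose = c(0, 300)
)

#' Validate one liner record
#'
#' Checks a record against the schema: non-empty unique identifier,
#' controlled vocabularies, numeric sanity ranges, index bounds (all
#' indexes >= 0, CI < 1). Every violated invariant is reported, not only
#' the first; validation itself never raises.
#'
#' @param rec A one-row data frame or named list.
#' @return Character vector of violations (`"field: reason"`), empty when
#'   the record is valid.
#' @export
validate_record <- function(rec) {
  rec <- as.list(rec)
  v <- character(0)
  note <- function(field, why) v <<- c(v, paste0(field, ": ", why))
  id <- rec$liner_id
  if (is.null(id) || is.na(id) || !nzchar(as.character(id))) {
    note("liner_id", "must be non-empty")
  }
  for (f in names(VOCAB)) {
    x <- rec[[f]]
    if (!is.null(x) && !is.na(x) && !(x %in% VOCAB[[f]])) {
      note(f, sprintf("value '%s' not in vocabulary {%s}", x,
                      paste(VOCAB[[f]], collapse = ", ")))
    }
  }
  for (f in names(NUMERIC_RANGES)) {
    x <- suppressWarnings(as.numeric(rec[[f]]))
    if (!is.null(rec[[f]]) && length(x) == 1L && !is.na(x)) {
      r <- NUMERIC_RANGES[[f]]
      if (x < r[1] || x > r[2]) {
        note(f, sprintf("value %g outside sanity range [%g, %g]", x, r[1], r[2]))
      }
    }
  }
  for (f in intersect(c(INDEX_COLUMNS, HV_COLUMNS), names(rec))) {
    x <- suppressWarnings(as.numeric(rec[[f]]))
    if (length(x) == 1L && !is.na(x)) {
      if (x < 0) note(f, "index values must be >= 0")
      if (startsWith(f, "CI(") && x >= 1) note(f, "CI must be < 1")
    }
  }
  v
}

#' Retrieval database container
#'
#' Wraps a validated record table together with its provenance (source
#' names and record counts) and a schema version.
#'
#' @param records Data frame of liner records (schema columns; missing
#'   optional columns are added as NA).
#' @param source Provenance label(s) for these records.
#' @param schema_version Schema version string.
#' @return An object of class `retrieval_db`.
#' @export
retrieval_db <- function(records, source = "in-memory",
                         schema_version = SCHEMA_VERSION) {
  sch <- retrieval_schema()
  miss_mand <- setdiff(sch$column[sch$mandatory], names(records))
  if (length(miss_mand)) {
    stop("missing mandatory column(s): ", paste(miss_mand, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(sch$column, names(records))) records[[col]] <- NA
  records <- records[, sch$column]
  if (anyDuplicated(records$liner_id)) {
    dup <- unique(records$liner_id[duplicated(records$liner_id)])
    stop("duplicate liner_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- lapply(seq_len(nrow(records)), function(i) validate_record(records[i, ]))
  nbad <- vapply(bad, length, integer(1))
  if (any(nbad > 0)) {
    i <- which(nbad > 0)[1]
    stop(sprintf("record %s violates schema invariants: %s",
                 records$liner_id[i], paste(bad[[i]], collapse = "; ")),
         call. = FALSE)
  }
  records <- records[order(records$liner_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 provenance = data.frame(source = source,
                                         n_records = nrow(records),
                                         stringsAsFactors = FALSE),
                 schema_version = schema_version),
            class = "retrieval_db")
}

#' @export
print.retrieval_db <- function(x, ...) {
  cat(sprintf("<retrieval_db> %d records (schema %s) from %d source(s)\n",
              nrow(x$records), x$schema_version, nrow(x$provenance)))
  invisible(x)
}

#' Load a data-entry template file
#'
#' Reads one participant's template (CSV or .xlsx) into liner records. Rows
#' that fail validation are reported with their row number and reason and
#' excluded; they are never silently dropped. Missing optional columns are
#' allowed; missing mandatory columns abort the load.
#'
#' @param path Path to a `.csv` or `.xlsx` template file.
#' @return List with `records` (data frame of valid rows, schema columns)
#'   and `issues` (data frame with `row`, `liner_id`, `reason`).
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path), check.names = FALSE,
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  sch <- retrieval_schema()
  miss_mand <- setdiff(sch$column[sch$mandatory], names(df))
  if (length(miss_mand)) {
    stop("template is missing mandatory column(s): ",
         paste(miss_mand, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(sch$column, names(df))) df[[col]] <- NA
  df <- df[, sch$column]
  issues <- data.frame(row = integer(0), liner_id = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    viol <- validate_record(df[i, ])
    if (length(viol)) {
      issues <- rbind(issues, data.frame(
        row = i, liner_id = as.character(df$liner_id[i]),
        reason = paste(viol, collapse = "; "), stringsAsFactors = FALSE))
    } else {
      keep[i] <- TRUE
    }
  }
  list(records = df[keep, , drop = FALSE], issues = issues, source = basename(path))
}

#' Merge record tables into one database
#'
#' Combines any number of per-participant tables (results of [load_table()],
#' plain record data frames or `retrieval_db` objects) into one database.
#' Record counts are additive; a `liner_id` occurring in more than one
#' input is an error listing the collisions; the output is canonically
#' ordered by `liner_id`, so merging is input-order invariant.
#'
#' @param tables List of inputs as described above.
#' @return A [retrieval_db()] with per-source provenance.
#' @export
merge_databases <- function(tables) {
  if (!is.list(tables) || length(tables) < 1L) {
    stop("need at least one table to merge", call. = FALSE)
  }
  as_records <- function(x, i) {
    if (inherits(x, "retrieval_db")) {
      list(records = x$records, source = paste(x$provenance$source, collapse = "+"))
    } else if (is.list(x) && !is.data.frame(x) && !is.null(x$records)) {
      list(records = x$records, source = x$source %||% paste0("table", i))
    } else if (is.data.frame(x)) {
      list(records = x, source = paste0("table", i))
    } else {
      stop("table ", i, " is not a record table", call. = FALSE)
    }
  }
  parts <- lapply(seq_along(tables), function(i) as_records(tables[[i]], i))
  sch <- retrieval_schema()
  recs <- lapply(parts, function(p) {
    df <- p$records
    for (col in setdiff(sch$column, names(df))) df[[col]] <- NA
    df[, sch$column]
  })
  all_ids <- unlist(lapply(recs, `[[`, "liner_id"))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup)) {
    stop("duplicate liner_id across inputs: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  combined <- do.call(rbind, recs)
  db <- retrieval_db(combined, source = "merge")
  db$provenance <- data.frame(
    source = vapply(parts, `[[`, character(1), "source"),
    n_records = vapply(recs, nrow, integer(1)),
    stringsAsFactors = FALSE)
  db
}

backtick_columns <- function(expr_string, columns) {
  # longest names first so e.g. OI(max,UW) is quoted before OI(max,U)
  for (col in columns[order(-nchar(columns))]) {
    if (grepl("[^A-Za-z0-9_.]", col)) {
      expr_string <- gsub(col, paste0("`", col, "`"), expr_string, fixed = TRUE)
    }
  }
  expr_string
}

#' Filter a database with a predicate over schema fields
#'
#' Subsets a database by a predicate expression over schema columns, e.g.
#' `"OI(max,UW) <= 4"` (the exclusion used when extremely oxidized liners
#' distort correlation structure) or `"sterilization == 'gIRR'"`. The
#' predicate may be given as a string (column names are quoted
#' automatically) or as an unevaluated R expression. Rows where the
#' predicate is NA (missing fields) are excluded. The applied filter and
#' the before/after counts are recorded in the provenance.
#'
#' @param db A [retrieval_db()].
#' @param predicate Predicate string or expression.
#' @return Filtered `retrieval_db`.
#' @export
filter_database <- function(db, predicate) {
  stopifnot(inherits(db, "retrieval_db"))
  cols <- names(db$records)
  expr <- if (is.character(predicate)) {
    str2lang(backtick_columns(predicate, cols))
  } else if (is.call(predicate) || is.name(predicate)) {
    predicate
  } else {
    stop("predicate must be a string or an expression", call. = FALSE)
  }
  used <- all.vars(expr)
  unknown <- setdiff(used, cols)
  if (length(unknown)) {
    stop("predicate references unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- eval(expr, db$records, baseenv())
  if (!is.logical(keep) || !(length(keep) %in% c(1L, nrow(db$records)))) {
    stop("predicate must evaluate to a logical vector over records", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  if (length(keep) == 1L) keep <- rep(keep, nrow(db$records))
  out <- db
  out$records <- db$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$provenance <- rbind(
    db$provenance,
    data.frame(source = sprintf("filter[%s]: %d -> %d",
                                paste(deparse(expr), collapse = " "),
                                nrow(db$records), sum(keep)),
               n_records = sum(keep), stringsAsFactors = FALSE))
  out
}

#' Write a database's record table to CSV
#'
#' @param db A [retrieval_db()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_database_csv <- function(db, path) {
  stopifnot(inherits(db, "retrieval_db"))
  utils::write.csv(db$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export provenance and issues as JSON
#'
#' @param db A [retrieval_db()].
#' @param path Output JSON path.
#' @param issues Optional issue report from [load_table()].
#' @return `path`, invisibly.
#' @export
write_provenance_json <- function(db, path, issues = NULL) {
  stopifnot(inherits(db, "retrieval_db"))
  x <- list(schema_version = db$schema_version, provenance = db$provenance)
  if (!is.null(issues)) x$issues <- issues
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
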