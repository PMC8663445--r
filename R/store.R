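#' Build an anonymized evaluation record
#'
#' The audit row persisted after a completed assessment: the answers, the
#' engine's top-ranked differential, the user's selection (if any), the
#' risk-score total and class, and the recommendation keys shown. The
#' schema carries no patient identifiers — anonymity is structural. The
#' `hypothetical` flag lets users mark test entries so they can be excluded
#' from the congruence report.
#'
#' @param assessment A `syncope_assessment`.
#' @param record_id Opaque record id; a random hex id when omitted.
#' @param timestamp ISO-8601 timestamp string; current UTC time when
#'   omitted.
#' @param hypothetical Mark the record as a hypothetical (test) entry.
#' @return A `syncope_record` list.
#' @export
evaluation_record <- function(assessment, record_id = NULL, timestamp = NULL,
                              hypothetical = FALSE) {
  stopifnot(inherits(assessment, "syncope_assessment"))
  if (is.null(record_id)) {
    record_id <- paste0(
      format(as.hexmode(sample.int(.Machine$integer.max, 4)), width = 8),
      collapse = "")
  }
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  rec_keys <- tidy.syncope_recommendations(assessment$recommendations)
  structure(
    list(
      record_id = record_id,
      timestamp = timestamp,
      answers = as.list(assessment$answers$answers),
      user_selected_ddx = assessment$answers$user_selected_ddx,
      app_top = app_top(assessment$differential),
      css_total = assessment$css$total,
      risk_class = assessment$css$risk_class,
      recommendation_keys = paste(rec_keys$category, rec_keys$key,
                                  sep = ":"),
      hypothetical = isTRUE(hypothetical)
    ),
    class = "syncope_record"
  )
}

#' Append a record to the evaluation store
#'
#' The store is an append-only JSON Lines file, one record per line
#' (schema under `inst/schema/record.schema.json`). Before writing, the
#' record's `app_top` and `css_total` are recomputed from its answers
#' against the knowledge base; a mismatch raises an integrity error rather
#' than persisting an inconsistent row.
#'
#' @param path Store file path (created if absent).
#' @param record A `syncope_record`.
#' @param kb The `syncope_kb` to verify consistency against.
#' @return `path`, invisibly.
#' @export
append_record <- function(path, record, kb = load_knowledge_base()) {
  stopifnot(inherits(record, "syncope_record"))
  answers <- as_answer_set(record$answers,
                           user_selected_ddx = record$user_selected_ddx)
  redo <- assess(answers, kb)
  if (!identical(app_top(redo$differential), record$app_top) ||
      !identical(redo$css$total, as.integer(record$css_total))) {
    stop("integrity error: record '", record$record_id,
         "' disagrees with recomputation (app_top/css_total)",
         call. = FALSE)
  }
  line <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE,
                           null = "null", digits = NA)
  con <- tryCatch(suppressWarnings(file(path, open = "a")),
                  error = function(e) stop("cannot open store for append: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  ok <- tryCatch({ writeLines(line, con); TRUE },
                 error = function(e) stop("cannot write to store '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  invisible(path)
}

#' Read an evaluation store
#'
#' @param path JSON Lines store path.
#' @return List of `syncope_record` objects, in append order.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop("evaluation store not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    rec$answers <- lapply(rec$answers, as.character)
    rec$recommendation_keys <- as.character(unlist(rec$recommendation_keys))
    rec$css_total <- as.integer(rec$css_total)
    rec$hypothetical <- isTRUE(rec$hypothetical)
    structure(rec, class = "syncope_record")
  })
}

#' Tabulate evaluation records
#'
#' @param records List of `syncope_record` objects (from [read_records()]).
#' @return A tibble with one row per record.
#' @export
records_tibble <- function(records) {
  purrr::map_dfr(records, function(r) {
    tibble::tibble(
      record_id = r$record_id,
      timestamp = r$timestamp,
      app_top = r$app_top,
      user_selected_ddx = r$user_selected_ddx %||% NA_character_,
      css_total = r$css_total,
      risk_class = r$risk_class,
      hypothetical = r$hypothetical
    )
  })
}

#' App-vs-user congruence report
#'
#' The feedback metric of the evaluation loop: among logged assessments
#' where the clinician selected a diagnosis, the fraction in which the
#' engine's top-ranked etiology matched that selection. `restrict_to`
#' filters on the *user-selected* etiology (e.g.
#' `c("cardiogenic", "vasovagal")` restricts the metric to the two
#' best-supported etiologies). Hypothetical (test) records are excluded by
#' default. With zero eligible records an explicit empty report is
#' returned rather than a division error.
#'
#' @param records List of `syncope_record` objects, or a store path.
#' @param restrict_to Optional character vector of etiology ids to filter
#'   the user selections on.
#' @param include_hypothetical Include records flagged hypothetical.
#' @return A `syncope_congruence` one-row tibble: `fraction` (NA when no
#'   record is eligible), `n_concordant`, `n_eligible`, `n_records`.
#' @export
#' @examples
#' congruence_report(list())  # empty report
congruence_report <- function(records, restrict_to = NULL,
                              include_hypothetical = FALSE) {
  if (is.character(records) && length(records) == 1) {
    records <- read_records(records)
  }
  n_records <- length(records)
  if (!include_hypothetical) {
    records <- purrr::discard(records, ~ isTRUE(.x$hypothetical))
  }
  has_user <- purrr::keep(records, ~ !is.null(.x$user_selected_ddx))
  if (!is.null(restrict_to)) {
    has_user <- purrr::keep(has_user,
                            ~ .x$user_selected_ddx %in% restrict_to)
  }
  n_eligible <- length(has_user)
  n_concordant <- sum(vapply(has_user, function(r)
    identical(r$app_top, r$user_selected_ddx), logical(1)))
  out <- tibble::tibble(
    fraction = if (n_eligible == 0) NA_real_ else n_concordant / n_eligible,
    n_concordant = as.integer(n_concordant),
    n_eligible = as.integer(n_eligible),
    n_records = as.integer(n_records)
  )
  class(out) <- c("syncope_congruence", class(out))
  out
}

#' @export
print.syncope_congruence <- function(x, ...) {
  if (is.na(x$fraction)) {
    cat("Congruence report: no eligible records (", x$n_records,
        " total)\n", sep = "")
  } else {
    cat("Congruence report: ", x$n_concordant, "/", x$n_eligible,
        " concordant (", sprintf("%.1f%%", 100 * x$fraction), ") of ",
        x$n_records, " records\n", sep = "")
  }
  invisible(x)
}
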