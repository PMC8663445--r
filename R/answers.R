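#' Construct an answer set for one patient encounter
#'
#' An answer set records the yes/no/unknown responses to the assessment
#' questions, plus the clinician's own top differential when one was
#' selected. Questions not mentioned are treated as `unknown` and contribute
#' no evidence, so partially completed assessments still yield a
#' differential.
#'
#' @param ... Named answers, e.g. `age_le_35 = "yes"`; each value one of
#'   `"yes"`, `"no"`, `"unknown"`.
#' @param user_selected_ddx Optional etiology id the clinician selected as
#'   their top differential (see [syncope_etiologies()]).
#' @return A `syncope_answers` object.
#' @export
#' @examples
#' answer_set(age_le_35 = "yes", trigger_context = "yes",
#'            user_selected_ddx = "vasovagal")
answer_set <- function(..., user_selected_ddx = NULL) {
  vals <- list(...)
  as_answer_set(vals, user_selected_ddx = user_selected_ddx)
}

#' Coerce a named list or vector to an answer set
#'
#' @param x Named character vector or named list of `"yes"`/`"no"`/
#'   `"unknown"` values keyed by question id.
#' @param user_selected_ddx Optional etiology id.
#' @return A `syncope_answers` object.
#' @export
as_answer_set <- function(x, user_selected_ddx = NULL) {
  vals <- unlist(x) %||% character()
  if (length(vals) > 0 &&
      (is.null(names(vals)) || any(!nzchar(names(vals))))) {
    stop("answers must be named by question id", call. = FALSE)
  }
  if (anyDuplicated(names(vals))) {
    stop("at most one answer per question: duplicate id '",
         names(vals)[duplicated(names(vals))][1], "'", call. = FALSE)
  }
  bad <- setdiff(unique(vals), c("yes", "no", "unknown"))
  if (length(bad) > 0) {
    stop("answer values must be 'yes', 'no' or 'unknown' (got '",
         bad[1], "')", call. = FALSE)
  }
  if (!is.null(user_selected_ddx) &&
      !(user_selected_ddx %in% syncope_etiologies())) {
    stop("user_selected_ddx must be one of: ",
         paste(syncope_etiologies(), collapse = ", "), call. = FALSE)
  }
  structure(
    list(answers = vals, user_selected_ddx = user_selected_ddx),
    class = "syncope_answers"
  )
}

#' Read a case file
#'
#' A case file is a JSON document with an `answers` object mapping question
#' ids to `"yes"`/`"no"`/`"unknown"` and an optional `user_selected_ddx`
#' (schema shipped under `inst/schema/case.schema.json`).
#'
#' @param path Path to a case JSON file.
#' @return A `syncope_answers` object.
#' @export
read_case <- function(path) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("case parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.list(raw) || !("answers" %in% names(raw))) {
    stop("case file '", path, "' must contain an 'answers' object",
         call. = FALSE)
  }
  as_answer_set(raw$answers, user_selected_ddx = raw$user_selected_ddx)
}

#' Write a case file
#'
#' @param answers A `syncope_answers` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_case <- function(answers, path) {
  out <- list(answers = as.list(answers$answers))
  if (!is.null(answers$user_selected_ddx)) {
    out$user_selected_ddx <- answers$user_selected_ddx
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Check an answer set against a knowledge base; errors on unknown ids.
validate_answers <- function(answers, kb) {
  stopifnot(inherits(answers, "syncope_answers"))
  bad <- setdiff(names(answers$answers), names(kb$questions))
  if (length(bad) > 0) {
    stop("answer references unknown question id(s): ",
         paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  }
  invisible(answers)
}

# Answer value for one question: "yes", "no", or "unknown" (also for
# questions with no recorded answer).
answer_value <- function(answers, question_id) {
  if (!question_id %in% names(answers$answers)) return("unknown")
  unname(answers$answers[[question_id]])
}

#' @exportS3Method tibble::as_tibble
as_tibble.syncope_answers <- function(x, ...) {
  tibble::tibble(
    question_id = names(x$answers),
    value = unname(x$answers)
  )
}

#' @export
print.syncope_answers <- function(x, ...) {
  n <- length(x$answers)
  cat("<syncope_answers> ", n, " recorded answer", if (n == 1) "" else "s",
      " (", sum(x$answers == "yes"), " yes, ", sum(x$answers == "no"),
      " no, ", sum(x$answers == "unknown"), " unknown)\n", sep = "")
  if (!is.null(x$user_selected_ddx)) {
    cat("  user-selected differential: ", x$user_selected_ddx, "\n", sep = "")
  }
  invisible(x)
}
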