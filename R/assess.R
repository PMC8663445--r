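#' Run a full syncope assessment
#'
#' The end-to-end pipeline for one encounter, mirroring the four steps of a
#' bedside evaluation: compute the ranked differential
#' ([compute_differential()]), resolve the working diagnosis
#' ([resolve_diagnosis()]), score and classify risk ([compute_css()]), and
#' assemble the recommendation bundle ([build_recommendations()]).
#'
#' @param answers A `syncope_answers` object.
#' @param kb A `syncope_kb` (the packaged default if omitted).
#' @return A `syncope_assessment` holding `differential`, `css`,
#'   `recommendations`, and the input `answers`.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' assess(answer_set(age_le_35 = "yes", trigger_context = "yes"), kb)
assess <- function(answers, kb = load_knowledge_base()) {
  validate_answers(answers, kb)
  differential <- compute_differential(answers, kb)
  diag <- resolve_diagnosis(answers, differential)
  css <- compute_css(answers, diag$etiology, kb,
                     diagnosis_source = diag$source)
  recommendations <- build_recommendations(differential, answers, css, kb)
  structure(
    list(answers = answers, differential = differential, css = css,
         recommendations = recommendations, kb_version = kb$version),
    class = "syncope_assessment"
  )
}

#' @export
print.syncope_assessment <- function(x, ...) {
  cat("== Assessment ==\n")
  print(x$answers)
  cat("\n== Differential Diagnosis ==\n")
  print(x$differential)
  if (!is.null(x$answers$user_selected_ddx)) {
    concord <- identical(x$answers$user_selected_ddx, app_top(x$differential))
    cat("user selection ", if (concord) "concordant" else "discordant",
        " with the engine's top rank\n", sep = "")
  }
  cat("\n== Risk Stratification ==\n")
  print(x$css)
  cat("\n== Recommendations ==\n")
  print(x$recommendations)
  invisible(x)
}

#' @rdname glance.syncope_assessment
#' @exportS3Method generics::tidy
tidy.syncope_assessment <- function(x, ...) {
  tidy.syncope_differential(x$differential)
}

#' Summarise an assessment
#'
#' `glance()` gives a one-row tibble (top etiology, user selection, score
#' total, risk class); `tidy()` returns the differential rows.
#'
#' @param x A `syncope_assessment`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.syncope_assessment <- function(x, ...) {
  tibble::tibble(
    app_top = app_top(x$differential),
    user_selected_ddx = x$answers$user_selected_ddx %||% NA_character_,
    diagnosis_used = x$css$diagnosis_used,
    css_total = x$css$total,
    risk_class = x$css$risk_class,
    any_override = any(x$differential$overridden)
  )
}

# Serializable view of an assessment, used by the CLI's JSON output.
assessment_to_list <- function(x) {
  diff_df <- as.data.frame(tidy.syncope_differential(x$differential))
  rec <- x$recommendations
  list(
    differential = diff_df,
    app_top = app_top(x$differential),
    user_selected_ddx = x$answers$user_selected_ddx,
    css = list(
      items = as.data.frame(x$css$items),
      total = x$css$total,
      risk_class = x$css$risk_class,
      diagnosis_used = x$css$diagnosis_used,
      diagnosis_source = x$css$diagnosis_source
    ),
    recommendations = list(
      primary = rec$primary,
      secondary = rec$secondary,
      question_specific = as.data.frame(rec$question_specific),
      disposition = rec$disposition
    )
  )
}
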