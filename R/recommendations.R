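#' Assemble the recommendation bundle
#'
#' Four pieces, mirroring the final screen of a syncope evaluation:
#'
#' * **primary** — keyed by the resolved diagnosis ([resolve_diagnosis()]):
#'   the user's selection when one exists, else the engine's top rank.
#' * **secondary** — present only when the engine's top-ranked etiology is
#'   discordant with an existing user selection; keyed by the ordered pair
#'   (app top, user choice).
#' * **question-specific** — one entry per triggering question: for each
#'   override etiology whose flagged questions were answered yes in part
#'   (at least one, but not all — all-yes fires the rank override
#'   instead), and for every prompt-only question answered yes.
#' * **disposition** — the risk-class text (discharge / short observation
#'   of six hours or less / admission).
#'
#' @param differential A `syncope_differential`.
#' @param answers The `syncope_answers` the differential was computed from.
#' @param css The `syncope_css` for the same encounter.
#' @param kb A `syncope_kb`.
#' @return A `syncope_recommendations` object.
#' @export
build_recommendations <- function(differential, answers, css, kb) {
  rec <- kb$recommendations
  diag <- resolve_diagnosis(answers, differential)
  primary <- list(etiology = diag$etiology,
                  text = rec$primary[[diag$etiology]])
  if (is.null(primary$text)) {
    stop("no primary recommendation text configured for '", diag$etiology,
         "'", call. = FALSE)
  }

  secondary <- NULL
  user <- answers$user_selected_ddx
  top <- app_top(differential)
  if (!is.null(user) && !identical(user, top)) {
    key <- paste(top, user, sep = "|")
    txt <- rec$secondary[[key]]
    if (is.null(txt)) {
      stop("no secondary recommendation text configured for discordant ",
           "pair ", key, call. = FALSE)
    }
    secondary <- list(app = top, user = user, text = txt)
  }

  qs <- question_specific_triggers(answers, kb)
  qs_text <- vapply(qs, function(qid) {
    txt <- rec$question_specific[[qid]]
    if (is.null(txt)) {
      stop("no question-specific recommendation text configured for '",
           qid, "'", call. = FALSE)
    }
    txt
  }, character(1))
  question_specific <- tibble::tibble(
    question_id = qs,
    text = unname(qs_text)
  )

  disposition <- list(risk_class = css$risk_class,
                      text = disposition_for_risk(css$risk_class, kb))

  structure(
    list(primary = primary, secondary = secondary,
         question_specific = question_specific, disposition = disposition),
    class = "syncope_recommendations"
  )
}

# Question ids triggering a question-specific recommendation: override
# etiologies with a partial yes pattern, plus prompt-only yes answers.
question_specific_triggers <- function(answers, kb) {
  qt <- kb_questions(kb)
  out <- character()
  for (et in unique(stats::na.omit(qt$override_for))) {
    qids <- qt$id[!is.na(qt$override_for) & qt$override_for == et]
    yes <- qids[vapply(qids, function(q) answer_value(answers, q) == "yes",
                       logical(1))]
    if (length(yes) >= 1 && length(yes) < length(qids)) {
      out <- c(out, yes)
    }
  }
  prompt <- qt$id[qt$prompt_only]
  out <- c(out, prompt[vapply(prompt, function(q)
    answer_value(answers, q) == "yes", logical(1))])
  # deterministic order: knowledge-base question order
  intersect(qt$id, out)
}

#' Disposition text for a risk class
#'
#' @param risk_class One of `"low"`, `"intermediate"`, `"high"`.
#' @param kb A `syncope_kb`.
#' @return The configured disposition text. The packaged defaults encode:
#'   discharge from the ED with outpatient workup (low), short-term
#'   observation of 6 hours or less (intermediate), longer-term observation
#'   and admission (high).
#' @export
disposition_for_risk <- function(risk_class, kb = load_knowledge_base()) {
  risk_class <- match.arg(risk_class, c("low", "intermediate", "high"))
  kb$recommendations$disposition[[risk_class]]
}

#' @export
print.syncope_recommendations <- function(x, ...) {
  cat("Recommendations\n")
  cat("  primary [", x$primary$etiology, "]: ", x$primary$text, "\n",
      sep = "")
  if (!is.null(x$secondary)) {
    cat("  secondary [app ", x$secondary$app, " vs user ", x$secondary$user,
        "]: ", x$secondary$text, "\n", sep = "")
  }
  if (nrow(x$question_specific) > 0) {
    for (i in seq_len(nrow(x$question_specific))) {
      cat("  question-specific [", x$question_specific$question_id[i],
          "]: ", x$question_specific$text[i], "\n", sep = "")
    }
  }
  cat("  disposition [", x$disposition$risk_class, " risk]: ",
      x$disposition$text, "\n", sep = "")
  invisible(x)
}

#' Tidy a recommendation bundle
#'
#' One row per recommendation, in a long tibble with columns `category`
#' (`primary`, `secondary`, `question_specific`, `disposition`), `key`
#' (etiology, discordant pair, question id, or risk class) and `text`.
#'
#' @param x A `syncope_recommendations`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.syncope_recommendations <- function(x, ...) {
  rows <- list(
    tibble::tibble(category = "primary", key = x$primary$etiology,
                   text = x$primary$text)
  )
  if (!is.null(x$secondary)) {
    rows <- c(rows, list(tibble::tibble(
      category = "secondary",
      key = paste(x$secondary$app, x$secondary$user, sep = "|"),
      text = x$secondary$text
    )))
  }
  if (nrow(x$question_specific) > 0) {
    rows <- c(rows, list(tibble::tibble(
      category = "question_specific",
      key = x$question_specific$question_id,
      text = x$question_specific$text
    )))
  }
  rows <- c(rows, list(tibble::tibble(
    category = "disposition", key = x$disposition$risk_class,
    text = x$disposition$text
  )))
  dplyr::bind_rows(rows)
}
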