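#' Convert log-odds to a probability
#'
#' The inverse-logit transform, `1 / (1 + exp(-log_odds))`; strictly
#' increasing in its argument.
#'
#' @param log_odds Finite numeric vector of natural-log odds.
#' @return Probabilities in (0,1).
#' @export
#' @examples
#' probability_from_log_odds(0)        # 0.5
#' probability_from_log_odds(log(3))   # 0.75
probability_from_log_odds <- function(log_odds) {
  if (!is.numeric(log_odds) || any(!is.finite(log_odds))) {
    stop("log_odds must be finite numeric", call. = FALSE)
  }
  stats::plogis(log_odds)
}

#' Posttest log-odds of one etiology
#'
#' Accumulates likelihood-ratio evidence on the log-odds scale: starting
#' from the pretest log-odds `log(prior / (1 - prior))`, each answered
#' question with a likelihood-ratio pair for the etiology contributes
#' `log(LHR+)` for a yes and `log(LHR-)` for a no. Questions answered
#' unknown, prompt-only questions, and absent likelihood-ratio cells
#' contribute nothing (a factor of 1 on the odds scale). Equivalent to
#' multiplying the pretest odds by the product of the answered findings'
#' likelihood ratios.
#'
#' @param prior Pretest probability in the open interval (0,1).
#' @param answers A `syncope_answers` object.
#' @param kb A `syncope_kb`.
#' @param etiology One of [syncope_etiologies()].
#' @return The posttest log-odds (natural log, dimensionless).
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' posttest_log_odds(0.35, answer_set(age_le_35 = "yes"), kb, "vasovagal")
posttest_log_odds <- function(prior, answers, kb, etiology) {
  if (!is.numeric(prior) || length(prior) != 1 || is.na(prior) ||
      prior <= 0 || prior >= 1) {
    stop("prior must lie in the open interval (0,1)", call. = FALSE)
  }
  etiology <- match.arg(etiology, syncope_etiologies())
  validate_answers(answers, kb)
  lo <- log(prior / (1 - prior))
  # stable summation order: knowledge-base question order
  for (q in kb$questions) {
    cell <- q$lhr[[etiology]]
    if (is.null(cell)) next
    a <- answer_value(answers, q$id)
    if (a == "yes") lo <- lo + log(cell$lhr_pos)
    else if (a == "no") lo <- lo + log(cell$lhr_neg)
  }
  lo
}

# Alternative parameterization of the same logistic model: an intercept
# absorbing the negative-finding baseline plus per-question coefficients,
#   intercept = logit(prior) + sum over answered cells of log(lhr_neg)
#   beta_q    = log(lhr_pos / lhr_neg), x_q = 1 for yes, 0 for no.
# Must agree with posttest_log_odds() exactly (up to float roundoff); the
# test suite asserts the equality. Unknown answers drop out of both the
# intercept and the linear term.
posttest_log_odds_beta <- function(prior, answers, kb, etiology) {
  if (!is.numeric(prior) || length(prior) != 1 || is.na(prior) ||
      prior <= 0 || prior >= 1) {
    stop("prior must lie in the open interval (0,1)", call. = FALSE)
  }
  etiology <- match.arg(etiology, syncope_etiologies())
  validate_answers(answers, kb)
  intercept <- log(prior / (1 - prior))
  linear <- 0
  for (q in kb$questions) {
    cell <- q$lhr[[etiology]]
    if (is.null(cell)) next
    a <- answer_value(answers, q$id)
    if (a == "unknown") next
    intercept <- intercept + log(cell$lhr_neg)
    x <- as.numeric(a == "yes")
    linear <- linear + x * log(cell$lhr_pos / cell$lhr_neg)
  }
  intercept + linear
}

#' Apply the clinical-override weighting to a ranked differential
#'
#' Two etiologies (orthostatic and neurogenic loss of consciousness) have
#' sparse likelihood-ratio literature; the engine compensates by marking
#' each one overridden when *all* of its override-flagged questions were
#' answered yes, and ranking overridden etiologies above every
#' non-overridden one. Probabilities are never numerically altered — only
#' the rank changes. Among multiple overridden etiologies, and among equal
#' probabilities, the knowledge base's fixed risk-first precedence breaks
#' ties (default: neurogenic LOC, cardiogenic, orthostatic, vasovagal).
#'
#' @param posteriors A tibble with columns `etiology`, `log_odds`,
#'   `probability` for all four etiologies (as produced inside
#'   [compute_differential()]).
#' @param answers A `syncope_answers` object.
#' @param kb A `syncope_kb`.
#' @return The posteriors tibble with an `overridden` column, re-ranked, and
#'   a `rank` column (1 = top of the differential).
#' @export
apply_overrides <- function(posteriors, answers, kb) {
  stopifnot(setequal(posteriors$etiology, syncope_etiologies()))
  flagged <- kb_questions(kb)
  flagged <- flagged[!is.na(flagged$override_for), c("id", "override_for")]
  overridden_for <- function(et) {
    qids <- flagged$id[flagged$override_for == et]
    length(qids) > 0 &&
      all(vapply(qids, function(q) answer_value(answers, q) == "yes",
                 logical(1)))
  }
  posteriors$overridden <- vapply(posteriors$etiology, overridden_for,
                                  logical(1))
  prec <- match(posteriors$etiology, kb$tie_break_order)
  # overridden first; among overridden the risk-first precedence decides
  # (neurogenic LOC before orthostatic), otherwise probability, then
  # precedence for exact ties
  ord <- order(-posteriors$overridden, ifelse(posteriors$overridden, prec, 0),
               -posteriors$probability, prec)
  out <- posteriors[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Compute the ranked differential diagnosis
#'
#' Runs four independent binary models, one per etiology: the posttest
#' log-odds from [posttest_log_odds()], transformed to a probability, then
#' ranked after [apply_overrides()]. Probabilities are raw per-etiology
#' posteriors and are deliberately not renormalized across etiologies —
#' each model answers "how likely is this cause, given these findings"
#' on its own.
#'
#' @param answers A `syncope_answers` object.
#' @param kb A `syncope_kb` (the packaged default if omitted).
#' @return A `syncope_differential`: a tibble with columns `rank`,
#'   `etiology`, `log_odds`, `probability`, `overridden`, ordered rank 1
#'   first, with attribute `app_top` naming the top-ranked etiology.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' compute_differential(answer_set(trigger_context = "yes"), kb)
compute_differential <- function(answers, kb = load_knowledge_base()) {
  validate_answers(answers, kb)
  ets <- syncope_etiologies()
  lo <- vapply(ets, function(et)
    posttest_log_odds(kb$priors[[et]], answers, kb, et), numeric(1))
  posteriors <- tibble::tibble(
    etiology = ets,
    log_odds = unname(lo),
    probability = probability_from_log_odds(unname(lo))
  )
  ranked <- apply_overrides(posteriors, answers, kb)
  ranked <- ranked[, c("rank", "etiology", "log_odds", "probability",
                       "overridden")]
  structure(
    ranked,
    app_top = ranked$etiology[1],
    class = c("syncope_differential", class(ranked))
  )
}

#' Top-ranked etiology of a differential
#'
#' @param differential A `syncope_differential`.
#' @return The etiology id ranked first.
#' @export
app_top <- function(differential) {
  attr(differential, "app_top")
}

#' @export
print.syncope_differential <- function(x, ...) {
  cat("Differential diagnosis (rank 1 = most likely):\n")
  df <- as.data.frame(x)
  df$probability <- sprintf("%.4f", df$probability)
  df$note <- ifelse(df$overridden, "overridden to top", "")
  print(df[, c("rank", "etiology", "probability", "note")], row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.syncope_differential
#' @exportS3Method generics::glance
glance.syncope_differential <- function(x, ...) {
  tibble::tibble(
    app_top = app_top(x),
    top_probability = x$probability[1],
    any_override = any(x$overridden)
  )
}

#' Tidy a differential
#'
#' `tidy()` returns the per-etiology rows as a plain tibble; `glance()`
#' returns a one-row summary with the top-ranked etiology.
#'
#' @param x A `syncope_differential`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.syncope_differential <- function(x, ...) {
  tibble::as_tibble(unclass_differential(x))
}

unclass_differential <- function(x) {
  class(x) <- setdiff(class(x), "syncope_differential")
  attr(x, "app_top") <- NULL
  x
}

#' Plot a differential
#'
#' Bar chart of per-etiology posttest probabilities, overridden etiologies
#' highlighted.
#'
#' @param object A `syncope_differential`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.syncope_differential <- function(object, ...) {
  df <- tidy.syncope_differential(object)
  df$etiology <- stats::reorder(df$etiology, -df$rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$etiology,
                                   fill = .data$overridden)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick"),
                               name = "overridden") +
    ggplot2::labs(x = "posttest probability", y = NULL,
                  title = "Differential diagnosis") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
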