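#' Resolve the diagnosis feeding the risk score
#'
#' The Canadian Syncope Score includes two items driven by the clinician's
#' diagnostic impression. The user-selected differential is used whenever
#' one exists; the engine's top-ranked etiology is the fallback when the
#' user declined to pick.
#'
#' @param answers A `syncope_answers` object (carries `user_selected_ddx`).
#' @param differential A `syncope_differential`.
#' @return A list with `etiology` (the resolved diagnosis) and `source`
#'   (`"user"` or `"app"`).
#' @export
resolve_diagnosis <- function(answers, differential) {
  if (!is.null(answers$user_selected_ddx)) {
    list(etiology = answers$user_selected_ddx, source = "user")
  } else {
    list(etiology = app_top(differential), source = "app")
  }
}

#' Compute the Canadian Syncope Score
#'
#' Tallies the score's point items: question-sourced items trigger when
#' their source question was answered yes (unknown answers conservatively
#' do not trigger, and the untallied item remains visible in the itemized
#' output), and the two diagnosis-derived items trigger when the resolved
#' diagnosis is vasovagal (negative points) or cardiogenic (positive
#' points). The total is classified with [classify_risk()].
#'
#' @param answers A `syncope_answers` object.
#' @param diagnosis The resolved diagnosis etiology id (see
#'   [resolve_diagnosis()]).
#' @param kb A `syncope_kb`.
#' @param diagnosis_source `"user"` or `"app"`, recorded in the result.
#' @return A `syncope_css` object: itemized tally (`items` tibble with
#'   `name`, `source`, `points`, `triggered`), integer `total`,
#'   `risk_class` (`"low"`, `"intermediate"`, `"high"`), and the diagnosis
#'   used.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' compute_css(answer_set(troponin_elevated = "yes"), "cardiogenic", kb)
compute_css <- function(answers, diagnosis, kb, diagnosis_source = "user") {
  diagnosis <- match.arg(diagnosis, syncope_etiologies())
  validate_answers(answers, kb)
  items <- kb$css$items
  missing_q <- setdiff(items$source[!startsWith(items$source, "diagnosis:")],
                       names(kb$questions))
  if (length(missing_q) > 0) {
    stop("score item references missing question id(s): ",
         paste0("'", missing_q, "'", collapse = ", "), call. = FALSE)
  }
  triggered <- vapply(items$source, function(src) {
    if (src == "diagnosis:vasovagal") diagnosis == "vasovagal"
    else if (src == "diagnosis:cardiac") diagnosis == "cardiogenic"
    else answer_value(answers, src) == "yes"
  }, logical(1))
  items <- tibble::tibble(
    name = items$name, source = items$source,
    points = as.integer(items$points), triggered = unname(triggered)
  )
  total <- sum(items$points[items$triggered])
  structure(
    list(
      items = items,
      total = as.integer(total),
      risk_class = classify_risk(total, kb),
      diagnosis_used = diagnosis,
      diagnosis_source = diagnosis_source
    ),
    class = "syncope_css"
  )
}

#' Classify a risk score total
#'
#' The published cut points: low risk below 1, intermediate risk 1 to 3
#' inclusive, high risk above 3. With integer totals, "below 1" means 0 or
#' less.
#'
#' @param total Integer score total.
#' @param kb A `syncope_kb` (carries configurable cut points
#'   `low_below` and `high_above`).
#' @return One of `"low"`, `"intermediate"`, `"high"`.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' classify_risk(0, kb)  # "low"
#' classify_risk(2, kb)  # "intermediate"
#' classify_risk(4, kb)  # "high"
classify_risk <- function(total, kb = load_knowledge_base()) {
  if (!is.numeric(total) || length(total) != 1 || is.na(total) ||
      total != round(total)) {
    stop("total must be a single integer", call. = FALSE)
  }
  th <- kb$css$thresholds
  if (total < th$low_below) "low"
  else if (total > th$high_above) "high"
  else "intermediate"
}

#' @export
print.syncope_css <- function(x, ...) {
  cat("Canadian Syncope Score: total ", x$total, " -> ", x$risk_class,
      " risk\n", sep = "")
  cat("  diagnosis used: ", x$diagnosis_used, " (", x$diagnosis_source,
      ")\n", sep = "")
  df <- as.data.frame(x$items)
  df$tally <- ifelse(df$triggered, sprintf("%+d", df$points), ".")
  print(df[, c("name", "tally")], row.names = FALSE)
  invisible(x)
}

#' Tidy a risk-score result
#'
#' `tidy()` returns the itemized tally; `glance()` a one-row summary.
#'
#' @param x A `syncope_css`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.syncope_css <- function(x, ...) {
  x$items
}

#' @rdname tidy.syncope_css
#' @exportS3Method generics::glance
glance.syncope_css <- function(x, ...) {
  tibble::tibble(
    total = x$total,
    risk_class = x$risk_class,
    diagnosis_used = x$diagnosis_used,
    diagnosis_source = x$diagnosis_source,
    n_triggered = sum(x$items$triggered)
  )
}

#' Plot a risk-score tally
#'
#' @param object A `syncope_css`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.syncope_css <- function(object, ...) {
  df <- object$items
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = ifelse(.data$triggered, .data$points,
                                              0),
                                   y = .data$name,
                                   alpha = .data$triggered)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1),
                                name = "triggered") +
    ggplot2::labs(x = "points contributed", y = NULL,
                  title = paste0("Risk score: ", object$total, " (",
                                 object$risk_class, ")")) +
    ggplot2::theme_minimal()
}
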