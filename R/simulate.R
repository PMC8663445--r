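#' Configuration for the synthetic-case generator
#'
#' @param seed Integer seed; a single seeded generator drives everything
#'   and the seed is recorded in cohort output.
#' @param n Number of cases to generate.
#' @param mix Named numeric vector of etiology mix probabilities (summing
#'   to 1). Defaults to the knowledge base's priors renormalized at
#'   generation time.
#' @param unknown_rate Probability, in `[0, 1)`, that a question is left
#'   unanswered (marked unknown), independently per question.
#' @param neutral_rate Yes-rate used for questions whose
#'   likelihood-ratio cell under the true etiology is absent or not
#'   invertible to a sensitivity/specificity pair (default 0.2).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed, n, mix = NULL, unknown_rate = 0,
                             neutral_rate = 0.2) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(n), length(n) == 1, n >= 0,
            unknown_rate >= 0, unknown_rate < 1,
            neutral_rate > 0, neutral_rate < 1)
  if (!is.null(mix)) {
    if (is.null(names(mix)) ||
        !all(names(mix) %in% syncope_etiologies())) {
      stop("mix must be named by etiology id", call. = FALSE)
    }
    if (abs(sum(mix) - 1) > 1e-9) {
      stop("mix must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n = as.integer(n), mix = mix,
         unknown_rate = unknown_rate, neutral_rate = neutral_rate),
    class = "generator_config"
  )
}

#' Invert a likelihood-ratio pair to sensitivity and specificity
#'
#' Solves the defining identities `LHR+ = sens / (1 - spec)` and
#' `LHR- = (1 - sens) / spec` for the underlying 2x2 operating point:
#' `spec = (LHR+ - 1) / (LHR+ - LHR-)` and `sens = LHR+ * (1 - spec)`.
#' Only orientation-consistent informative pairs (`LHR+ > 1 > LHR- > 0`)
#' are invertible; for others a domain error is raised and the generator
#' falls back to its configured neutral yes-rate.
#'
#' @param lhr_pos Positive likelihood ratio (> 1).
#' @param lhr_neg Negative likelihood ratio (in (0, 1)).
#' @return A list with `sensitivity` and `specificity`, both in (0,1).
#' @export
#' @examples
#' sens_spec_from_lhr(3, 0.5)   # sensitivity 0.6, specificity 0.8
sens_spec_from_lhr <- function(lhr_pos, lhr_neg) {
  if (!is.numeric(lhr_pos) || !is.numeric(lhr_neg) ||
      length(lhr_pos) != 1 || length(lhr_neg) != 1 ||
      !(lhr_pos > 1) || !(lhr_neg < 1) || !(lhr_neg > 0)) {
    stop("likelihood-ratio pair is not invertible: requires ",
         "lhr_pos > 1 > lhr_neg > 0", call. = FALSE)
  }
  spec <- (lhr_pos - 1) / (lhr_pos - lhr_neg)
  sens <- lhr_pos * (1 - spec)
  list(sensitivity = sens, specificity = spec)
}

# Per-question yes-probabilities under a given true etiology: the cell's
# sensitivity where invertible, the neutral rate elsewhere.
yes_rates_for_etiology <- function(etiology, kb, neutral_rate) {
  vapply(kb$questions, function(q) {
    cell <- q$lhr[[etiology]]
    if (is.null(cell)) return(neutral_rate)
    ss <- tryCatch(sens_spec_from_lhr(cell$lhr_pos, cell$lhr_neg),
                   error = function(e) NULL)
    if (is.null(ss)) neutral_rate else ss$sensitivity
  }, numeric(1))
}

#' Generate one labeled synthetic case
#'
#' Draws an answer vector conditional on a true etiology: each question is
#' answered yes with the sensitivity implied by its likelihood-ratio cell
#' under that etiology ([sens_spec_from_lhr()]), or with the neutral rate
#' where no invertible cell exists; answers are conditionally independent
#' given the etiology. Each answer is then independently replaced by
#' unknown with probability `unknown_rate`.
#'
#' @param etiology The true etiology id.
#' @param kb A `syncope_kb`.
#' @param config A [generator_config()].
#' @param seed Optional seed for standalone reproducibility; when `NULL`
#'   (as inside [generate_cohort()]) the current RNG stream is consumed.
#' @return A `syncope_answers` object with attribute `true_etiology`.
#' @export
generate_case <- function(etiology, kb, config, seed = NULL) {
  etiology <- match.arg(etiology, syncope_etiologies())
  if (!is.null(seed)) set.seed(seed)
  rates <- yes_rates_for_etiology(etiology, kb, config$neutral_rate)
  vals <- ifelse(stats::runif(length(rates)) < rates, "yes", "no")
  unknown <- stats::runif(length(rates)) < config$unknown_rate
  vals[unknown] <- "unknown"
  names(vals) <- names(kb$questions)
  out <- as_answer_set(vals)
  attr(out, "true_etiology") <- etiology
  out
}

#' Generate a labeled synthetic cohort
#'
#' Labels are drawn from the configured etiology mix (defaulting to the
#' knowledge base's priors renormalized to sum to 1); cases come from
#' [generate_case()]. Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param kb A `syncope_kb`.
#' @return A tibble with columns `case_id`, `true_etiology`, and `answers`
#'   (a list-column of `syncope_answers`); attribute `seed` records the
#'   seed used.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' cohort <- generate_cohort(generator_config(seed = 1, n = 5), kb)
generate_cohort <- function(config, kb) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  mix <- config$mix
  if (is.null(mix)) {
    pr <- kb$priors[syncope_etiologies()]
    mix <- pr / sum(pr)
  }
  labels <- if (config$n == 0) character() else
    sample(names(mix), config$n, replace = TRUE, prob = unname(mix))
  cases <- lapply(labels, function(et) generate_case(et, kb, config))
  out <- tibble::tibble(
    case_id = sprintf("case_%05d", seq_len(config$n)),
    true_etiology = labels,
    answers = cases
  )
  attr(out, "seed") <- config$seed
  out
}

#' Write a cohort to disk
#'
#' Writes the cohort as a JSON array of case objects (each in the case-file
#' schema) plus a labels sidecar CSV mapping case ids to true etiologies
#' and recording the generator seed.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cases <- lapply(seq_len(nrow(cohort)), function(i) {
    list(case_id = cohort$case_id[i],
         answers = as.list(cohort$answers[[i]]$answers))
  })
  jsonlite::write_json(cases, file.path(dir, "cases.json"),
                       auto_unbox = TRUE, digits = NA)
  labels <- data.frame(case_id = cohort$case_id,
                       true_etiology = cohort$true_etiology,
                       seed = attr(cohort, "seed"))
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Top-rank recovery of the true etiology on a labeled cohort
#'
#' Runs the differential engine on every case and scores whether the true
#' etiology is ranked first. With `restrict_to`, ranking is evaluated among
#' the given etiologies only (e.g. the two-etiology discrimination check on
#' a vasovagal-vs-cardiogenic cohort).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param kb A `syncope_kb`.
#' @param restrict_to Optional character vector of etiology ids to rank
#'   within.
#' @return A one-row tibble: `accuracy`, `n_correct`, `n`.
#' @export
cohort_top1_accuracy <- function(cohort, kb, restrict_to = NULL) {
  correct <- vapply(seq_len(nrow(cohort)), function(i) {
    d <- compute_differential(cohort$answers[[i]], kb)
    if (!is.null(restrict_to)) {
      d <- d[d$etiology %in% restrict_to, ]
    }
    d$etiology[1] == cohort$true_etiology[i]
  }, logical(1))
  tibble::tibble(
    accuracy = mean(correct),
    n_correct = as.integer(sum(correct)),
    n = nrow(cohort)
  )
}
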