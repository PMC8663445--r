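#' The four etiology identifiers
#'
#' The engine models four causes of transient loss of consciousness as
#' independent binary outcomes: vasovagal (reflex-mediated), orthostatic,
#' cardiogenic, and neurogenic loss of consciousness (e.g. seizure; the
#' highest-risk non-syncopal etiology).
#'
#' @return Character vector of the four etiology ids.
#' @export
#' @examples
#' syncope_etiologies()
syncope_etiologies <- function() {
  c("vasovagal", "orthostatic", "cardiogenic", "neurogenic_loc")
}

# Risk-first precedence used for tie-breaks and ordering among overridden
# etiologies; overridable via the KB's tie_break_order field.
default_tie_break_order <- function() {
  c("neurogenic_loc", "cardiogenic", "orthostatic", "vasovagal")
}

#' Load a knowledge base
#'
#' Reads, parses, and validates a declarative knowledge base: the assessment
#' questions with their per-etiology likelihood-ratio pairs, the pretest
#' prevalences, the Canadian Syncope Score item weights and risk cut points,
#' and the recommendation texts. With no `path` the packaged default is
#' loaded; its content transcribes the published question tables (20
#' questions with positive/negative likelihood ratios for vasovagal and
#' cardiogenic syncope, plus the override and score-input flags).
#'
#' Files are JSON by default; paths ending in `.yaml`/`.yml` are read as a
#' YAML dialect mapping 1:1 onto the JSON schema (shipped under
#' `inst/schema/kb.schema.json`). Absent likelihood-ratio cells are encoded
#' as JSON `null`.
#'
#' @param path Path to a knowledge-base file, or `NULL` for the packaged
#'   default.
#' @return A validated `syncope_kb` object.
#' @seealso [validate_knowledge_base()], [kb_questions()], [kb_lhr_cells()]
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' kb_questions(kb)
load_knowledge_base <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kb_default.json", package = "syncopedx",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("knowledge-base file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) {
        stop("knowledge-base parse error in '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  kb <- new_knowledge_base(raw)
  violations <- validate_knowledge_base(kb)
  if (length(violations) > 0) {
    stop("invalid knowledge base ('", path, "'):\n",
         paste0("  - ", violations, collapse = "\n"), call. = FALSE)
  }
  kb
}

# Build the internal representation from parsed JSON/YAML. Structural
# problems that make validation impossible raise immediately; everything
# else is left for validate_knowledge_base() to report.
new_knowledge_base <- function(raw) {
  if (!is.list(raw)) stop("knowledge base must be a JSON object", call. = FALSE)
  questions <- lapply(raw$questions, function(q) {
    lhr <- q$lhr
    # keep only present (non-null) cells; names are etiology ids
    if (is.null(lhr)) lhr <- list()
    lhr <- lhr[!vapply(lhr, is.null, logical(1))]
    list(
      id = q$id %||% NA_character_,
      text = q$text %||% "",
      lhr = lhr,
      css_input = isTRUE(q$css_input),
      prompt_only = isTRUE(q$prompt_only),
      override_for = q$override_for,
      numeric_threshold = q$numeric_threshold
    )
  })
  names(questions) <- vapply(questions, function(q) as.character(q$id),
                             character(1))
  css_items <- tibble::tibble(
    name = vapply(raw$css$items, function(i) as.character(i$name %||% NA),
                  character(1)),
    source = vapply(raw$css$items, function(i) as.character(i$source %||% NA),
                    character(1)),
    points = vapply(raw$css$items, function(i) as.numeric(i$points %||% NA),
                    numeric(1))
  )
  structure(
    list(
      version = raw$version %||% NA_character_,
      tie_break_order = unlist(raw$tie_break_order) %||%
        default_tie_break_order(),
      questions = questions,
      priors = unlist(raw$priors),
      css = list(
        items = css_items,
        thresholds = list(
          low_below = raw$css$thresholds$low_below,
          high_above = raw$css$thresholds$high_above
        )
      ),
      recommendations = list(
        primary = lapply(raw$recommendations$primary, as.character),
        secondary = lapply(raw$recommendations$secondary, as.character),
        question_specific = lapply(raw$recommendations$question_specific,
                                   as.character),
        disposition = lapply(raw$recommendations$disposition, as.character)
      )
    ),
    class = "syncope_kb"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a knowledge base
#'
#' Checks every structural invariant of the knowledge base and returns the
#' full list of violations (an empty character vector when the knowledge
#' base is valid). Violations are collected, not raised, so a malformed file
#' can be diagnosed in one pass; each message names the offending entity and
#' the rule it breaks.
#'
#' @param kb A `syncope_kb` object (possibly invalid).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
#' @examples
#' validate_knowledge_base(load_knowledge_base())
validate_knowledge_base <- function(kb) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  ets <- syncope_etiologies()

  if (!is.character(kb$version) || is.na(kb$version) || !nzchar(kb$version)) {
    add("version: must be a non-empty string")
  }
  tbo <- kb$tie_break_order
  if (!setequal(tbo, ets) || length(tbo) != 4) {
    add("tie_break_order: must be a permutation of the four etiology ids")
  }

  ids <- names(kb$questions)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add(paste0("question '", d, "': duplicate question id"))
  if (any(is.na(ids) | !nzchar(ids))) add("question ids must be non-empty")

  for (q in kb$questions) {
    qid <- q$id
    bad_et <- setdiff(names(q$lhr), ets)
    for (b in bad_et) {
      add(paste0("question '", qid, "': unknown etiology '", b,
                 "' in likelihood-ratio map"))
    }
    for (et in intersect(names(q$lhr), ets)) {
      cell <- q$lhr[[et]]
      lp <- cell$lhr_pos
      ln_ <- cell$lhr_neg
      if (is.null(lp) || is.null(ln_)) {
        add(paste0("question '", qid, "' / ", et,
                   ": likelihood-ratio pair must be fully present or absent"))
      } else if (!is.numeric(lp) || !is.numeric(ln_) || lp <= 0 || ln_ <= 0) {
        add(paste0("question '", qid, "' / ", et,
                   ": likelihood ratio must be > 0"))
      }
    }
    if (q$prompt_only && length(q$lhr) > 0) {
      add(paste0("question '", qid,
                 "': prompt-only questions carry no likelihood ratios"))
    }
    if (!is.null(q$override_for) && !(q$override_for %in% ets)) {
      add(paste0("question '", qid, "': override_for must name an etiology"))
    }
  }

  for (et in ets) {
    p <- kb$priors[[et]]
    if (is.null(p) || is.na(p)) {
      add(paste0("priors: missing pretest probability for ", et))
    } else if (p <= 0 || p >= 1) {
      add(paste0("priors: ", et,
                 " pretest probability must lie in the open interval (0,1)"))
    }
  }

  v <- c(v, validate_css_config(kb))
  v <- c(v, validate_recommendation_texts(kb))
  v
}

validate_css_config <- function(kb) {
  v <- character()
  items <- kb$css$items
  th <- kb$css$thresholds
  if (is.null(th$low_below) || is.null(th$high_above)) {
    v <- c(v, "css thresholds: low_below and high_above are required")
  } else if (!(th$low_below < th$high_above)) {
    v <- c(v, "css thresholds: low_below must be < high_above")
  }
  if (any(is.na(items$points)) || any(items$points != round(items$points))) {
    v <- c(v, "css items: points must be signed integers")
  }
  diag_items <- items$source[startsWith(items$source, "diagnosis:")]
  if (!setequal(diag_items, c("diagnosis:vasovagal", "diagnosis:cardiac")) ||
      length(diag_items) != 2) {
    v <- c(v, paste0("css items: exactly two diagnosis-derived items are ",
                     "required (diagnosis:vasovagal, diagnosis:cardiac)"))
  }
  q_sources <- items$source[!startsWith(items$source, "diagnosis:")]
  missing_q <- setdiff(q_sources, names(kb$questions))
  for (m in missing_q) {
    v <- c(v, paste0("css item sourced from '", m,
                     "': no such question in the knowledge base"))
  }
  css_flagged <- names(kb$questions)[vapply(kb$questions, function(q)
    isTRUE(q$css_input), logical(1))]
  for (qid in css_flagged) {
    n <- sum(q_sources == qid)
    if (n != 1) {
      v <- c(v, paste0("question '", qid, "': flagged as a score input but ",
                       "mapped to ", n, " score items (expected exactly 1)"))
    }
  }
  v
}

validate_recommendation_texts <- function(kb) {
  v <- character()
  rec <- kb$recommendations
  ets <- syncope_etiologies()
  for (et in setdiff(ets, names(rec$primary))) {
    v <- c(v, paste0("recommendations: missing primary text for ", et))
  }
  # every discordant ordered (app, user) pair must have a secondary text
  pairs <- expand.grid(app = ets, user = ets, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$app != pairs$user, ]
  keys <- paste(pairs$app, pairs$user, sep = "|")
  for (k in setdiff(keys, names(rec$secondary))) {
    v <- c(v, paste0("recommendations: missing secondary text for ",
                     "discordant pair ", k))
  }
  for (cl in setdiff(c("low", "intermediate", "high"),
                     names(rec$disposition))) {
    v <- c(v, paste0("recommendations: missing disposition text for ", cl,
                     " risk"))
  }
  # question-specific texts must exist for every question that can trigger
  # one: override-flagged and prompt-only questions
  triggers <- names(kb$questions)[vapply(kb$questions, function(q)
    isTRUE(q$prompt_only) || !is.null(q$override_for), logical(1))]
  for (qid in setdiff(triggers, names(rec$question_specific))) {
    v <- c(v, paste0("recommendations: missing question-specific text for '",
                     qid, "'"))
  }
  v
}

#' Serialize a knowledge base
#'
#' Writes a `syncope_kb` back to JSON in the published schema, so that a
#' load/serialize/load round trip reproduces the object field-for-field.
#'
#' @param kb A validated `syncope_kb`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  ets <- syncope_etiologies()
  questions <- lapply(unname(kb$questions), function(q) {
    lhr <- if (q$prompt_only || length(q$lhr) == 0) {
      structure(list(), names = character())
    } else {
      cells <- lapply(ets, function(et) {
        cell <- q$lhr[[et]]
        if (is.null(cell)) NULL else
          list(lhr_pos = cell$lhr_pos, lhr_neg = cell$lhr_neg)
      })
      names(cells) <- ets
      cells
    }
    list(
      id = q$id, text = q$text, lhr = lhr,
      css_input = q$css_input, prompt_only = q$prompt_only,
      override_for = q$override_for,
      numeric_threshold = q$numeric_threshold
    )
  })
  out <- list(
    version = kb$version,
    tie_break_order = kb$tie_break_order,
    questions = questions,
    priors = as.list(kb$priors),
    css = list(
      items = lapply(seq_len(nrow(kb$css$items)), function(i) {
        list(name = kb$css$items$name[i], source = kb$css$items$source[i],
             points = kb$css$items$points[i])
      }),
      thresholds = kb$css$thresholds
    ),
    recommendations = kb$recommendations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Question table of a knowledge base
#'
#' @param kb A `syncope_kb`.
#' @return A tibble with one row per assessment question: `id`, `text`,
#'   `css_input`, `prompt_only`, `override_for` (NA when not an override
#'   trigger), and `n_lhr_cells` (number of etiologies with a
#'   likelihood-ratio pair).
#' @export
kb_questions <- function(kb) {
  tibble::tibble(
    id = names(kb$questions),
    text = vapply(kb$questions, function(q) q$text, character(1)),
    css_input = vapply(kb$questions, function(q) q$css_input, logical(1)),
    prompt_only = vapply(kb$questions, function(q) q$prompt_only, logical(1)),
    override_for = vapply(kb$questions, function(q)
      q$override_for %||% NA_character_, character(1)),
    n_lhr_cells = vapply(kb$questions, function(q) length(q$lhr), integer(1))
  )
}

#' Likelihood-ratio cells of a knowledge base, in long form
#'
#' @param kb A `syncope_kb`.
#' @return A tibble with one row per present (question, etiology)
#'   likelihood-ratio pair: `question_id`, `etiology`, `lhr_pos`, `lhr_neg`.
#' @export
kb_lhr_cells <- function(kb) {
  rows <- purrr::map_dfr(kb$questions, function(q) {
    if (length(q$lhr) == 0) return(NULL)
    tibble::tibble(
      question_id = q$id,
      etiology = names(q$lhr),
      lhr_pos = vapply(q$lhr, function(c) as.numeric(c$lhr_pos), numeric(1)),
      lhr_neg = vapply(q$lhr, function(c) as.numeric(c$lhr_neg), numeric(1))
    )
  })
  rows
}

#' Pretest prevalences of a knowledge base
#'
#' @param kb A `syncope_kb`.
#' @return A tibble with columns `etiology` and `prior` (pretest probability
#'   in (0,1); the four etiologies are modelled independently, so priors need
#'   not sum to 1).
#' @export
kb_priors <- function(kb) {
  ets <- syncope_etiologies()
  tibble::tibble(etiology = ets, prior = unname(kb$priors[ets]))
}

#' @export
print.syncope_kb <- function(x, ...) {
  qt <- kb_questions(x)
  cat("<syncope_kb> version ", x$version, "\n", sep = "")
  cat("  ", nrow(qt), " questions (", sum(qt$css_input), " score inputs, ",
      sum(qt$prompt_only), " prompt-only, ",
      sum(!is.na(qt$override_for)), " override triggers)\n", sep = "")
  pr <- kb_priors(x)
  cat("  priors: ",
      paste0(pr$etiology, "=", format(pr$prior), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
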