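# Shared fixtures and independent oracles.

default_kb <- load_knowledge_base()

# Brute-force oracle for the posttest probability: sequential pretest-odds
# times likelihood-ratio product, never touching the log scale. Kept
# independent of the engine's log-sum path on purpose.
oracle_posttest_probability <- function(prior, answers, kb, etiology) {
  odds <- prior / (1 - prior)
  for (qid in names(kb$questions)) {
    cell <- kb$questions[[qid]]$lhr[[etiology]]
    if (is.null(cell)) next
    a <- answers$answers[qid]
    if (!is.na(a) && a == "yes") odds <- odds * cell$lhr_pos
    if (!is.na(a) && a == "no") odds <- odds * cell$lhr_neg
  }
  odds / (1 + odds)
}

# Random knowledge base: the default structure with every LHR cell and
# prior replaced by random values (cells dropped at random), exercising
# the engine over arbitrary evidence patterns.
random_kb <- function() {
  kb <- default_kb
  for (qid in names(kb$questions)) {
    if (kb$questions[[qid]]$prompt_only) next
    cells <- list()
    for (et in syncope_etiologies()) {
      if (stats::runif(1) < 0.6) {
        cells[[et]] <- list(lhr_pos = stats::rlnorm(1, 0, 1),
                            lhr_neg = stats::rlnorm(1, 0, 1))
      }
    }
    kb$questions[[qid]]$lhr <- cells
  }
  pr <- stats::runif(4, 0.02, 0.9)
  names(pr) <- syncope_etiologies()
  kb$priors <- pr
  kb
}

random_answers <- function(kb, p_unknown = 0.3) {
  vals <- sample(c("yes", "no", "unknown"), length(kb$questions),
                 replace = TRUE,
                 prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2,
                          p_unknown))
  names(vals) <- names(kb$questions)
  as_answer_set(vals)
}

# A small store of records with a prescribed concordance pattern, built by
# running the real engine and picking the user selection to agree or not.
build_store <- function(path, n_concordant, n_discordant, kb = default_kb) {
  if (file.exists(path)) unlink(path)
  add <- function(user) {
    a <- answer_set(age_le_35 = "yes", trigger_context = "yes",
                    user_selected_ddx = user)
    append_record(path, evaluation_record(assess(a, kb)), kb)
  }
  # these answers rank vasovagal first
  for (i in seq_len(n_concordant)) add("vasovagal")
  for (i in seq_len(n_discordant)) add("cardiogenic")
  path
}
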