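# Shared fixtures and builders for the test suite.

mini_db <- fixture_food_db("mini")

# Answer every key question 'no' except those named in `yes`, then apply the
# given follow-up answers. `answers` is a list of lists(question, option,
# amount) applied in order; entries with option = NA are skipped questions.
build_session <- function(db, yes = character(), answers = list(),
                          participant = "p1", supplement = "no") {
  s <- new_recall_session(participant, as.Date("2020-10-01"))
  s <- answer_question(s, db, "Q_RESTRICT", "none")
  keys <- db$questions$question_id[db$questions$qtype == "key"]
  for (k in keys) {
    s <- answer_question(s, db, k, if (k %in% yes) "yes" else "no")
  }
  for (a in answers) {
    s <- if (is.na(a$option[1])) {
      skip_question(s, db, a$question)
    } else {
      answer_question(s, db, a$question, a$option,
                      if (is.null(a$amount)) NA_real_ else a$amount)
    }
  }
  s <- answer_question(s, db, "Q_USUAL1", "usual")
  s <- answer_question(s, db, "Q_USUAL2", "yes")
  s <- answer_question(s, db, "Q_SUPP", supplement)
  finalize_session(db, s)
}

ans <- function(question, option, amount = NULL) {
  list(question = question, option = option, amount = amount)
}

# Independent two-way ANOVA mean-squares oracle for the ICC, via stats::aov.
icc_oracle_aov <- function(x, form = "consistency") {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(as.matrix(x)),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (form == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
}

# Simulate an n x k table from the two-way random model with true ICC rho.
sim_icc_table <- function(n, k, rho, sigma_total = 1) {
  sb <- sqrt(rho * sigma_total^2)
  se <- sqrt((1 - rho) * sigma_total^2)
  subj <- stats::rnorm(n, 0, sb)
  matrix(subj, n, k) + matrix(stats::rnorm(n * k, 0, se), n, k)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
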