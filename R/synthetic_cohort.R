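#' Specify a synthetic validation cohort
#'
#' Bundles the parameters of the synthetic data generator that stands in for
#' a real validation sample: cohort size and demographic mix, the rate at
#' which respondents skip imputable type/source/preparation follow-ups, and
#' the latent paired-measurement model that drives simulated between-tool
#' agreement. Defaults mirror the validation-study conditions: 186
#' participants sampled to resemble the adult Brazilian population (55%
#' women, 61% from the Southeast/Northeast, mean age 41.3 years, 30%
#' overweight and 24% obese), 23/186 participants with at least one skipped
#' imputable field, and mean Nova energy shares of 52.3/11.6/17.1/19.0% for
#' groups 1--4.
#'
#' The paired-measurement model is additive-log-ratio (alr) normal so noisy
#' share vectors stay on the simplex: each participant has a latent 3-vector
#' `u ~ N(alr(mean_shares), sd_between^2 I)` observed once per tool with
#' independent `N(0, sd_within^2)` noise, then mapped back to percentages.
#' On the alr scale the implied intraclass correlation is
#' `sd_between^2 / (sd_between^2 + sd_within^2)` (see [implied_icc()]).
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed driving all randomness.
#' @param missingness Probability that any one imputable follow-up is
#'   skipped, chosen so the expected share of participants with at least one
#'   skip matches the observed 23/186.
#' @param mean_shares Length-4 percentage vector (renormalised to 100).
#' @param sd_between,sd_within Between-participant and within-participant
#'   (tool) standard deviations on the alr scale.
#' @param bias_b Length-4 additive bias (percentage points) applied to tool
#'   B's shares before renormalisation.
#' @param p_yes Probability a simulated respondent answers a key question
#'   with yes.
#' @param demographics Named list of category probabilities for sex, region
#'   group, education and BMI category, plus age mean/sd.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 186L, seed = 1L,
                        missingness = 23 / 186,
                        mean_shares = c(52.3, 11.6, 17.1, 19.0),
                        sd_between = 0.8, sd_within = 0.45,
                        bias_b = c(0, 0, 0, 0),
                        p_yes = 0.5,
                        demographics = list(
                          sex = c(female = 0.55, male = 0.45),
                          region = c(southeast_northeast = 0.61, other = 0.39),
                          education = c(less_than_secondary = 0.049,
                                        secondary = 0.462, university = 0.489),
                          bmi = c(under_normal = 0.46, overweight = 0.30,
                                  obese = 0.24),
                          age_mean = 41.3, age_sd = 13
                        )) {
  stopifnot(length(mean_shares) == 4L, all(mean_shares > 0),
            sd_between >= 0, sd_within >= 0, length(bias_b) == 4L)
  if (missingness < 0 || missingness > 1) {
    nova_abort("missingness rate must be in [0, 1]", "nova24r_contract_error")
  }
  for (nm in c("sex", "region", "education", "bmi")) {
    p <- demographics[[nm]]
    if (abs(sum(p) - 1) > 1e-9) {
      nova_abort(sprintf("demographic proportions for '%s' must sum to 1", nm),
                 "nova24r_contract_error")
    }
  }
  structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         missingness = missingness,
         mean_shares = 100 * mean_shares / sum(mean_shares),
         sd_between = sd_between, sd_within = sd_within, bias_b = bias_b,
         p_yes = p_yes, demographics = demographics),
    class = "cohort_spec"
  )
}

#' Implied alr-scale ICC of a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @return `sd_between^2 / (sd_between^2 + sd_within^2)`, the intraclass
#'   correlation of the latent paired-measurement model on the
#'   additive-log-ratio scale.
#' @export
implied_icc <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$sd_between == 0 && spec$sd_within == 0) {
    nova_abort("degenerate variance specification", "nova24r_contract_error")
  }
  spec$sd_between^2 / (spec$sd_between^2 + spec$sd_within^2)
}

#' Simulate participant demographics
#'
#' @param spec A `cohort_spec`.
#' @return A tibble with one row per participant: `participant_id`, `age`,
#'   `sex`, `region`, `education`, `bmi_category`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$demographics
  with_seed(spec$seed, {
    n <- spec$n_participants
    draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      age = round(pmax(18, stats::rnorm(n, d$age_mean, d$age_sd))),
      sex = draw(d$sex),
      region = draw(d$region),
      education = draw(d$education),
      bmi_category = draw(d$bmi)
    )
  })
}

# Simulate one traversal of the question graph. `prior` (a named list of
# previous choices) and `fidelity` support correlated repeat administrations:
# each decision reuses the prior choice with probability `fidelity`.
sim_one_session <- function(db, participant_id, p_yes, missingness,
                            prior = NULL, fidelity = 1) {
  session <- new_recall_session(participant_id, as.Date("2020-10-01"))
  choices <- list()
  decide <- function(qid, fresh) {
    if (!is.null(prior) && !is.null(prior[[qid]]) && stats::runif(1) < fidelity) {
      prior[[qid]]
    } else {
      fresh()
    }
  }
  repeat {
    nq <- next_questions(db, session)
    if (nrow(nq) == 0L) break
    q <- nq[1, ]
    opts <- db$options$option_id[db$options$question_id == q$question_id]
    ch <- switch(q$qtype,
      key = decide(q$question_id, function() {
        list(option = if (stats::runif(1) < p_yes) "yes" else "no", amount = NA_real_)
      }),
      type_amount = ,
      added_item = decide(q$question_id, function() {
        list(option = opts[sample.int(length(opts), 1)],
             amount = sample(1:3, 1))
      }),
      detail = ,
      preparation = decide(q$question_id, function() {
        if (stats::runif(1) < missingness) {
          list(option = NA_character_, amount = NA_real_)  # skipped
        } else {
          list(option = opts[sample.int(length(opts), 1)], amount = NA_real_)
        }
      }),
      decide(q$question_id, function() {
        list(option = opts[sample.int(length(opts), 1)], amount = NA_real_)
      })
    )
    choices[[q$question_id]] <- ch
    session <- if (is.na(ch$option)) {
      skip_question(session, db, q$question_id)
    } else {
      answer_question(session, db, q$question_id, ch$option, ch$amount)
    }
  }
  list(session = finalize_session(db, session), choices = choices)
}

#' Simulate recall sessions over a food database
#'
#' Generates seeded random traversals of the question graph: each key
#' question is answered yes with probability `spec$p_yes`, triggered
#' type-and-amount and added-item questions receive a uniformly chosen
#' option with 1--3 portions, and each imputable detail/preparation
#' follow-up is skipped (recorded missing) with probability
#' `spec$missingness`. Sessions are returned finalized.
#'
#' @param spec A `cohort_spec`.
#' @param db A `food_db`.
#' @return A list of `recall_session` objects of length
#'   `spec$n_participants`.
#' @export
simulate_sessions <- function(spec, db) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(db, "food_db"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_participants), function(i) {
      sim_one_session(db, sprintf("P%04d", i), spec$p_yes, spec$missingness)$session
    })
  })
}

#' Simulate paired recall sessions with controlled repeat fidelity
#'
#' For each participant, simulates a first ("tool A") session and a second
#' ("tool B") session that reuses each of A's answers with probability
#' `fidelity` and re-draws it otherwise. `fidelity = 1` reproduces identical
#' intakes; lower values inject tool disagreement, so agreement statistics
#' computed downstream decrease monotonically with `1 - fidelity`.
#'
#' @param spec A `cohort_spec`.
#' @param db A `food_db`.
#' @param fidelity Probability in `[0, 1]` that tool B repeats a tool-A
#'   answer.
#' @return A list with elements `a` and `b`, each a list of finalized
#'   sessions.
#' @export
simulate_session_pairs <- function(spec, db, fidelity = 0.9) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(db, "food_db"),
            fidelity >= 0, fidelity <= 1)
  with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_participants), function(i) {
      pid <- sprintf("P%04d", i)
      first <- sim_one_session(db, pid, spec$p_yes, spec$missingness)
      second <- sim_one_session(db, pid, spec$p_yes, spec$missingness,
                                prior = first$choices, fidelity = fidelity)
      list(a = first$session, b = second$session)
    })
    list(a = lapply(out, `[[`, "a"), b = lapply(out, `[[`, "b"))
  })
}

# alr transform between 4-part percentage compositions and R^3
alr <- function(p) log(p[1:3] / p[4])
alr_inv <- function(v) {
  e <- c(exp(v), 1)
  100 * e / sum(e)
}

#' Simulate paired Nova share measurements from the latent model
#'
#' Draws, for each participant, a latent 4-part Nova energy-share vector
#' from an additive-log-ratio normal distribution and observes it twice with
#' independent tool noise (plus an optional additive bias on tool B),
#' producing a long paired-shares table ready for [agreement_report()].
#'
#' @param spec A `cohort_spec`.
#' @return A tibble with columns `participant_id`, `tool` (`"tool_a"`,
#'   `"tool_b"`), `nova_group`, `share_pct`; attribute `seed` records the
#'   generator seed.
#' @export
simulate_paired_shares <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$sd_between == 0 && spec$sd_within == 0 && all(spec$bias_b == 0)) {
    # fully degenerate: identical constant vectors carry no agreement signal
    nova_abort("degenerate variance specification: no between- or within-subject variance",
               "nova24r_contract_error")
  }
  mu <- alr(spec$mean_shares)
  with_seed(spec$seed, {
    n <- spec$n_participants
    out <- purrr::map_dfr(seq_len(n), function(i) {
      u <- mu + stats::rnorm(3, 0, spec$sd_between)
      sa <- alr_inv(u + stats::rnorm(3, 0, spec$sd_within))
      sb <- alr_inv(u + stats::rnorm(3, 0, spec$sd_within))
      sb <- pmax(sb + spec$bias_b, 0)
      sb <- 100 * sb / sum(sb)
      tibble(
        participant_id = sprintf("P%04d", i),
        tool = rep(c("tool_a", "tool_b"), each = 4L),
        nova_group = rep(1:4, 2L),
        share_pct = c(sa, sb)
      )
    })
    attr(out, "seed") <- spec$seed
    out
  })
}

#' Pivot one Nova group of a long paired-shares table to two rating columns
#'
#' @param paired Long paired-shares tibble (`participant_id`, `tool`,
#'   `nova_group`, `share_pct`).
#' @param group Nova group to extract (1--4).
#' @return A tibble with one numeric column per tool, rows in participant
#'   order.
#' @export
pairs_wide <- function(paired, group) {
  tools <- sort(unique(paired$tool))
  w <- tidyr::pivot_wider(
    paired[paired$nova_group == group, c("participant_id", "tool", "share_pct")],
    names_from = "tool", values_from = "share_pct")
  w[stats::complete.cases(w), tools]
}
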