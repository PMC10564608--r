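#' Start a recall session
#'
#' A recall session records one participant's traversal of the branching
#' questionnaire for one recall day. Answers are added with
#' [answer_question()] (or [skip_question()]) and the session is closed with
#' [finalize_session()].
#'
#' @param participant_id Participant identifier.
#' @param recall_date Date of the recalled day (coerced with `as.Date()`).
#' @return An object of class `recall_session`.
#' @export
new_recall_session <- function(participant_id, recall_date = Sys.Date() - 1) {
  structure(
    list(
      participant_id = as.character(participant_id),
      recall_date = as.Date(recall_date),
      answers = empty_answers(),
      status = "in_progress"
    ),
    class = "recall_session"
  )
}

empty_answers <- function() {
  tibble(question_id = character(), option_ids = list(),
         amount_units = double(), skipped = logical())
}

#' @export
print.recall_session <- function(x, ...) {
  cat(sprintf("<recall_session> participant %s, %s, %s; %d answer(s)\n",
              x$participant_id, format(x$recall_date), x$status, nrow(x$answers)))
  invisible(x)
}

# Question ids whose trigger predicate is satisfied by the session's answers.
# Root questions (restriction, key, usual-intake, supplement) are always
# triggered; a follow-up is triggered when its parent was answered (not
# skipped) and, if the trigger names an option, that option was selected.
triggered_questions <- function(db, session) {
  qs <- db$questions
  ans <- session$answers
  answered <- stats::setNames(rep(FALSE, nrow(qs)), qs$question_id)
  selected <- list()
  for (i in seq_len(nrow(ans))) {
    if (!ans$skipped[i]) {
      answered[[ans$question_id[i]]] <- TRUE
      selected[[ans$question_id[i]]] <- ans$option_ids[[i]]
    }
  }
  trig <- logical(nrow(qs))
  for (i in seq_len(nrow(qs))) {
    p <- qs$trigger_question_id[i]
    if (is.na(p)) {
      trig[i] <- TRUE
    } else if (isTRUE(answered[[p]])) {
      o <- qs$trigger_option_id[i]
      trig[i] <- is.na(o) || o %in% (selected[[p]] %||% character())
    }
  }
  qs$question_id[trig]
}

#' Questions to present next
#'
#' Returns the question nodes whose trigger predicate is satisfied by the
#' answers recorded so far and which have not yet been answered or skipped,
#' in presentation order. An empty result means the session may be finalized.
#' The returned tibble includes any duplicate-entry `warning` text attached
#' to a node, which a front end must display alongside the prompt.
#'
#' @param db A `food_db` (carries the question graph).
#' @param session A `recall_session`.
#' @return A tibble of question nodes (possibly zero rows).
#' @export
next_questions <- function(db, session) {
  stopifnot(inherits(db, "food_db"), inherits(session, "recall_session"))
  if (session$status != "in_progress") {
    nova_abort("session is not in progress", "nova24r_state_error")
  }
  trig <- triggered_questions(db, session)
  seen <- session$answers$question_id
  db$questions[db$questions$question_id %in% setdiff(trig, seen), ]
}

#' Record an answer in a recall session
#'
#' Validates that the question is currently triggered and that the selected
#' options exist, then records the answer. Re-answering a question is
#' permitted; answers to follow-up questions that are no longer triggered by
#' the revised answer are dropped.
#'
#' @param session A `recall_session`.
#' @param db A `food_db`.
#' @param question_id Question being answered.
#' @param option_ids Selected option id(s).
#' @param amount_units Number of portions consumed, for options bound to a
#'   portion (e.g. 2 glasses).
#' @return The updated `recall_session`.
#' @export
answer_question <- function(session, db, question_id, option_ids,
                            amount_units = NA_real_) {
  record_answer(session, db, question_id, option_ids, amount_units, skipped = FALSE)
}

#' Skip a question
#'
#' Any triggered non-key question may be skipped; the field is recorded as
#' missing and is eligible for population-distribution imputation downstream.
#' Key questions cannot be skipped.
#'
#' @inheritParams answer_question
#' @return The updated `recall_session`.
#' @export
skip_question <- function(session, db, question_id) {
  record_answer(session, db, question_id, character(), NA_real_, skipped = TRUE)
}

record_answer <- function(session, db, question_id, option_ids, amount_units,
                          skipped) {
  stopifnot(inherits(db, "food_db"), inherits(session, "recall_session"))
  if (session$status != "in_progress") {
    nova_abort("cannot answer a finalized session", "nova24r_state_error")
  }
  qs <- db$questions
  if (!question_id %in% qs$question_id) {
    nova_abort(sprintf("unknown question '%s'", question_id), "nova24r_state_error")
  }
  if (!question_id %in% triggered_questions(db, session)) {
    nova_abort(sprintf("question '%s' is not triggered by the current answers",
                       question_id), "nova24r_state_error")
  }
  qtype <- qs$qtype[qs$question_id == question_id]
  if (skipped && qtype == "key") {
    nova_abort("key questions cannot be skipped", "nova24r_state_error")
  }
  if (!skipped) {
    valid <- db$options$option_id[db$options$question_id == question_id]
    bad <- setdiff(option_ids, valid)
    if (length(bad)) {
      nova_abort(sprintf("question '%s' has no option '%s'", question_id, bad[1]),
                 "nova24r_state_error")
    }
    if (length(option_ids) == 0L) {
      nova_abort("an answer must select at least one option", "nova24r_state_error")
    }
  }
  ans <- session$answers[session$answers$question_id != question_id, ]
  ans <- dplyr::bind_rows(ans, tibble(
    question_id = question_id, option_ids = list(as.character(option_ids)),
    amount_units = as.double(amount_units), skipped = skipped
  ))
  session$answers <- ans
  # revision may untrigger follow-ups: drop answers to untriggered questions
  repeat {
    trig <- triggered_questions(db, session)
    stale <- !session$answers$question_id %in% trig
    if (!any(stale)) break
    session$answers <- session$answers[!stale, ]
  }
  session
}

#' Count questions by type
#'
#' @param db A `food_db`.
#' @return A tibble with one row per question type plus a `total_food` row
#'   summing the five food-question types (key, type-and-amount, added-item,
#'   preparation and detail).
#' @export
count_questions <- function(db) {
  stopifnot(inherits(db, "food_db"))
  qt <- table(factor(db$questions$qtype, levels = question_types))
  out <- tibble(qtype = names(qt), n = as.integer(qt))
  dplyr::bind_rows(out, tibble(qtype = "total_food",
                               n = sum(out$n[out$qtype %in% food_question_types])))
}

#' Finalize a recall session
#'
#' A session can be finalized when every triggered question has been answered
#' or explicitly skipped. Key, restriction, usual-intake and supplement
#' questions must be answered (they cannot be skipped). Skipped fields remain
#' recorded as missing for downstream imputation.
#'
#' @param db A `food_db`.
#' @param session A `recall_session`.
#' @return The session with `status = "complete"`.
#' @export
finalize_session <- function(db, session) {
  stopifnot(inherits(db, "food_db"), inherits(session, "recall_session"))
  if (session$status == "complete") return(session)
  pending <- next_questions(db, session)
  if (nrow(pending)) {
    nova_abort(sprintf("session incomplete; unanswered triggered question(s): %s",
                       paste(pending$question_id, collapse = ", ")),
               "nova24r_incomplete_error")
  }
  session$status <- "complete"
  session
}

# ---- session JSON I/O -------------------------------------------------------

#' Read or write recall sessions as JSON
#'
#' Sessions are stored as
#' `{participant_id, recall_date, status, answers: [{question_id, option_ids,
#' amount_units, skipped}]}`.
#'
#' @param session A `recall_session`.
#' @param path File path.
#' @return `read_session()` returns a `recall_session`; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recall_session"))
  obj <- list(
    participant_id = session$participant_id,
    recall_date = format(session$recall_date),
    status = session$status,
    answers = purrr::pmap(session$answers, function(question_id, option_ids,
                                                    amount_units, skipped) {
      a <- list(question_id = question_id, option_ids = as.list(option_ids),
                skipped = skipped)
      if (!is.na(amount_units)) a$amount_units <- amount_units
      a
    })
  )
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  s <- new_recall_session(obj$participant_id, as.Date(obj$recall_date))
  s$status <- obj$status %||% "in_progress"
  s$answers <- purrr::map_dfr(obj$answers %||% list(), function(a) tibble(
    question_id = a$question_id,
    option_ids = list(as.character(unlist(a$option_ids))),
    amount_units = as.double(a$amount_units %||% NA_real_),
    skipped = isTRUE(a$skipped)
  ))
  if (nrow(s$answers) == 0L) s$answers <- empty_answers()
  s
}
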