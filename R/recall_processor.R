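#' Impute a skipped type/source/preparation answer
#'
#' When a respondent reports a food and its amount but skips the follow-up
#' specifying its type, source or preparation, the reported amount is
#' distributed among all options available for that food, proportionally to
#' the population answer distribution. The split conserves the reported mass
#' exactly (the last share absorbs floating-point remainder) and every
#' resulting allocation is flagged as imputed.
#'
#' @param item_id Item whose field is missing.
#' @param field One of `"type"`, `"source"`, `"preparation"`.
#' @param grams Reported amount in grams (positive).
#' @param dists Population distributions: tibble with columns `item_id`,
#'   `field`, `option_id`, `share`.
#' @param fallback What to do when no distribution covers `(item_id, field)`:
#'   `"error"` (default) or `"uniform"`, which splits equally across
#'   `options` with a note.
#' @param options Option ids of the skipped question; required for the
#'   uniform fallback and used to check distribution coverage.
#' @return A tibble with columns `option_id`, `grams`, `imputed` (all `TRUE`).
#' @export
impute_missing <- function(item_id, field, grams, dists,
                           fallback = c("error", "uniform"), options = NULL) {
  fallback <- match.arg(fallback)
  if (!is.numeric(grams) || length(grams) != 1L || is.na(grams) || grams <= 0) {
    nova_abort("`grams` must be a single positive number", "nova24r_contract_error")
  }
  if (!field %in% imputable_fields) {
    nova_abort("`field` must be one of type/source/preparation", "nova24r_contract_error")
  }
  d <- NULL
  if (!is.null(dists)) {
    d <- dists[dists$item_id == item_id & dists$field == field, ]
    if (!is.null(options)) d <- d[d$option_id %in% options, ]
  }
  if (is.null(d) || nrow(d) == 0L) {
    if (fallback == "error") {
      nova_abort(sprintf(
        "no population distribution for item '%s' field '%s' and no fallback configured",
        item_id, field), "nova24r_imputation_error")
    }
    if (is.null(options) || length(options) == 0L) {
      nova_abort("uniform fallback requires the option ids of the skipped question",
                 "nova24r_contract_error")
    }
    inform(sprintf("no distribution for ('%s', '%s'); splitting uniformly over %d options",
                   item_id, field, length(options)))
    d <- tibble(option_id = as.character(options),
                share = rep(1 / length(options), length(options)))
  }
  if (any(d$share < 0)) {
    nova_abort("distribution shares must be non-negative", "nova24r_contract_error")
  }
  if (abs(sum(d$share) - 1) > 1e-9) {
    nova_abort(sprintf("distribution shares for ('%s', '%s') sum to %.9f, not 1",
                       item_id, field, sum(d$share)), "nova24r_contract_error")
  }
  keep <- d$share > 0
  tibble(option_id = d$option_id[keep],
         grams = split_exact(grams, d$share[keep]),
         imputed = TRUE)
}

#' Disaggregate a culinary preparation into its ingredients
#'
#' Replaces a reported dish by its recipe ingredients: each ingredient
#' receives `grams * mass_fraction` of the dish mass, with exact mass
#' conservation.
#'
#' @param item_id A preparation item.
#' @param grams Dish mass consumed, in grams.
#' @param db A `food_db`.
#' @return A tibble with columns `food_code`, `grams`.
#' @export
disaggregate <- function(item_id, grams, db) {
  stopifnot(inherits(db, "food_db"))
  row <- db$items[db$items$item_id == item_id, ]
  if (nrow(row) == 0L) {
    nova_abort(sprintf("unknown item '%s'", item_id), "nova24r_contract_error")
  }
  if (row$kind != "preparation") {
    nova_abort(sprintf("item '%s' is not a culinary preparation", item_id),
               "nova24r_contract_error")
  }
  rec <- db$recipes[db$recipes$item_id == item_id, ]
  if (nrow(rec) == 0L) {
    nova_abort(sprintf("no recipe for preparation '%s'", item_id),
               "nova24r_integrity_error")
  }
  tibble(food_code = rec$food_code,
         grams = split_exact(grams, rec$mass_fraction))
}

#' Process a completed recall session into long-format consumption records
#'
#' Runs the full output pipeline: each answered food question is resolved
#' through portion conversion, fractional imputation of skipped
#' type/source/preparation follow-ups, disaggregation of culinary
#' preparations into recipe ingredients, and attachment of nutritional
#' composition and Nova classification. Supplements are retained as session
#' metadata but contribute no records (and hence no energy).
#'
#' @param session A completed `recall_session`.
#' @param db A `food_db`.
#' @param dists Population distributions for imputation (see
#'   [impute_missing()]); may be `NULL` when nothing was skipped.
#' @param fallback Imputation fallback, `"error"` or `"uniform"`.
#' @return A tibble of consumption records: `participant_id`, `recall_date`,
#'   `source_item_id`, `resolved_code`, `grams`, `energy_kcal`, `nova_group`,
#'   `nova_subgroup`, `imputed`.
#' @export
process_session <- function(session, db, dists = NULL,
                            fallback = c("error", "uniform")) {
  stopifnot(inherits(session, "recall_session"), inherits(db, "food_db"))
  fallback <- match.arg(fallback)
  if (session$status != "complete") {
    nova_abort("session must be finalized before processing", "nova24r_contract_error")
  }
  qs <- db$questions
  op <- db$options
  ans <- session$answers

  empty <- tibble(participant_id = character(), recall_date = as.Date(character()),
                  source_item_id = character(), resolved_code = character(),
                  grams = double(), energy_kcal = double(),
                  nova_group = integer(), nova_subgroup = character(),
                  imputed = logical())

  # reported foods: answered options of type_amount / added_item questions
  # that bind an item
  reported <- list()
  for (i in seq_len(nrow(ans))) {
    if (ans$skipped[i]) next
    qid <- ans$question_id[i]
    qtype <- qs$qtype[qs$question_id == qid]
    if (!qtype %in% c("type_amount", "added_item")) next
    for (oid in ans$option_ids[[i]]) {
      orow <- op[op$question_id == qid & op$option_id == oid, ]
      if (is.na(orow$item_id)) next
      grams <- resolve_portion(orow, ans$amount_units[i], db, qid)
      reported[[length(reported) + 1L]] <- list(
        item_id = orow$item_id, grams = grams,
        answer_q = qid, answer_o = oid
      )
    }
  }
  if (length(reported) == 0L) return(empty)

  trig <- triggered_questions(db, session)
  answered_ids <- ans$question_id[!ans$skipped]
  skipped_ids <- ans$question_id[ans$skipped]

  rows <- purrr::map_dfr(reported, function(rep_) {
    item <- db$items[db$items$item_id == rep_$item_id, ]
    # start as a single allocation; refinement questions may split/override it
    alloc <- tibble(code = item$food_code, grams = rep_$grams, imputed = FALSE)
    refine <- qs[qs$qtype %in% c("detail", "preparation") &
                   !is.na(qs$refines_item_id) &
                   qs$refines_item_id == rep_$item_id &
                   qs$question_id %in% trig, ]
    for (j in seq_len(nrow(refine))) {
      rq <- refine[j, ]
      ropts <- op[op$question_id == rq$question_id, ]
      if (rq$question_id %in% answered_ids) {
        sel <- ans$option_ids[[which(ans$question_id == rq$question_id)]]
        ov <- ropts$food_code_override[match(sel[1], ropts$option_id)]
        if (!is.na(ov)) alloc$code <- ov
      } else {
        # skipped (or left unanswered): distribute over all options
        splits <- impute_missing(rep_$item_id, rq$field, 1.0, dists,
                                 fallback = fallback, options = ropts$option_id)
        alloc <- purrr::map_dfr(seq_len(nrow(alloc)), function(a) {
          g <- split_exact(alloc$grams[a], splits$grams)
          tibble(
            code = ifelse(is.na(ropts$food_code_override[match(splits$option_id, ropts$option_id)]),
                          alloc$code[a],
                          ropts$food_code_override[match(splits$option_id, ropts$option_id)]),
            grams = g, imputed = TRUE
          )
        })
      }
    }
    # disaggregate preparations that were not overridden to a concrete code
    out <- purrr::map_dfr(seq_len(nrow(alloc)), function(a) {
      if (is.na(alloc$code[a])) {
        ing <- disaggregate(rep_$item_id, alloc$grams[a], db)
        tibble(resolved_code = ing$food_code, grams = ing$grams,
               imputed = alloc$imputed[a])
      } else {
        tibble(resolved_code = alloc$code[a], grams = alloc$grams[a],
               imputed = alloc$imputed[a])
      }
    })
    out$source_item_id <- rep_$item_id
    out
  })

  cmp <- db$composition
  idx <- match(rows$resolved_code, cmp$food_code)
  tibble(
    participant_id = session$participant_id,
    recall_date = session$recall_date,
    source_item_id = rows$source_item_id,
    resolved_code = rows$resolved_code,
    grams = rows$grams,
    energy_kcal = rows$grams * cmp$energy_kcal_per_100g[idx] / 100,
    nova_group = cmp$nova_group[idx],
    nova_subgroup = cmp$nova_subgroup[idx],
    imputed = rows$imputed
  )
}

resolve_portion <- function(orow, amount_units, db, qid) {
  if (is.na(orow$portion_id)) {
    nova_abort(sprintf("option '%s' of question '%s' binds an item but no portion",
                       orow$option_id, qid), "nova24r_processing_error")
  }
  g <- db$portions$grams[db$portions$portion_id == orow$portion_id]
  units <- if (is.na(amount_units)) 1 else amount_units
  if (units <= 0) {
    nova_abort(sprintf("non-positive amount for question '%s'", qid),
               "nova24r_processing_error")
  }
  units * g
}

#' Relative energy contribution of the four Nova groups
#'
#' Computes, for one participant's consumption records, the percentage of
#' total energy intake contributed by each Nova group. Shares always cover
#' all four groups (zero where nothing was consumed) and sum to 100 when the
#' recall contains any energy. A zero-energy recall yields `NA` shares with
#' `zero_energy = TRUE`, so downstream aggregation can exclude it explicitly.
#'
#' @param records Consumption records from [process_session()], for a single
#'   participant.
#' @return A tibble with columns `participant_id`, `total_energy_kcal`,
#'   `nova_group`, `share_pct`, `zero_energy` (class `nova_shares`).
#' @export
nova_shares <- function(records) {
  pid <- unique(records$participant_id)
  if (length(pid) > 1L) {
    nova_abort("records span multiple participants; use nova_shares_all()",
               "nova24r_contract_error")
  }
  if (length(pid) == 0L) pid <- NA_character_
  total <- sum(records$energy_kcal)
  by_group <- vapply(1:4, function(g) {
    sum(records$energy_kcal[records$nova_group == g])
  }, double(1))
  share <- if (total > 0) 100 * by_group / total else rep(NA_real_, 4)
  out <- tibble(
    participant_id = pid,
    total_energy_kcal = total,
    nova_group = 1:4,
    share_pct = share,
    zero_energy = total <= 0
  )
  class(out) <- c("nova_shares", class(out))
  out
}

#' @describeIn nova_shares Apply [nova_shares()] to records spanning several
#'   participants, returning one block of four rows per participant.
#' @export
nova_shares_all <- function(records) {
  out <- records %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::group_modify(function(d, key) {
      nova_shares(dplyr::mutate(d, participant_id = key$participant_id))[, -1]
    }) %>%
    dplyr::ungroup()
  class(out) <- c("nova_shares", class(out))
  out
}
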