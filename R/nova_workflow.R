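#' Adjudicate independent Nova classifications
#'
#' Implements the consensus stage of the multi-reviewer classification
#' procedure: each food item or ingredient is assigned to one of the four
#' mutually exclusive Nova groups (and a subgroup) by at least two reviewers
#' working independently; items on which all reviewers agree are assigned
#' directly, while items with disagreement between any two reviewers are
#' shortlisted for scrutiny by an expert panel (see [resolve_panel()]).
#'
#' By default consensus requires agreement on both the Nova group and the
#' subgroup; `group_only = TRUE` relaxes this to the group alone.
#'
#' @param assignments Tibble with columns `reviewer_id`, `item`,
#'   `nova_group` (1--4), `nova_subgroup`, and optionally `stage` (kept in
#'   the audit trail).
#' @param group_only Ignore subgroup disagreements?
#' @return A tibble of class `nova_adjudication` with columns `item`,
#'   `n_reviewers`, `status` (`"consensus"` or `"shortlisted"`),
#'   `final_group`, `final_subgroup`. The reviewer-level audit trail is kept
#'   in the `"audit"` attribute.
#' @export
adjudicate <- function(assignments, group_only = FALSE) {
  assignments <- as_tibble(assignments)
  need <- c("reviewer_id", "item", "nova_group", "nova_subgroup")
  if (!all(need %in% names(assignments))) {
    nova_abort(paste("assignments need columns:", paste(need, collapse = ", ")),
               "nova24r_contract_error")
  }
  if (any(!assignments$nova_group %in% 1:4)) {
    nova_abort("nova_group assignments must be in 1..4", "nova24r_contract_error")
  }
  out <- assignments %>%
    dplyr::group_by(item = .data$item) %>%
    dplyr::summarise(
      n_reviewers = dplyr::n(),
      agree = dplyr::n_distinct(.data$nova_group) == 1L &&
        (group_only || dplyr::n_distinct(.data$nova_subgroup) == 1L),
      final_group = dplyr::first(.data$nova_group),
      final_subgroup = dplyr::first(.data$nova_subgroup),
      .groups = "drop"
    )
  if (any(out$n_reviewers < 2L)) {
    nova_abort(sprintf("item '%s' has fewer than 2 reviewer assignments",
                       out$item[out$n_reviewers < 2L][1]),
               "nova24r_contract_error")
  }
  out <- out %>%
    dplyr::mutate(
      status = ifelse(.data$agree, "consensus", "shortlisted"),
      final_group = ifelse(.data$agree, .data$final_group, NA_integer_),
      final_subgroup = ifelse(.data$agree, .data$final_subgroup, NA_character_)
    ) %>%
    dplyr::select("item", "n_reviewers", "status", "final_group", "final_subgroup")
  attr(out, "audit") <- assignments
  class(out) <- c("nova_adjudication", class(out))
  out
}

#' Resolve a shortlisted item by expert-panel decision
#'
#' Applies the third stage of the classification procedure: the expert
#' panel's decision becomes the final Nova group and subgroup of a
#' shortlisted item. Items already at consensus cannot be resolved again;
#' the audit trail records the panel decision.
#'
#' @param adjudication A `nova_adjudication` from [adjudicate()].
#' @param item Shortlisted item to resolve.
#' @param nova_group Panel decision (1--4).
#' @param nova_subgroup Panel subgroup decision.
#' @return The updated `nova_adjudication`.
#' @export
resolve_panel <- function(adjudication, item, nova_group, nova_subgroup = NA_character_) {
  stopifnot(inherits(adjudication, "nova_adjudication"))
  if (!nova_group %in% 1:4) {
    nova_abort("panel decision must assign a Nova group in 1..4",
               "nova24r_validation_error")
  }
  i <- which(adjudication$item == item)
  if (length(i) != 1L) {
    nova_abort(sprintf("unknown item '%s'", item), "nova24r_contract_error")
  }
  if (adjudication$status[i] != "shortlisted") {
    nova_abort(sprintf("item '%s' is not shortlisted (status: %s)",
                       item, adjudication$status[i]), "nova24r_contract_error")
  }
  adjudication$status[i] <- "panel_resolved"
  adjudication$final_group[i] <- as.integer(nova_group)
  adjudication$final_subgroup[i] <- nova_subgroup
  audit <- attr(adjudication, "audit")
  attr(adjudication, "audit") <- dplyr::bind_rows(audit, tibble(
    reviewer_id = "expert_panel", item = item,
    nova_group = as.integer(nova_group), nova_subgroup = nova_subgroup,
    stage = "panel"
  ))
  adjudication
}
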