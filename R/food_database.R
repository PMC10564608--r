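#' Construct a food database
#'
#' A food database is the long-format matrix behind the recall engine: the food
#' items offered by the questionnaire, the recipes that disaggregate culinary
#' preparations into ingredients, the nutritional composition table, the
#' household-measure portion options, and the branching question graph itself.
#' All referential integrity rules are checked on construction.
#'
#' @param items Tibble with columns `item_id`, `label`, `key_question_id`,
#'   `kind` (one of `"individual"`, `"grouped"`, `"preparation"`),
#'   `food_code` (`NA` for preparations), `member_labels` (list column of
#'   character vectors, non-empty only for grouped items), `representative`
#'   (the grouped member whose food code the item carries), `nova_group`
#'   (integer 1--4, `NA` for preparations) and `nova_subgroup`.
#' @param recipes Tibble with columns `item_id`, `food_code`, `mass_fraction`
#'   (fraction of prepared-dish mass) and `source` (`"standard"` or
#'   `"adapted"`). Fractions are renormalised to sum to one at construction;
#'   a deviation beyond `1e-9` raises a warning.
#' @param composition Tibble with columns `food_code`, `energy_kcal_per_100g`,
#'   `protein_g`, `carb_g`, `fat_g`, `nova_group`, `nova_subgroup`.
#' @param portions Tibble with columns `portion_id`, `label`, `grams`.
#' @param questions Tibble of question nodes: `question_id`, `qtype`,
#'   `prompt`, `field` (imputable field name for detail/preparation nodes),
#'   `refines_item_id`, `trigger_question_id`, `trigger_option_id`,
#'   `warning`. Row order is presentation order.
#' @param options Tibble of answer options: `question_id`, `option_id`,
#'   `label`, `item_id`, `food_code_override`, `portion_id`.
#' @param manifest List with at least `schema_version`; optionally
#'   `expected_counts`, a named list checked by [validate_counts()].
#'
#' @return An object of class `food_db`.
#' @seealso [load_food_db()], [write_food_db()], [fixture_food_db()]
#' @export
new_food_db <- function(items, recipes, composition, portions,
                        questions, options,
                        manifest = list(schema_version = "1.0")) {
  db <- structure(
    list(
      items = as_tibble(items),
      recipes = as_tibble(recipes),
      composition = as_tibble(composition),
      portions = as_tibble(portions),
      questions = as_tibble(questions),
      options = as_tibble(options),
      manifest = manifest
    ),
    class = "food_db"
  )
  validate_food_db(db)
}

item_kinds <- c("individual", "grouped", "preparation")
question_types <- c("restriction", "key", "type_amount", "added_item",
                    "preparation", "detail", "usual_intake", "supplement")
food_question_types <- c("key", "type_amount", "added_item", "preparation", "detail")
imputable_fields <- c("type", "source", "preparation")

# Full structural validation; returns the (possibly normalised) database.
validate_food_db <- function(db) {
  it <- db$items
  cmp <- db$composition
  rec <- db$recipes
  qs <- db$questions
  op <- db$options

  fail <- function(file, record, rule) {
    nova_abort(
      sprintf("database validation failed [%s] record '%s': %s", file, record, rule),
      "nova24r_schema_error"
    )
  }
  integrity <- function(file, record, rule) {
    nova_abort(
      sprintf("referential integrity violation [%s] record '%s': %s", file, record, rule),
      "nova24r_integrity_error"
    )
  }

  if (anyDuplicated(it$item_id)) fail("items", it$item_id[duplicated(it$item_id)][1], "duplicate item_id")
  if (anyDuplicated(cmp$food_code)) fail("composition", cmp$food_code[duplicated(cmp$food_code)][1], "duplicate food_code")
  if (anyDuplicated(qs$question_id)) fail("questions", qs$question_id[duplicated(qs$question_id)][1], "duplicate question_id")

  bad_kind <- !it$kind %in% item_kinds
  if (any(bad_kind)) fail("items", it$item_id[bad_kind][1], "kind must be individual/grouped/preparation")
  bad_qtype <- !qs$qtype %in% question_types
  if (any(bad_qtype)) fail("questions", qs$question_id[bad_qtype][1], "unknown question type")

  # Nova group present iff the item is not a preparation (a preparation's Nova
  # content comes from its ingredients).
  prep <- it$kind == "preparation"
  if (any(prep & !is.na(it$nova_group))) {
    fail("items", it$item_id[prep & !is.na(it$nova_group)][1], "preparations carry no nova_group")
  }
  if (any(!prep & is.na(it$nova_group))) {
    fail("items", it$item_id[!prep & is.na(it$nova_group)][1], "non-preparation items need a nova_group")
  }
  if (any(!it$nova_group[!prep] %in% 1:4)) {
    fail("items", it$item_id[!prep][!it$nova_group[!prep] %in% 1:4][1], "nova_group must be 1..4")
  }
  if (any(prep & !is.na(it$food_code))) {
    fail("items", it$item_id[prep & !is.na(it$food_code)][1], "preparations carry no food_code")
  }
  if (any(!prep & is.na(it$food_code))) {
    fail("items", it$item_id[!prep & is.na(it$food_code)][1], "non-preparation items need a food_code")
  }

  grp <- it$kind == "grouped"
  n_members <- vapply(it$member_labels, length, integer(1))
  if (any(grp & n_members < 2L)) {
    fail("items", it$item_id[grp & n_members < 2L][1], "grouped items need >= 2 member labels")
  }
  if (any(!grp & n_members > 0L)) {
    fail("items", it$item_id[!grp & n_members > 0L][1], "member_labels only allowed for grouped items")
  }
  rep_ok <- mapply(function(r, m) is.na(r) || r %in% m, it$representative, it$member_labels)
  if (any(grp & (is.na(it$representative) | !rep_ok))) {
    fail("items", it$item_id[grp & (is.na(it$representative) | !rep_ok)][1],
         "grouped items must name a representative drawn from member_labels")
  }

  # composition closure
  miss <- setdiff(stats::na.omit(it$food_code), cmp$food_code)
  if (length(miss)) integrity("items", miss[1], "food_code missing from composition table")
  miss <- setdiff(rec$food_code, cmp$food_code)
  if (length(miss)) integrity("recipes", miss[1], "ingredient food_code missing from composition table")
  if (any(is.na(cmp$nova_group) | !cmp$nova_group %in% 1:4)) {
    fail("composition", cmp$food_code[is.na(cmp$nova_group) | !cmp$nova_group %in% 1:4][1],
         "every composition entry needs a Nova group 1..4")
  }
  if (any(cmp$energy_kcal_per_100g < 0, na.rm = TRUE)) {
    fail("composition", cmp$food_code[cmp$energy_kcal_per_100g < 0][1], "negative energy")
  }

  # macronutrient plausibility (4/4/9 kcal/g within +-30%): warning, not error,
  # so deliberately degenerate test fixtures still load.
  has_macros <- stats::complete.cases(cmp[, c("protein_g", "carb_g", "fat_g")])
  macro_kcal <- 4 * cmp$protein_g + 4 * cmp$carb_g + 9 * cmp$fat_g
  check <- has_macros & !is.na(cmp$energy_kcal_per_100g) & cmp$energy_kcal_per_100g > 0
  off <- check & abs(macro_kcal - cmp$energy_kcal_per_100g) > 0.30 * cmp$energy_kcal_per_100g
  if (any(off)) {
    warn(sprintf(
      "composition: macronutrient energy deviates by more than 30%% from stated energy for %d code(s) (e.g. '%s')",
      sum(off), cmp$food_code[which(off)[1]]
    ), class = "nova24r_plausibility_warning")
  }

  # recipes: one recipe per preparation item, positive fractions, unit sum
  rec_items <- unique(rec$item_id)
  miss <- setdiff(it$item_id[prep], rec_items)
  if (length(miss)) integrity("recipes", miss[1], "preparation item has no recipe")
  extra <- setdiff(rec_items, it$item_id[prep])
  if (length(extra)) integrity("recipes", extra[1], "recipe references a non-preparation item")
  if (any(rec$mass_fraction <= 0)) {
    fail("recipes", rec$item_id[rec$mass_fraction <= 0][1], "mass fractions must be strictly positive")
  }
  if (nrow(rec)) {
    sums <- tapply(rec$mass_fraction, rec$item_id, sum)
    off <- abs(sums - 1) > 1e-9
    if (any(off)) {
      warn(sprintf(
        "recipes: mass fractions of %d recipe(s) do not sum to 1 (e.g. '%s' sums to %.6f); renormalising",
        sum(off), names(sums)[which(off)[1]], sums[which(off)[1]]
      ), class = "nova24r_normalisation_warning")
      db$recipes <- rec %>%
        dplyr::group_by(.data$item_id) %>%
        dplyr::mutate(mass_fraction = .data$mass_fraction / sum(.data$mass_fraction)) %>%
        dplyr::ungroup()
      rec <- db$recipes
    }
  }

  # options: references resolve
  bad <- !op$question_id %in% qs$question_id
  if (any(bad)) integrity("options", op$question_id[bad][1], "option references unknown question")
  bad <- !is.na(op$item_id) & !op$item_id %in% it$item_id
  if (any(bad)) integrity("options", op$item_id[bad][1], "option binds unknown item")
  bad <- !is.na(op$food_code_override) & !op$food_code_override %in% cmp$food_code
  if (any(bad)) integrity("options", op$food_code_override[bad][1], "option overrides to unknown food_code")
  bad <- !is.na(op$portion_id) & !op$portion_id %in% db$portions$portion_id
  if (any(bad)) integrity("options", op$portion_id[bad][1], "option references unknown portion")
  if (anyDuplicated(paste(op$question_id, op$option_id))) {
    fail("options", op$question_id[duplicated(paste(op$question_id, op$option_id))][1],
         "duplicate option_id within question")
  }

  # question graph: triggers resolve, roots are root types, acyclic
  root_types <- c("restriction", "key", "usual_intake", "supplement")
  is_root <- is.na(qs$trigger_question_id)
  if (any(!is_root & qs$qtype %in% root_types)) {
    fail("questions", qs$question_id[!is_root & qs$qtype %in% root_types][1],
         "restriction/key/usual-intake/supplement questions must be roots")
  }
  if (any(is_root & !qs$qtype %in% root_types)) {
    fail("questions", qs$question_id[is_root & !qs$qtype %in% root_types][1],
         "follow-up questions need a trigger")
  }
  bad <- !is_root & !qs$trigger_question_id %in% qs$question_id
  if (any(bad)) integrity("questions", qs$question_id[bad][1], "trigger references unknown question")
  bad <- !is.na(qs$trigger_option_id) &
    !paste(qs$trigger_question_id, qs$trigger_option_id) %in% paste(op$question_id, op$option_id)
  if (any(bad)) integrity("questions", qs$question_id[bad][1], "trigger references unknown option")
  bad <- !is.na(qs$refines_item_id) & !qs$refines_item_id %in% it$item_id
  if (any(bad)) integrity("questions", qs$question_id[bad][1], "refines unknown item")
  if (any(qs$qtype %in% c("detail", "preparation") & !qs$field %in% imputable_fields)) {
    fail("questions",
         qs$question_id[qs$qtype %in% c("detail", "preparation") & !qs$field %in% imputable_fields][1],
         "detail/preparation questions must declare field type/source/preparation")
  }
  # acyclicity: walk up the trigger chain from each node
  parent <- stats::setNames(qs$trigger_question_id, qs$question_id)
  for (q in qs$question_id) {
    seen <- character()
    cur <- q
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) integrity("questions", q, "cycle in trigger chain")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (length(seen) > nrow(qs)) integrity("questions", q, "cycle in trigger chain")
    }
  }

  # each item is owned by an existing key question and bound by at least one option
  bad <- !it$key_question_id %in% qs$question_id[qs$qtype == "key"]
  if (any(bad)) integrity("items", it$item_id[bad][1], "key_question_id is not a key question")
  unbound <- setdiff(it$item_id, c(op$item_id[!is.na(op$item_id)], qs$refines_item_id))
  if (length(unbound)) integrity("items", unbound[1], "item not reachable from any question option")

  db
}

#' Summarise database structure and check it against an expected-count manifest
#'
#' Reports item counts by kind, the number of recipes, and question counts by
#' type (plus the total number of food-related questions). When the database
#' manifest carries `expected_counts`, or one is supplied, each observed count
#' is compared against it and mismatches are flagged.
#'
#' @param db A `food_db`.
#' @param expected Optional named list of expected counts; defaults to
#'   `db$manifest$expected_counts`.
#' @return A tibble with columns `count`, `observed`, `expected`, `match`.
#' @export
validate_counts <- function(db, expected = NULL) {
  stopifnot(inherits(db, "food_db"))
  expected <- expected %||% db$manifest$expected_counts
  qt <- table(factor(db$questions$qtype, levels = question_types))
  observed <- c(
    items_individual_grouped = sum(db$items$kind %in% c("individual", "grouped")),
    items_preparation = sum(db$items$kind == "preparation"),
    items_total = nrow(db$items),
    recipes = length(unique(db$recipes$item_id)),
    questions_key = unname(qt[["key"]]),
    questions_type_amount = unname(qt[["type_amount"]]),
    questions_added_item = unname(qt[["added_item"]]),
    questions_preparation = unname(qt[["preparation"]]),
    questions_detail = unname(qt[["detail"]]),
    questions_food_total = sum(qt[food_question_types])
  )
  exp_vec <- vapply(names(observed), function(nm) {
    if (!is.null(expected) && !is.null(expected[[nm]])) as.integer(expected[[nm]]) else NA_integer_
  }, integer(1))
  tibble(
    count = names(observed),
    observed = as.integer(unname(observed)),
    expected = unname(exp_vec),
    match = is.na(exp_vec) | exp_vec == as.integer(unname(observed))
  )
}

#' @export
print.food_db <- function(x, ...) {
  cat("<food_db> schema", x$manifest$schema_version %||% "?", "\n")
  cc <- validate_counts(x)
  cat(sprintf(
    "  %d items (%d individual/grouped, %d preparations), %d recipes\n",
    cc$observed[cc$count == "items_total"],
    cc$observed[cc$count == "items_individual_grouped"],
    cc$observed[cc$count == "items_preparation"],
    cc$observed[cc$count == "recipes"]
  ))
  cat(sprintf(
    "  %d questions (%d food questions), %d composition entries, %d portions\n",
    nrow(x$questions), cc$observed[cc$count == "questions_food_total"],
    nrow(x$composition), nrow(x$portions)
  ))
  invisible(x)
}

# ---- bundle I/O -------------------------------------------------------------

#' Load a food database bundle from disk
#'
#' A bundle is a directory with `items.csv`, `recipes.csv`, `composition.csv`,
#' `portions.csv`, `questions.json` and `manifest.yaml` (UTF-8, `.` decimal
#' separator). Grouped-item member labels are pipe-separated in `items.csv`.
#' Composition energy may be given as `energy_kj_per_100g` instead of kcal;
#' it is converted at 4.184 kJ/kcal with a note.
#'
#' @param path Bundle directory.
#' @return A validated `food_db`.
#' @export
load_food_db <- function(path) {
  need <- c("items.csv", "recipes.csv", "composition.csv", "portions.csv",
            "questions.json", "manifest.yaml")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    nova_abort(sprintf("bundle at '%s' is missing: %s", path,
                       paste(missing, collapse = ", ")),
               "nova24r_schema_error")
  }
  rd <- function(f, types) readr::read_csv(file.path(path, f), col_types = types,
                                           progress = FALSE)
  items <- rd("items.csv", readr::cols(
    item_id = "c", label = "c", key_question_id = "c", kind = "c",
    food_code = "c", member_labels = "c", representative = "c",
    nova_group = "i", nova_subgroup = "c"
  ))
  items$member_labels <- lapply(items$member_labels, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
  })
  recipes <- rd("recipes.csv", readr::cols(
    item_id = "c", food_code = "c", mass_fraction = "d", source = "c"
  ))
  composition <- rd("composition.csv", readr::cols(.default = "d", food_code = "c",
                                                   nova_group = "i", nova_subgroup = "c"))
  if (!"energy_kcal_per_100g" %in% names(composition) &&
      "energy_kj_per_100g" %in% names(composition)) {
    inform("composition energies given in kJ; converting to kcal at 4.184 kJ/kcal")
    composition$energy_kcal_per_100g <- composition$energy_kj_per_100g / 4.184
    composition$energy_kj_per_100g <- NULL
  }
  portions <- rd("portions.csv", readr::cols(portion_id = "c", label = "c", grams = "d"))

  qj <- jsonlite::fromJSON(file.path(path, "questions.json"), simplifyVector = FALSE)
  questions <- purrr::map_dfr(qj, function(n) tibble(
    question_id = n$question_id, qtype = n$qtype, prompt = n$prompt %||% "",
    field = n$field %||% NA_character_,
    refines_item_id = n$refines_item_id %||% NA_character_,
    trigger_question_id = n$trigger_question_id %||% NA_character_,
    trigger_option_id = n$trigger_option_id %||% NA_character_,
    warning = n$warning %||% NA_character_
  ))
  options <- purrr::map_dfr(qj, function(n) {
    purrr::map_dfr(n$options %||% list(), function(o) tibble(
      question_id = n$question_id, option_id = o$option_id, label = o$label %||% "",
      item_id = o$item_id %||% NA_character_,
      food_code_override = o$food_code_override %||% NA_character_,
      portion_id = o$portion_id %||% NA_character_
    ))
  })
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  new_food_db(items, recipes, composition, portions, questions, options, manifest)
}

#' Write a food database bundle to disk
#'
#' Inverse of [load_food_db()]: `load_food_db(write_food_db(db, path))` is
#' field-for-field identical to `db` after normalisation. All files are
#' written atomically.
#'
#' @param db A `food_db`.
#' @param path Destination directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  stopifnot(inherits(db, "food_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  items <- db$items
  items$member_labels <- vapply(items$member_labels, paste, character(1), collapse = "|")
  items$member_labels[!nzchar(items$member_labels)] <- NA_character_
  wcsv <- function(x, f) write_atomic(file.path(path, f), function(tmp) {
    readr::write_csv(x, tmp, na = "", progress = FALSE)
  })
  wcsv(items, "items.csv")
  wcsv(db$recipes, "recipes.csv")
  wcsv(db$composition, "composition.csv")
  wcsv(db$portions, "portions.csv")
  nodes <- purrr::pmap(db$questions, function(question_id, qtype, prompt, field,
                                              refines_item_id, trigger_question_id,
                                              trigger_option_id, warning) {
    n <- list(question_id = question_id, qtype = qtype, prompt = prompt)
    if (!is.na(field)) n$field <- field
    if (!is.na(refines_item_id)) n$refines_item_id <- refines_item_id
    if (!is.na(trigger_question_id)) n$trigger_question_id <- trigger_question_id
    if (!is.na(trigger_option_id)) n$trigger_option_id <- trigger_option_id
    if (!is.na(warning)) n$warning <- warning
    ops <- db$options[db$options$question_id == question_id, ]
    n$options <- purrr::pmap(ops, function(question_id, option_id, label, item_id,
                                           food_code_override, portion_id) {
      o <- list(option_id = option_id, label = label)
      if (!is.na(item_id)) o$item_id <- item_id
      if (!is.na(food_code_override)) o$food_code_override <- food_code_override
      if (!is.na(portion_id)) o$portion_id <- portion_id
      o
    })
    n
  })
  write_atomic(file.path(path, "questions.json"), function(tmp) {
    jsonlite::write_json(nodes, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  write_atomic(file.path(path, "manifest.yaml"), function(tmp) {
    yaml::write_yaml(db$manifest, tmp)
  })
  invisible(path)
}
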