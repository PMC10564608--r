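test_that("mini fixture covers every item kind, question type and Nova group", {
  db <- mini_db
  expect_s3_class(db, "food_db")
  expect_setequal(unique(db$items$kind), c("individual", "grouped", "preparation"))
  expect_setequal(unique(db$questions$qtype),
                  c("restriction", "key", "type_amount", "added_item",
                    "preparation", "detail", "usual_intake", "supplement"))
  expect_setequal(sort(unique(db$composition$nova_group)), 1:4)
  expect_gte(length(unique(db$recipes$item_id)), 3L)
  rice <- db$recipes[db$recipes$item_id == "rice_cooked", ]
  expect_setequal(rice$food_code, c("C_RICE", "C_OIL", "C_ONION", "C_GARLIC", "C_SALT"))
  cc <- validate_counts(db)
  expect_true(all(cc$match))
})

test_that("paper-shape fixture reproduces the instrument's structural counts", {
  db <- fixture_food_db("paper_shape", seed = 1)
  cc <- validate_counts(db)
  get <- function(nm) cc$observed[cc$count == nm]
  expect_identical(get("items_total"), 526L)
  expect_identical(get("items_individual_grouped"), 347L)
  expect_identical(get("items_preparation"), 179L)
  expect_identical(get("recipes"), 179L)
  expect_identical(get("questions_key"), 57L)
  expect_identical(get("questions_type_amount"), 190L)
  expect_identical(get("questions_added_item"), 47L)
  expect_identical(get("questions_preparation"), 19L)
  expect_identical(get("questions_detail"), 82L)
  expect_identical(get("questions_food_total"), 395L)
  expect_true(all(cc$match))
  # 10 of the 179 recipes use an adapted rather than standard source
  adapted <- unique(db$recipes$item_id[db$recipes$source == "adapted"])
  expect_length(adapted, 10L)
})

test_that("fixture generation is deterministic and bundles are byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_food_db(fixture_food_db("paper_shape", seed = 42), d1)
  write_food_db(fixture_food_db("paper_shape", seed = 42), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes randomized content
  db_other <- fixture_food_db("paper_shape", seed = 43)
  expect_false(identical(db_other$composition$energy_kcal_per_100g,
                         fixture_food_db("paper_shape", seed = 42)$composition$energy_kcal_per_100g))
})

test_that("write/load round trip preserves the database field for field", {
  for (scale in c("mini", "paper_shape")) {
    db <- fixture_food_db(scale, seed = 7)
    dir <- withr::local_tempdir()
    write_food_db(db, dir)
    db2 <- load_food_db(dir)
    expect_equal(db$items, db2$items)
    expect_equal(db$recipes, db2$recipes)
    expect_equal(db$composition, db2$composition)
    expect_equal(db$portions, db2$portions)
    expect_equal(db$questions, db2$questions)
    expect_equal(db$options, db2$options)
    expect_equal(db$manifest$expected_counts, db2$manifest$expected_counts)
  }
})

test_that("recipe fractions off unit sum are renormalised with a warning", {
  db <- mini_db
  rec <- db$recipes
  rec$mass_fraction[rec$item_id == "rice_cooked"] <-
    rec$mass_fraction[rec$item_id == "rice_cooked"] * 0.98
  expect_warning(
    db2 <- new_food_db(db$items, rec, db$composition, db$portions,
                       db$questions, db$options, db$manifest),
    class = "nova24r_normalisation_warning"
  )
  sums <- tapply(db2$recipes$mass_fraction, db2$recipes$item_id, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("dangling references raise integrity errors naming the record", {
  db <- mini_db
  rec <- db$recipes
  rec$food_code[1] <- "C_NOT_A_CODE"
  expect_error(
    new_food_db(db$items, rec, db$composition, db$portions,
                db$questions, db$options, db$manifest),
    "C_NOT_A_CODE", class = "nova24r_integrity_error"
  )
  it <- db$items
  it$food_code[it$item_id == "apple"] <- "C_MISSING"
  expect_error(
    new_food_db(it, db$recipes, db$composition, db$portions,
                db$questions, db$options, db$manifest),
    class = "nova24r_integrity_error"
  )
})

test_that("schema violations are rejected", {
  db <- mini_db
  # preparation with a Nova group
  it <- db$items
  it$nova_group[it$item_id == "rice_cooked"] <- 1L
  expect_error(new_food_db(it, db$recipes, db$composition, db$portions,
                           db$questions, db$options, db$manifest),
               class = "nova24r_schema_error")
  # grouped item with a single member
  it <- db$items
  it$member_labels[it$item_id == "fish_fresh"] <- list("salmon")
  expect_error(new_food_db(it, db$recipes, db$composition, db$portions,
                           db$questions, db$options, db$manifest),
               class = "nova24r_schema_error")
  # non-positive recipe fraction
  rec <- db$recipes
  rec$mass_fraction[1] <- 0
  expect_error(new_food_db(db$items, rec, db$composition, db$portions,
                           db$questions, db$options, db$manifest),
               class = "nova24r_schema_error")
})

test_that("implausible macronutrient energy warns but still loads", {
  db <- mini_db
  cmp <- db$composition
  cmp$energy_kcal_per_100g[cmp$food_code == "C_APPLE"] <- 400
  expect_warning(
    db2 <- new_food_db(db$items, db$recipes, cmp, db$portions,
                       db$questions, db$options, db$manifest),
    class = "nova24r_plausibility_warning"
  )
  expect_s3_class(db2, "food_db")
})

test_that("kJ composition energies are converted at load", {
  db <- mini_db
  dir <- withr::local_tempdir()
  write_food_db(db, dir)
  cmp <- readr::read_csv(file.path(dir, "composition.csv"), show_col_types = FALSE)
  cmp$energy_kj_per_100g <- cmp$energy_kcal_per_100g * 4.184
  cmp$energy_kcal_per_100g <- NULL
  readr::write_csv(cmp, file.path(dir, "composition.csv"))
  expect_message(db2 <- load_food_db(dir), "4.184")
  expect_equal(db2$composition$energy_kcal_per_100g,
               db$composition$energy_kcal_per_100g,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("count report flags mismatches against a manifest", {
  db <- mini_db
  rep <- validate_counts(db, expected = list(items_total = 2L))
  expect_false(rep$match[rep$count == "items_total"])
  expect_true(all(rep$match[rep$count != "items_total"]))
})

test_that("every item is owned by one key question and reachable in traversal", {
  for (scale in c("mini", "paper_shape")) {
    db <- fixture_food_db(scale, seed = 3)
    keys <- db$questions$question_id[db$questions$qtype == "key"]
    expect_true(all(db$items$key_question_id %in% keys))
    # ownership is unique by construction (a single key_question_id per item)
    expect_identical(anyDuplicated(db$items$item_id), 0L)
    # every item is bound by at least one option or refine question
    bound <- union(db$options$item_id[!is.na(db$options$item_id)],
                   db$questions$refines_item_id[!is.na(db$questions$refines_item_id)])
    expect_setequal(setdiff(db$items$item_id, bound), character())
  }
})
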