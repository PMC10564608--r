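test_that("skipped source fields distribute mass over the population options", {
  # 100 g of honey bread with unknown origin: 20.4% homemade, 28% bakery,
  # 51.6% branded packed
  out <- impute_missing("honey_bread", "source", 100, fixture_population_dists())
  expect_identical(out$option_id, c("homemade", "bakery", "packed"))
  expect_equal(out$grams, c(20.4, 28.0, 51.6))
  expect_equal(sum(out$grams), 100, tolerance = 1e-12)  # exact conservation
  expect_true(all(out$imputed))
})

test_that("imputation conserves mass exactly for arbitrary distributions", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    sh <- stats::rgamma(k, 1)
    sh <- sh / sum(sh)
    dist <- tibble::tibble(item_id = "x", field = "type",
                           option_id = paste0("o", seq_len(k)), share = sh)
    g <- stats::runif(1, 1, 500)
    out <- impute_missing("x", "type", g, dist)
    expect_equal(sum(out$grams), g, tolerance = 1e-12)
  }
  # single-option distribution passes everything through
  one <- tibble::tibble(item_id = "x", field = "type", option_id = "a", share = 1)
  expect_equal(impute_missing("x", "type", 50, one)$grams, 50)
})

test_that("imputation without a distribution errors unless uniform fallback is set", {
  expect_error(impute_missing("unknown_item", "type", 10, fixture_population_dists()),
               class = "nova24r_imputation_error")
  expect_message(
    out <- impute_missing("unknown_item", "type", 10, NULL, fallback = "uniform",
                          options = c("a", "b")),
    "uniform"
  )
  expect_equal(out$grams, c(5, 5))
})

test_that("disaggregation splits dish mass by recipe fractions, conserving mass", {
  db <- mini_db
  out <- disaggregate("rice_cooked", 200, db)
  expect_identical(nrow(out), 5L)
  expect_setequal(out$food_code, c("C_RICE", "C_OIL", "C_ONION", "C_GARLIC", "C_SALT"))
  expect_equal(sum(out$grams), 200, tolerance = 1e-12)
  expect_error(disaggregate("apple", 100, db), class = "nova24r_contract_error")
})

test_that("dish energy equals the composition-table sum over ingredients", {
  db <- mini_db
  for (item in unique(db$recipes$item_id)) {
    grams <- 180
    out <- disaggregate(item, grams, db)
    # oracle: recompute energy directly from the composition table
    oracle <- sum(vapply(seq_len(nrow(out)), function(i) {
      e <- db$composition$energy_kcal_per_100g[
        db$composition$food_code == out$food_code[i]]
      out$grams[i] * e / 100
    }, double(1)))
    rec <- db$recipes[db$recipes$item_id == item, ]
    pipeline <- sum(grams * rec$mass_fraction *
                      db$composition$energy_kcal_per_100g[
                        match(rec$food_code, db$composition$food_code)] / 100)
    expect_equal(pipeline, oracle, tolerance = 1e-12)
  }
})

test_that("a single reported apple resolves through the whole pipeline", {
  db <- mini_db
  s <- build_session(db, yes = "K_FRUIT", answers = list(ans("T_FRUIT", "apple", 1)))
  rec <- process_session(s, db)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$resolved_code, "C_APPLE")
  expect_identical(rec$nova_group, 1L)
  expect_equal(rec$grams, 130)           # one apple = 130 g
  expect_equal(rec$energy_kcal, 130 * 52 / 100)
  expect_false(rec$imputed)
})

test_that("an all-'no' session yields an empty record list", {
  db <- mini_db
  s <- build_session(db)
  rec <- process_session(s, db)
  expect_identical(nrow(rec), 0L)
})

test_that("a honey-bread report with missing source becomes three imputed records", {
  db <- mini_db
  s <- build_session(db, yes = "K_BREAD",
                     answers = list(ans("T_BREAD", "bread", 100 / 60),
                                    ans("D_BREAD_SOURCE", NA)))
  rec <- process_session(s, db, dists = fixture_population_dists())
  expect_identical(nrow(rec), 3L)
  expect_true(all(rec$imputed))
  expect_equal(sort(rec$grams), sort(c(20.4, 28.0, 51.6)), tolerance = 1e-12)
  expect_equal(sum(rec$grams), 100, tolerance = 1e-12)
  expect_setequal(rec$resolved_code,
                  c("C_HONEYBREAD_HOME", "C_HONEYBREAD_BAKERY", "C_HONEYBREAD_PACKED"))
  # homemade/bakery are Nova 3; branded packed is ultra-processed
  expect_setequal(rec$nova_group[rec$resolved_code == "C_HONEYBREAD_PACKED"], 4L)
})

test_that("an answered source field overrides the resolved code without imputation", {
  db <- mini_db
  s <- build_session(db, yes = "K_BREAD",
                     answers = list(ans("T_BREAD", "bread", 1),
                                    ans("D_BREAD_SOURCE", "homemade")))
  rec <- process_session(s, db)
  expect_identical(rec$resolved_code, "C_HONEYBREAD_HOME")
  expect_false(any(rec$imputed))
})

test_that("supplements are excluded from consumption records", {
  db <- mini_db
  s <- build_session(db, supplement = "yes")
  rec <- process_session(s, db)
  expect_identical(nrow(rec), 0L)
})

test_that("nova_shares computes relative energy contributions", {
  rec1 <- tibble::tibble(participant_id = "p", energy_kcal = c(10, 20),
                         nova_group = c(1L, 1L))
  expect_equal(nova_shares(rec1)$share_pct, c(100, 0, 0, 0))

  # 300 kcal group 1 + 100 kcal group 4 -> 75% / 25%
  rec2 <- tibble::tibble(participant_id = "p", energy_kcal = c(300, 100),
                         nova_group = c(1L, 4L))
  expect_equal(nova_shares(rec2)$share_pct, c(75, 0, 0, 25))

  # shares always sum to 100 for positive energy
  set.seed(1)
  for (i in 1:20) {
    rec <- tibble::tibble(participant_id = "p",
                          energy_kcal = stats::runif(10, 0, 400),
                          nova_group = sample(1:4, 10, replace = TRUE))
    expect_equal(sum(nova_shares(rec)$share_pct), 100, tolerance = 1e-6)
  }

  # zero-energy recall is flagged, not silently zeroed
  rec0 <- tibble::tibble(participant_id = "p", energy_kcal = 0, nova_group = 2L)
  out <- nova_shares(rec0)
  expect_true(all(out$zero_energy))
  expect_true(all(is.na(out$share_pct)))

  # mixed participants are a contract error
  recm <- tibble::tibble(participant_id = c("a", "b"), energy_kcal = 1,
                         nova_group = 1L)
  expect_error(nova_shares(recm), class = "nova24r_contract_error")
  expect_identical(nrow(nova_shares_all(recm)), 8L)
})

test_that("records with no missing fields pass through unchanged by imputation", {
  db <- mini_db
  s <- build_session(db, yes = c("K_MILK", "K_RICE"),
                     answers = list(ans("T_MILK", "whole", 1),
                                    ans("A_MILK_SUGAR", "none"),
                                    ans("T_RICE", "rice", 2)))
  with_dists <- process_session(s, db, dists = fixture_population_dists())
  without <- process_session(s, db, dists = NULL)
  expect_equal(with_dists, without)
  expect_false(any(with_dists$imputed))
})

test_that("energy is additive across the long-format output", {
  db <- mini_db
  s <- build_session(db, yes = c("K_MILK", "K_RICE", "K_SOUP"),
                     answers = list(ans("T_MILK", "skim", 2),
                                    ans("A_MILK_SUGAR", "sugar", 1),
                                    ans("T_RICE", "rice", 3),
                                    ans("T_SOUP", "soup", 1)))
  rec <- process_session(s, db)
  # oracle totals computed directly from portions, recipes and composition
  e <- function(code) db$composition$energy_kcal_per_100g[db$composition$food_code == code]
  rice <- db$recipes[db$recipes$item_id == "rice_cooked", ]
  soup <- db$recipes[db$recipes$item_id == "veg_soup", ]
  oracle <- 2 * 200 * e("C_MILK_SKIM") / 100 +
    5 * e("C_SUGAR") / 100 +
    sum(3 * 45 * rice$mass_fraction * vapply(rice$food_code, e, 1) / 100) +
    sum(250 * soup$mass_fraction * vapply(soup$food_code, e, 1) / 100)
  expect_equal(sum(rec$energy_kcal), oracle, tolerance = 1e-9)
})
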