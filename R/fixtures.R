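#' Generate a fixture food database
#'
#' Two built-in databases support development and testing without any external
#' food-composition data. `"mini"` is a small hand-written database covering
#' every item kind and question type, all four Nova groups, and three recipes
#' (including a cooked-rice dish disaggregating into rice, oil, onion, garlic
#' and salt). `"paper_shape"` is generated programmatically to mirror the
#' structural counts of the full instrument: 57 yes/no key questions, 190
#' type-and-amount, 47 added-item, 19 preparation-method and 82 detail
#' questions (395 food questions in total) over 526 food items, of which 347
#' are individual or grouped items and 179 are culinary preparations, each
#' with a recipe. Labels, compositions and recipe proportions of the
#' paper-shape database are synthetic, drawn reproducibly from `seed`.
#'
#' @param scale `"mini"` or `"paper_shape"` (alias `"paper-shape"`).
#' @param seed Integer seed fixing all randomised content.
#' @return A validated `food_db`.
#' @export
fixture_food_db <- function(scale = c("mini", "paper_shape", "paper-shape"), seed = 1L) {
  scale <- match.arg(scale)
  switch(scale,
    mini = mini_food_db(),
    fixture_paper_shape(seed)
  )
}

# ---- mini fixture -----------------------------------------------------------

mini_food_db <- function() {
  cmpn <- function(code, kcal, p, c, f, g, sub) {
    tibble(food_code = code, energy_kcal_per_100g = kcal, protein_g = p,
           carb_g = c, fat_g = f, nova_group = as.integer(g), nova_subgroup = sub)
  }
  composition <- dplyr::bind_rows(
    cmpn("C_MILK_WHOLE", 61, 3.2, 4.6, 3.3, 1, "milk"),
    cmpn("C_MILK_SKIM", 35, 3.4, 5.0, 0.1, 1, "milk"),
    cmpn("C_SUGAR", 387, 0, 100, 0, 2, "table sugar"),
    cmpn("C_SALMON", 208, 20, 0, 13, 1, "fish"),
    cmpn("C_FISH_COOKED", 150, 26, 0, 5, 1, "fish"),
    cmpn("C_FISH_FRIED", 232, 22, 1, 16, 1, "fish"),
    cmpn("C_FISH_CANNED", 190, 24, 0, 10, 3, "canned fish"),
    cmpn("C_RICE", 130, 2.7, 28, 0.3, 1, "grains"),
    cmpn("C_OIL", 884, 0, 0, 100, 2, "plant oils"),
    cmpn("C_ONION", 40, 1.1, 9.3, 0.1, 1, "vegetables"),
    cmpn("C_GARLIC", 149, 6.4, 33, 0.5, 1, "vegetables"),
    cmpn("C_SALT", 0, 0, 0, 0, 2, "salt"),
    cmpn("C_BEANS", 91, 6, 16.6, 0.5, 1, "legumes"),
    cmpn("C_POTATO", 77, 2, 17, 0.1, 1, "vegetables"),
    cmpn("C_CARROT", 41, 0.9, 9.6, 0.2, 1, "vegetables"),
    cmpn("C_WATER", 0, 0, 0, 0, 1, "water"),
    cmpn("C_HONEYBREAD_HOME", 350, 5, 70, 6, 3, "breads"),
    cmpn("C_HONEYBREAD_BAKERY", 360, 6, 68, 8, 3, "breads"),
    cmpn("C_HONEYBREAD_PACKED", 375, 5, 72, 9, 4, "packaged breads"),
    cmpn("C_APPLE", 52, 0.3, 14, 0.2, 1, "fruits"),
    cmpn("C_BANANA", 89, 1.1, 23, 0.3, 1, "fruits"),
    cmpn("C_COLA", 42, 0, 10.6, 0, 4, "soft drinks")
  )

  itm <- function(id, label, key, kind, code, g, sub,
                  members = character(), representative = NA_character_) {
    tibble(item_id = id, label = label, key_question_id = key, kind = kind,
           food_code = code, member_labels = list(members),
           representative = representative,
           nova_group = if (is.na(g)) NA_integer_ else as.integer(g),
           nova_subgroup = sub)
  }
  items <- dplyr::bind_rows(
    itm("milk_whole", "whole milk", "K_MILK", "individual", "C_MILK_WHOLE", 1, "milk"),
    itm("milk_skim", "skimmed milk", "K_MILK", "individual", "C_MILK_SKIM", 1, "milk"),
    itm("sugar", "sugar", "K_MILK", "individual", "C_SUGAR", 2, "table sugar"),
    itm("fish_fresh", "fresh fish (salmon, tuna or sardine)", "K_FISH", "grouped",
        "C_SALMON", 1, "fish", members = c("salmon", "tuna", "sardine"),
        representative = "salmon"),
    itm("fish_canned", "canned fish", "K_FISH", "individual", "C_FISH_CANNED", 3, "canned fish"),
    itm("rice_cooked", "cooked rice", "K_RICE", "preparation", NA, NA, "rice dishes"),
    itm("beans_cooked", "cooked beans", "K_BEANS", "preparation", NA, NA, "bean dishes"),
    itm("veg_soup", "vegetable soup", "K_SOUP", "preparation", NA, NA, "soups"),
    itm("honey_bread", "honey bread", "K_BREAD", "individual", "C_HONEYBREAD_PACKED", 4,
        "packaged breads"),
    itm("apple", "apple", "K_FRUIT", "individual", "C_APPLE", 1, "fruits"),
    itm("banana", "banana", "K_FRUIT", "individual", "C_BANANA", 1, "fruits"),
    itm("cola", "cola soft drink", "K_SOFT", "individual", "C_COLA", 4, "soft drinks")
  )

  recipes <- dplyr::bind_rows(
    tibble(item_id = "rice_cooked",
           food_code = c("C_RICE", "C_OIL", "C_ONION", "C_GARLIC", "C_SALT"),
           mass_fraction = c(0.93, 0.03, 0.02, 0.012, 0.008),
           source = "standard"),
    tibble(item_id = "beans_cooked",
           food_code = c("C_BEANS", "C_OIL", "C_ONION", "C_GARLIC", "C_SALT"),
           mass_fraction = c(0.90, 0.04, 0.03, 0.02, 0.01),
           source = "standard"),
    tibble(item_id = "veg_soup",
           food_code = c("C_POTATO", "C_CARROT", "C_ONION", "C_OIL", "C_WATER", "C_SALT"),
           mass_fraction = c(0.35, 0.30, 0.20, 0.08, 0.05, 0.02),
           source = "adapted")
  )

  portions <- tibble(
    portion_id = c("P_GLASS", "P_TSP", "P_FILET", "P_CAN120", "P_SPOON", "P_LADLE",
                   "P_BOWL", "P_SLICE", "P_APPLE", "P_BANANA", "P_CAN350"),
    label = c("glass (200 ml)", "teaspoon", "fish filet", "small can", "serving spoon",
              "ladle", "bowl", "slice", "one apple", "one banana", "can (350 ml)"),
    grams = c(200, 5, 100, 120, 45, 85, 250, 60, 130, 90, 350)
  )

  qn <- function(id, qtype, prompt, field = NA, refines = NA, trig_q = NA,
                 trig_o = NA, warning = NA) {
    tibble(question_id = id, qtype = qtype, prompt = prompt,
           field = as.character(field), refines_item_id = as.character(refines),
           trigger_question_id = as.character(trig_q),
           trigger_option_id = as.character(trig_o), warning = as.character(warning))
  }
  opt <- function(q, id, label, item = NA, override = NA, portion = NA) {
    tibble(question_id = q, option_id = id, label = label,
           item_id = as.character(item), food_code_override = as.character(override),
           portion_id = as.character(portion))
  }
  yes_no <- function(q) dplyr::bind_rows(opt(q, "yes", "Yes"), opt(q, "no", "No"))

  questions <- dplyr::bind_rows(
    qn("Q_RESTRICT", "restriction", "Do you follow a food restriction or special diet?"),
    qn("K_MILK", "key", "Did you drink milk yesterday?",
       warning = paste("Attention! DO NOT include milk added to porridge or breakfast",
                       "cereal here so as not to duplicate what you ate.")),
    qn("T_MILK", "type_amount", "Which milk, and how many glasses?",
       trig_q = "K_MILK", trig_o = "yes"),
    qn("A_MILK_SUGAR", "added_item", "Did you add sugar? How many teaspoons?",
       trig_q = "T_MILK"),
    qn("K_FISH", "key", "Did you eat fish yesterday?"),
    qn("T_FISH", "type_amount", "Which fish, and how much?",
       trig_q = "K_FISH", trig_o = "yes"),
    qn("P_FISH_PREP", "preparation", "How was the fresh fish prepared?",
       field = "preparation", refines = "fish_fresh", trig_q = "T_FISH", trig_o = "fresh"),
    qn("K_RICE", "key", "Did you eat rice yesterday?"),
    qn("T_RICE", "type_amount", "How many serving spoons of cooked rice?",
       trig_q = "K_RICE", trig_o = "yes"),
    qn("K_BEANS", "key", "Did you eat beans yesterday?"),
    qn("T_BEANS", "type_amount", "How many ladles of cooked beans?",
       trig_q = "K_BEANS", trig_o = "yes"),
    qn("K_SOUP", "key", "Did you eat soup yesterday?"),
    qn("T_SOUP", "type_amount", "How many bowls of vegetable soup?",
       trig_q = "K_SOUP", trig_o = "yes"),
    qn("K_BREAD", "key", "Did you eat honey bread yesterday?"),
    qn("T_BREAD", "type_amount", "How many slices of honey bread?",
       trig_q = "K_BREAD", trig_o = "yes"),
    qn("D_BREAD_SOURCE", "detail", "Where did the honey bread come from?",
       field = "source", refines = "honey_bread", trig_q = "T_BREAD", trig_o = "bread"),
    qn("K_FRUIT", "key", "Did you eat fruit yesterday?"),
    qn("T_FRUIT", "type_amount", "Which fruit, and how many units?",
       trig_q = "K_FRUIT", trig_o = "yes"),
    qn("K_SOFT", "key", "Did you drink soft drinks yesterday?"),
    qn("T_SOFT", "type_amount", "How many cans of soft drink?",
       trig_q = "K_SOFT", trig_o = "yes"),
    qn("Q_USUAL1", "usual_intake",
       "Was yesterday's overall amount of food about usual, less or more?"),
    qn("Q_USUAL2", "usual_intake", "Does yesterday represent your typical daily intake?"),
    qn("Q_SUPP", "supplement", "Did you take vitamin or mineral supplements yesterday?")
  )

  options <- dplyr::bind_rows(
    opt("Q_RESTRICT", "none", "No restriction"),
    opt("Q_RESTRICT", "vegetarian", "Vegetarian"),
    opt("Q_RESTRICT", "vegan", "Vegan"),
    opt("Q_RESTRICT", "gluten_free", "Gluten-free"),
    yes_no("K_MILK"),
    opt("T_MILK", "whole", "Whole milk", item = "milk_whole", portion = "P_GLASS"),
    opt("T_MILK", "skim", "Skimmed milk", item = "milk_skim", portion = "P_GLASS"),
    opt("A_MILK_SUGAR", "sugar", "Yes, sugar", item = "sugar", portion = "P_TSP"),
    opt("A_MILK_SUGAR", "none", "No, nothing added"),
    yes_no("K_FISH"),
    opt("T_FISH", "fresh", "Fresh fish (salmon, tuna, sardine)",
        item = "fish_fresh", portion = "P_FILET"),
    opt("T_FISH", "canned", "Canned fish", item = "fish_canned", portion = "P_CAN120"),
    opt("P_FISH_PREP", "raw", "Raw or marinated"),
    opt("P_FISH_PREP", "cooked", "Cooked, roasted or grilled", override = "C_FISH_COOKED"),
    opt("P_FISH_PREP", "fried", "Fried or breaded", override = "C_FISH_FRIED"),
    yes_no("K_RICE"),
    opt("T_RICE", "rice", "Cooked rice", item = "rice_cooked", portion = "P_SPOON"),
    yes_no("K_BEANS"),
    opt("T_BEANS", "beans", "Cooked beans", item = "beans_cooked", portion = "P_LADLE"),
    yes_no("K_SOUP"),
    opt("T_SOUP", "soup", "Vegetable soup", item = "veg_soup", portion = "P_BOWL"),
    yes_no("K_BREAD"),
    opt("T_BREAD", "bread", "Honey bread", item = "honey_bread", portion = "P_SLICE"),
    opt("D_BREAD_SOURCE", "homemade", "Homemade", override = "C_HONEYBREAD_HOME"),
    opt("D_BREAD_SOURCE", "bakery", "Bought at a bakery", override = "C_HONEYBREAD_BAKERY"),
    opt("D_BREAD_SOURCE", "packed", "Branded packed", override = "C_HONEYBREAD_PACKED"),
    yes_no("K_FRUIT"),
    opt("T_FRUIT", "apple", "Apple", item = "apple", portion = "P_APPLE"),
    opt("T_FRUIT", "banana", "Banana", item = "banana", portion = "P_BANANA"),
    yes_no("K_SOFT"),
    opt("T_SOFT", "cola", "Cola", item = "cola", portion = "P_CAN350"),
    opt("Q_USUAL1", "usual", "About usual"),
    opt("Q_USUAL1", "less", "Less than usual"),
    opt("Q_USUAL1", "more", "More than usual"),
    yes_no("Q_USUAL2"),
    yes_no("Q_SUPP")
  )

  manifest <- list(
    schema_version = "1.0",
    name = "mini",
    expected_counts = list(
      items_individual_grouped = 9L, items_preparation = 3L, items_total = 12L,
      recipes = 3L, questions_key = 8L, questions_type_amount = 8L,
      questions_added_item = 1L, questions_preparation = 1L,
      questions_detail = 1L, questions_food_total = 19L
    )
  )
  new_food_db(items, recipes, composition, portions, questions, options, manifest)
}

#' Population answer distributions for the mini fixture
#'
#' Option shares used to impute skipped type/source/preparation answers, in
#' the same layout as the population-distributions CSV: one row per
#' `(item_id, field, option_id)` with a `share` column. The honey-bread
#' source shares are 0.204 homemade, 0.280 bakery and 0.516 branded packed.
#'
#' @return A tibble with columns `item_id`, `field`, `option_id`, `share`.
#' @export
fixture_population_dists <- function() {
  dplyr::bind_rows(
    tibble(item_id = "honey_bread", field = "source",
           option_id = c("homemade", "bakery", "packed"),
           share = c(0.204, 0.280, 0.516)),
    tibble(item_id = "fish_fresh", field = "preparation",
           option_id = c("raw", "cooked", "fried"),
           share = c(0.10, 0.60, 0.30))
  )
}

# ---- paper-shape fixture ----------------------------------------------------

# Structural counts of the full instrument.
PAPER_COUNTS <- list(
  key = 57L, type_amount = 190L, added_item = 47L, preparation = 19L,
  detail = 82L, items_individual_grouped = 347L, items_preparation = 179L
)

fixture_paper_shape <- function(seed) {
  with_seed(seed, {
    nk <- PAPER_COUNTS$key
    nta <- PAPER_COUNTS$type_amount
    # type-amount questions per key: 57*3 = 171, first 19 keys carry one extra
    ta_per_key <- rep(3L, nk) + c(rep(1L, nta - 3L * nk), rep(0L, nk - (nta - 3L * nk)))
    ta_key <- rep(seq_len(nk), ta_per_key)
    # items per type-amount question: 190*2 = 380, first 146 carry one extra
    n_items <- PAPER_COUNTS$items_individual_grouped + PAPER_COUNTS$items_preparation
    it_per_ta <- rep(2L, nta) + c(rep(1L, n_items - 2L * nta),
                                  rep(0L, nta - (n_items - 2L * nta)))
    item_ta <- rep(seq_len(nta), it_per_ta)

    kind <- rep("individual", n_items)
    kind[sample.int(n_items, PAPER_COUNTS$items_preparation)] <- "preparation"
    grouped_pool <- which(kind == "individual")
    kind[sample(grouped_pool, 40L)] <- "grouped"

    item_id <- sprintf("item_%03d", seq_len(n_items))
    item_code <- ifelse(kind == "preparation", NA_character_,
                        sprintf("C_ITEM_%03d", seq_len(n_items)))

    # ingredient pool for recipes + variant codes for refine-question overrides
    ing_code <- sprintf("C_ING_%02d", seq_len(30))
    nvar <- 2L * (PAPER_COUNTS$preparation + PAPER_COUNTS$detail)
    var_code <- sprintf("C_VAR_%03d", seq_len(nvar))

    all_codes <- c(stats::na.omit(item_code), ing_code, var_code)
    ncode <- length(all_codes)
    protein <- round(stats::runif(ncode, 0, 25), 1)
    carb <- round(stats::runif(ncode, 0, 60), 1)
    fat <- round(stats::runif(ncode, 0, 30), 1)
    macro <- 4 * protein + 4 * carb + 9 * fat
    composition <- tibble(
      food_code = all_codes,
      energy_kcal_per_100g = round(macro * stats::runif(ncode, 0.85, 1.15), 1),
      protein_g = protein, carb_g = carb, fat_g = fat,
      nova_group = sample(1:4, ncode, replace = TRUE),
      nova_subgroup = paste0("subgroup_", sample(1:12, ncode, replace = TRUE))
    )

    members <- lapply(seq_len(n_items), function(i) {
      if (kind[i] != "grouped") return(character())
      sprintf("member_%03d_%d", i, seq_len(sample(2:3, 1)))
    })
    representative <- vapply(members, function(m) {
      if (length(m)) m[[1]] else NA_character_
    }, character(1))

    items <- tibble(
      item_id = item_id,
      label = paste("food item", sprintf("%03d", seq_len(n_items))),
      key_question_id = sprintf("K%03d", ta_key[item_ta]),
      kind = kind,
      food_code = item_code,
      member_labels = members,
      representative = representative,
      nova_group = ifelse(kind == "preparation", NA_integer_,
                          composition$nova_group[match(item_code, composition$food_code)]),
      nova_subgroup = ifelse(kind == "preparation", "culinary preparations",
                             composition$nova_subgroup[match(item_code, composition$food_code)])
    )

    prep_ids <- item_id[kind == "preparation"]
    # 10 of the 179 recipes are adapted rather than standard
    adapted <- sample(prep_ids, 10L)
    recipes <- purrr::map_dfr(prep_ids, function(pid) {
      n_ing <- sample(3:5, 1)
      fr <- stats::rgamma(n_ing, shape = 2)
      tibble(item_id = pid,
             food_code = sample(ing_code, n_ing),
             mass_fraction = fr / sum(fr),
             source = if (pid %in% adapted) "adapted" else "standard")
    })

    portions <- tibble(
      portion_id = sprintf("P%02d", 1:8),
      label = c("teaspoon", "tablespoon", "cup", "glass", "bowl", "plate",
                "unit", "slice"),
      grams = c(5, 15, 150, 200, 250, 300, 110, 50)
    )

    qrows <- list()
    orows <- list()
    add_q <- function(id, qtype, prompt, field = NA, refines = NA, trig_q = NA,
                      trig_o = NA, warning = NA) {
      qrows[[length(qrows) + 1L]] <<- tibble(
        question_id = id, qtype = qtype, prompt = prompt,
        field = as.character(field), refines_item_id = as.character(refines),
        trigger_question_id = as.character(trig_q),
        trigger_option_id = as.character(trig_o), warning = as.character(warning))
    }
    add_o <- function(q, id, label, item = NA, override = NA, portion = NA) {
      orows[[length(orows) + 1L]] <<- tibble(
        question_id = q, option_id = id, label = label,
        item_id = as.character(item), food_code_override = as.character(override),
        portion_id = as.character(portion))
    }

    add_q("Q_RESTRICT", "restriction", "Do you follow a food restriction or special diet?")
    for (oo in c("none", "vegetarian", "vegan", "gluten_free")) {
      add_o("Q_RESTRICT", oo, oo)
    }

    ta_id <- sprintf("T%03d", seq_len(nta))
    # follow-up attachment: added-item on TA 1..47, preparation on the next 19,
    # detail on the 82 after that (disjoint, deterministic)
    np <- PAPER_COUNTS$preparation
    nd <- PAPER_COUNTS$detail
    na_ <- PAPER_COUNTS$added_item
    prep_ta <- seq.int(na_ + 1L, na_ + np)
    det_ta <- seq.int(na_ + np + 1L, na_ + np + nd)

    var_used <- 0L
    for (k in seq_len(nk)) {
      kid <- sprintf("K%03d", k)
      add_q(kid, "key", sprintf("Did you eat foods of group %d yesterday?", k),
            warning = if (k %% 10 == 1)
              "Attention! DO NOT record this food again under another question." else NA)
      add_o(kid, "yes", "Yes"); add_o(kid, "no", "No")
      for (t in which(ta_key == k)) {
        tid <- ta_id[t]
        add_q(tid, "type_amount", sprintf("Which type, and how much? (%s)", tid),
              trig_q = kid, trig_o = "yes")
        its <- which(item_ta == t)
        for (j in seq_along(its)) {
          add_o(tid, sprintf("o%d", j), items$label[its[j]],
                item = item_id[its[j]],
                portion = sample(portions$portion_id, 1))
        }
        if (t <= na_) {
          aid <- sprintf("A%03d", t)
          # the added item (e.g. sugar added to coffee) is one of this key's items
          add_q(aid, "added_item", "Did you add anything to it?",
                trig_q = tid)
          add_o(aid, "added", "Yes, added", item = item_id[its[1]], portion = "P01")
          add_o(aid, "none", "No, nothing added")
        }
        if (t %in% prep_ta || t %in% det_ta) {
          is_prep <- t %in% prep_ta
          fid <- if (is_prep) sprintf("P%03d", t) else sprintf("D%03d", t)
          field <- if (is_prep) "preparation" else sample(c("type", "source"), 1)
          ref <- item_id[its[1]]
          add_q(fid, if (is_prep) "preparation" else "detail",
                "How was it prepared or sourced?", field = field, refines = ref,
                trig_q = tid, trig_o = "o1")
          add_o(fid, "v0", "as reported")
          add_o(fid, "v1", "variant 1", override = var_code[var_used + 1L])
          add_o(fid, "v2", "variant 2", override = var_code[var_used + 2L])
          var_used <- var_used + 2L
        }
      }
    }
    add_q("Q_USUAL1", "usual_intake",
          "Was yesterday's overall amount of food about usual, less or more?")
    for (oo in c("usual", "less", "more")) add_o("Q_USUAL1", oo, oo)
    add_q("Q_USUAL2", "usual_intake", "Does yesterday represent your typical intake?")
    add_o("Q_USUAL2", "yes", "Yes"); add_o("Q_USUAL2", "no", "No")
    add_q("Q_SUPP", "supplement", "Did you take vitamin or mineral supplements?")
    add_o("Q_SUPP", "yes", "Yes"); add_o("Q_SUPP", "no", "No")

    manifest <- list(
      schema_version = "1.0",
      name = "paper_shape",
      seed = as.integer(seed),
      expected_counts = list(
        items_individual_grouped = PAPER_COUNTS$items_individual_grouped,
        items_preparation = PAPER_COUNTS$items_preparation,
        items_total = n_items,
        recipes = PAPER_COUNTS$items_preparation,
        questions_key = PAPER_COUNTS$key,
        questions_type_amount = PAPER_COUNTS$type_amount,
        questions_added_item = PAPER_COUNTS$added_item,
        questions_preparation = PAPER_COUNTS$preparation,
        questions_detail = PAPER_COUNTS$detail,
        questions_food_total = PAPER_COUNTS$key + PAPER_COUNTS$type_amount +
          PAPER_COUNTS$added_item + PAPER_COUNTS$preparation + PAPER_COUNTS$detail
      )
    )
    new_food_db(items, recipes, composition, portions,
                dplyr::bind_rows(qrows), dplyr::bind_rows(orows), manifest)
  })
}
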