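test_that("diet vectors average diary grams over 7 days", {
  foods <- fixture_foods()
  ev <- fixture_events(list(1, "lunch", "apple", 140))
  dv <- build_diet_vector(ev, foods)
  expect_equal(unname(dv$diet[1, "apple"]), 20)

  ev2 <- rbind(fixture_week(c(bread = 100)),
               fixture_events(list(3, "afternoon_snack", "cola", 330)))
  dv2 <- build_diet_vector(ev2, foods)
  expect_equal(unname(dv2$diet[1, "bread"]), 100)
  expect_equal(unname(dv2$diet[1, "cola"]), 330 / 7, tolerance = 1e-12)

  expect_error(build_diet_vector(
    fixture_events(list(1, "lunch", "nonexistent", 10)), foods), "unknown food")
})

test_that("alcoholic beverages are excluded from the diet vector", {
  foods <- fixture_foods()
  ev <- rbind(fixture_week(c(bread = 100)),
              fixture_events(list(2, "dinner", "wine", 140)))
  dv <- build_diet_vector(ev, foods)
  expect_equal(unname(dv$diet[1, "wine"]), 0)
  expect_equal(unname(dv$alcohol_g["P1"]), 20)
})

test_that("intakes are the linear roll-up of per-100 g contents", {
  foods <- fixture_foods()
  diet <- c(bread = 100)  # 250 kcal/100 g
  ik <- compute_intakes(diet, foods)
  expect_equal(unname(ik["energy"]), 250)

  # independently hand-computed 3-food profile
  diet3 <- c(bread = 150, apple = 80, cheese = 40)
  ik3 <- compute_intakes(diet3, foods)
  expect_equal(unname(ik3["energy"]), 1.5 * 250 + 0.8 * 52 + 0.4 * 330)
  expect_equal(unname(ik3["protein"]), 1.5 * 8 + 0.8 * 0.3 + 0.4 * 22)
  expect_equal(unname(ik3["sodium"]), 1.5 * 500 + 0.8 * 2 + 0.4 * 750)
  expect_equal(unname(ik3["free_sugars"]), 1.5 * 0.3)
  # sugar identity holds on any diet
  expect_equal(unname(ik3["non_free_sugars"]),
               unname(ik3["sugars"] - ik3["free_sugars"]))
  # linearity: doubling the diet doubles every nutrient
  expect_equal(compute_intakes(diet3 * 2, foods), ik3 * 2)
})

test_that("moment sub-totals decompose the daily totals exactly", {
  foods <- fixture_foods()
  ev <- rbind(fixture_week(c(bread = 80), moment = "breakfast"),
              fixture_week(c(cake = 50), moment = "afternoon_snack"),
              fixture_events(list(5, "evening_snack", "cola", 330)))
  sub <- moment_subtotals(ev, foods)
  dv <- build_diet_vector(ev, foods)
  ik <- compute_intakes(dv$diet, foods)
  expect_equal(sub$energy_meals + sub$energy_snacks, unname(ik[1, "energy"]),
               tolerance = 1e-9)
  expect_equal(sub$fs_meals + sub$fs_snacks, unname(ik[1, "free_sugars"]),
               tolerance = 1e-9)
  expect_equal(sub$energy_meals, 80 * 2.5)
  expect_equal(sub$energy_snacks, 50 * 3.8 + 330 * 0.42 / 7)
})

test_that("the Goldberg screen flags implausibly low reporters", {
  ind <- data.frame(individual_id = "A", age = 40, gender = "male",
                    weight = 75, height = 1.78,
                    physical_activity = "moderate", survey_weight = 1,
                    stringsAsFactors = FALSE)
  par <- goldberg_params()
  bmr <- 11.472 * 75 + 873.1
  expect_equal(goldberg_screen(ind, 0.5 * bmr), "under_reporter")
  expect_equal(goldberg_screen(ind, bmr * 1.6), "plausible")
  # exact cutoff boundary: one kcal either side flips the flag
  s <- sqrt(par$cv_wei^2 / 7 + par$cv_wb^2 + par$cv_tp^2)
  cutoff_ei <- bmr * 1.6 * exp(-2 * s / 100)
  expect_equal(goldberg_screen(ind, cutoff_ei + 1), "plausible")
  expect_equal(goldberg_screen(ind, cutoff_ei - 1), "under_reporter")
  # missing anthropometrics cannot be screened
  ind$weight <- NA
  expect_equal(goldberg_screen(ind, 2000), "unscreenable")
})

test_that("free-sugar classification uses the inclusive 10% boundary", {
  # share = 400 * fs / energy; construct exact shares
  expect_equal(classify_fs_group(14.2 * 2000 / 400, 2000), "FS_EXCESS")
  expect_equal(classify_fs_group(10.0 * 2000 / 400, 2000), "FS_ACCEPTABLE")
  expect_equal(classify_fs_group(6.3 * 2000 / 400, 2000), "FS_ACCEPTABLE")
  expect_equal(classify_fs_group(10.001 * 2000 / 400, 2000), "FS_EXCESS")
  expect_error(free_sugar_share(10, 0), "positive")
})

test_that("survey validation enforces the 7-day and age rules", {
  foods <- fixture_foods()
  ev <- rbind(fixture_week(c(bread = 100), id = "ok"),
              fixture_events(list(1, "lunch", "bread", 50), id = "short"))
  ind <- data.frame(individual_id = c("ok", "short", "old"),
                    age = c(30, 30, 80), survey_weight = 1,
                    stringsAsFactors = FALSE)
  expect_message(v <- validate_survey(ev, ind, foods), "dropped")
  expect_equal(v$individuals$individual_id, "ok")
  expect_true(all(v$events$individual_id == "ok"))

  bad <- fixture_events(list(9, "lunch", "bread", 50))
  expect_error(validate_survey(bad, ind, foods), "days")
  bad2 <- fixture_events(list(1, "tea-time", "bread", 50))
  expect_error(validate_survey(bad2, ind, foods), "moment")
})
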