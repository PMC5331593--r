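test_that("solid energy density uses solid foods only", {
  foods <- fixture_foods()
  # single solid food at 185 kcal/100 g (observed survey magnitude)
  f <- foods; f$energy[f$food_id == "bread"] <- 185
  expect_equal(solid_energy_density(c(bread = 100), f), 185)
  # beverages (water, cola) change nothing
  expect_equal(solid_energy_density(c(bread = 100, water = 1000, cola = 330), f),
               185)
  # 300 g of solids providing 450 kcal
  g <- foods; g$energy[g$food_id == "apple"] <- 150
  expect_equal(solid_energy_density(c(apple = 300), g), 150)
  d <- c(bread = 100, cake = 200)
  expect_equal(solid_energy_density(d, foods),
               100 * (250 + 2 * 380) / 300)
  expect_warning(out <- solid_energy_density(c(water = 500, cola = 200), foods),
                 "undefined")
  expect_true(is.na(out))
})

test_that("variety counts distinct foods over the week", {
  foods <- fixture_foods()
  expect_equal(variety(fixture_week(c(bread = 100)), foods), 1)
  ten <- paste0("f", 1:10)
  ev <- data.frame(individual_id = "P1", day = rep(1:5, 2), moment = "lunch",
                   food_id = ten, amount_g = 10, stringsAsFactors = FALSE)
  expect_equal(variety(ev, foods), 10)
  # repeats: matches independent set-cardinality computation
  set.seed(7)
  ids <- sample(foods$food_id[!foods$is_alcoholic], 40, replace = TRUE)
  ev2 <- data.frame(individual_id = "P1", day = sample(1:7, 40, TRUE),
                    moment = "dinner", food_id = ids, amount_g = 5,
                    stringsAsFactors = FALSE)
  expect_equal(variety(ev2, foods), length(unique(ids)))
  # alcoholic drinks do not count; water counts unless excluded
  ev3 <- rbind(fixture_week(c(bread = 1, water = 1)),
               fixture_events(list(1, "dinner", "wine", 100)))
  expect_equal(variety(ev3, foods), 2)
  expect_equal(variety(ev3, foods, include_water = FALSE), 1)
})

test_that("MAR caps each nutrient at 100% and averages over 23", {
  refs <- load_nutrient_references()
  ids <- refs$id[refs$mar]
  expect_length(ids, 23)
  high <- stats::setNames(refs$rni[refs$mar] * 2, ids)
  expect_equal(mar(high, refs), 100)
  half <- stats::setNames(refs$rni[refs$mar] / 2, ids)
  expect_equal(mar(half, refs), 50)
  one_zero <- high; one_zero[1] <- 0
  expect_equal(mar(one_zero, refs), 2200 / 23)
  expect_error(mar(high[-1], refs), ids[1])
})

test_that("MER counts only exceedances above the maxima", {
  refs <- load_nutrient_references()
  expect_length(refs$id[refs$mer], 3)
  en <- 2000
  maxima <- c(sodium = 3150, sfa = 0.12 * en / 9, free_sugars = 0.10 * en / 4)
  below <- stats::setNames(maxima * 0.8, names(maxima))
  expect_equal(mer(below, en, refs), 0)
  sodium_double <- stats::setNames(c(2 * maxima[1], maxima[2], maxima[3]),
                                   names(maxima))
  expect_equal(mer(sodium_double, en, refs), 100 / 3)
  at_150 <- stats::setNames(maxima * 1.5, names(maxima))
  expect_equal(mer(at_150, en, refs), 50)
})

test_that("PANDiet probabilities follow the Gaussian usual-intake model", {
  refs <- load_nutrient_references()
  pd_ids <- refs$id[refs$pandiet]
  expect_length(pd_ids, 25)
  en <- 2000
  # construct 7-day series: far above every EAR, far below every maximum
  days <- matrix(0, 7, length(pd_ids), dimnames = list(NULL, pd_ids))
  for (j in seq_along(pd_ids)) {
    r <- refs[refs$id == pd_ids[j], ]
    base <- if (r$role == "adequacy") r$ear * 20 else
      fsdiet:::moderation_reference(r, en) * 0.01
    days[, j] <- base * (1 + 0.01 * seq(-3, 3) / 3)
  }
  out <- pandiet(days, en, refs)
  expect_equal(out$pandiet, 100, tolerance = 1e-6)

  # a mean exactly at the EAR gives probability 0.5
  j <- which(pd_ids == "vit_c")
  r <- refs[refs$id == "vit_c", ]
  days[, j] <- r$ear + c(-3, -2, -1, 0, 1, 2, 3)
  out2 <- pandiet(days, en, refs)
  expect_equal(unname(out2$probabilities["vit_c"]), 0.5, tolerance = 1e-12)

  # two-nutrient toy vs. an independent numeric CDF (integration of the
  # normal density), at the model's combined variance
  mu <- 95; ear <- 85; cvr <- 0.15
  series <- mu + c(-9, -4, -1, 0, 1, 4, 9)
  s2w <- stats::var(series)
  sd_tot <- sqrt((cvr * ear)^2 + s2w / 7)
  p_num <- stats::integrate(function(z) stats::dnorm(z, mean = 0, sd = 1),
                            -Inf, (mean(series) - ear) / sd_tot,
                            rel.tol = 1e-12)$value
  days[, j] <- series
  out3 <- pandiet(days, en, refs)
  expect_equal(unname(out3$probabilities["vit_c"]), p_num, tolerance = 1e-9)
})

test_that("quality scores are invariant to reordering diary days and monotone", {
  foods <- fixture_foods()
  ev <- rbind(fixture_week(c(bread = 100, apple = 150, cheese = 30,
                             fish = 40))[-(1:2), ],
              fixture_events(list(1, "lunch", "cake", 60)),
              fixture_events(list(1, "dinner", "bread", 90)),
              fixture_events(list(2, "breakfast", "apple", 120)),
              fixture_events(list(2, "lunch", "fish", 50)))
  sc <- quality_scores(ev, foods)
  shuffled <- ev
  shuffled$day <- c(8 - ev$day)  # reverse the week
  sc2 <- quality_scores(shuffled, foods)
  for (col in c("sed", "variety", "mar", "mer", "pandiet"))
    expect_equal(sc[[col]], sc2[[col]], tolerance = 1e-12)

  # MAR rises, MER never falls, when an adequacy / moderated intake grows
  refs <- load_nutrient_references()
  ids <- refs$id[refs$mar]
  base <- stats::setNames(refs$rni[refs$mar] * 0.7, ids)
  bumped <- base; bumped["iron"] <- base[["iron"]] * 1.2
  expect_gt(mar(bumped, refs), mar(base, refs))
  en <- 2000
  m0 <- stats::setNames(c(4000, 40, 60), c("sodium", "sfa", "free_sugars"))
  m1 <- m0; m1["sodium"] <- 5000
  expect_gt(mer(m1, en), mer(m0, en))
})
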