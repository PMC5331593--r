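test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_individuals = 10, n_foods = 50)
  ft1 <- generate_food_table(cfg, seed = 5)
  ft2 <- generate_food_table(cfg, seed = 5)
  expect_identical(ft1, ft2)
  p1 <- generate_population(cfg, ft1, seed = 6)
  p2 <- generate_population(cfg, ft1, seed = 6)
  expect_identical(p1$events, p2$events)
  expect_identical(p1$individuals, p2$individuals)
  expect_false(identical(p1$events,
                         generate_population(cfg, ft1, seed = 7)$events))
})

test_that("generated food tables are valid and structured as configured", {
  cfg <- generator_config(n_foods = 60)
  ft <- generate_food_table(cfg, seed = 5)
  expect_equal(nrow(ft), 60)
  expect_true(all(table(ft$subcategory) >= 1))
  expect_length(unique(ft$subcategory), 33)
  # water is an energy-free drink; fruit juices carry all sugars as free
  expect_true(all(ft$is_energy_free_drink[ft$subcategory == "Water"]))
  ju <- ft$subcategory == "Fruit juices"
  expect_equal(ft$free_sugars[ju], ft$sugars[ju])
  expect_true(all(ft$free_sugars[ft$subcategory == "Fresh fruits"] == 0))
  # passes the composition-table validation (invariants)
  expect_silent(validate_food_table(ft, load_taxonomy()))
})

test_that("every diary validates and reproduces its drawn targets", {
  pop <- tiny_population()
  v <- validate_survey(pop$events, pop$individuals, pop$foods)
  expect_equal(nrow(v$individuals), nrow(pop$individuals))
  dv <- build_diet_vector(pop$events, pop$foods)
  ik <- compute_intakes(dv$diet, pop$foods)
  tr <- pop$truth[match(rownames(dv$diet), pop$truth$individual_id), ]
  share <- free_sugar_share(ik[, "free_sugars"], ik[, "energy"])
  expect_equal(unname(share), tr$fs_share_target, tolerance = 1e-9)
  expect_equal(unname(ik[, "energy"]), tr$energy_target, tolerance = 1e-9)
  # label consistency: classifier reproduces the generator's labels exactly
  lab <- classify_fs_group(ik[, "free_sugars"], ik[, "energy"])
  expect_equal(unname(lab), tr$group)
})

test_that("truncated-normal moment matching hits requested moments", {
  p <- truncnorm_match(6.3, 2.5, lower = 1, upper = 10)
  m <- fsdiet:::tnorm_moments(p["mu"], p["sigma"], 1, 10)
  expect_equal(unname(m[1]), 6.3, tolerance = 1e-3)
  expect_equal(unname(m[2]), 2.5, tolerance = 1e-3)
  p2 <- truncnorm_match(2123, 539, lower = 1200, upper = 4200)
  m2 <- fsdiet:::tnorm_moments(p2["mu"], p2["sigma"], 1200, 4200)
  expect_equal(unname(m2[1]), 2123, tolerance = 1)
  # an impossible request errors instead of silently drifting
  expect_error(truncnorm_match(5, 5, lower = 0, upper = Inf), "cannot match")
})

test_that("moment report flags tampered populations but not clean ones", {
  pop <- tiny_population()
  mr <- moment_report(pop)
  expect_equal(nrow(mr), 6)
  expect_true(all(c("target", "realized_mean", "se", "flag") %in% names(mr)))
  # doubling all amounts doubles energy: the energy moment must flag
  tampered <- pop
  tampered$events$amount_g <- tampered$events$amount_g * 2
  mr2 <- moment_report(tampered)
  expect_true(any(mr2$flag[mr2$variable == "energy"]))
  # a single-individual group reports NA dispersion
  one <- pop
  keep <- pop$truth$individual_id[c(which(pop$truth$group == "FS_EXCESS")[1],
                                    which(pop$truth$group == "FS_ACCEPTABLE")[1])]
  one$events <- one$events[one$events$individual_id %in% keep, ]
  one$truth <- one$truth[one$truth$individual_id %in% keep, ]
  mr3 <- moment_report(one)
  expect_true(all(is.na(mr3$realized_sd)))
  expect_true(all(!mr3$flag))
})

test_that("a survey round-trips through the CSV writers", {
  pop <- tiny_population()
  d <- tempfile("survey")
  paths <- write_survey(pop, d)
  expect_true(all(file.exists(paths)))
  ft <- load_food_table(file.path(d, "foods.csv"))
  expect_equal(ft$free_sugars, pop$foods$free_sugars, tolerance = 1e-12)
  ev <- utils::read.csv(file.path(d, "events.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(ev), nrow(pop$events))
  unlink(d, recursive = TRUE)
})

test_that("realized group proportions recover the mixture weight", {
  # modest-n recovery check (the acceptance suite runs the full sizes)
  cfg <- generator_config(n_individuals = 400, n_foods = 70)
  pop <- generate_population(cfg, generate_food_table(cfg, seed = 21),
                             seed = 22)
  p_hat <- mean(pop$truth$group == "FS_EXCESS")
  se <- sqrt(0.41 * 0.59 / 400)
  expect_lt(abs(p_hat - 0.41), 3 * se)
})
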