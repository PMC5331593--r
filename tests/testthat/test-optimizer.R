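# helpers: a 2-food world with hand-checkable model structure
two_food_world <- function() {
  foods <- fixture_foods()[fixture_foods()$food_id %in% c("bread", "apple"), ]
  diets <- rbind(P1 = c(100, 200), P2 = c(150, 100))
  colnames(diets) <- foods$food_id
  list(foods = foods, diets = diets,
       limits = population_limits(diets, foods))
}

minimal_constraints <- function() {
  list(nutritional = data.frame(
    id = c("fiber_min", "sodium_max"),
    kind = c("nutrient_min", "nutrient_max"),
    nutrient = c("fiber", "sodium"),
    bound = c(0, 1e6), basis = "absolute_per_day",
    stringsAsFactors = FALSE),
    structural = list(total_weight_multiplier = 2,
                      total_cost_multiplier = 2,
                      acceptability_quantile = 0.95))
}

test_that("the LP matrix of a 2-food model matches hand construction", {
  w <- two_food_world()
  mod <- build_model(w$diets["P1", ], w$foods, w$limits,
                     minimal_constraints(), model_params())
  # variables: d+ then d- for (bread, apple); no non-repertoire foods
  expect_equal(length(mod$obj), 4)
  expect_equal(unname(mod$obj), c(1 / 100, 1 / 200, 2 / 100, 2 / 200))
  e <- w$foods$energy / 100
  expect_equal(unname(mod$A[mod$constraint_ids == "energy_equality", ]),
               c(e, -e))
  expect_equal(mod$rhs[mod$constraint_ids == "energy_equality"], 0)
  fib <- w$foods$fiber / 100
  expect_equal(unname(mod$A[mod$constraint_ids == "fiber_min", ]),
               c(fib, -fib))
  expect_equal(mod$dir[mod$constraint_ids == "fiber_min"], ">=")
  # d- bounded by the observed amounts
  expect_equal(unname(mod$ub[3:4]), c(100, 200))
})

test_that("a feasible observed diet is returned unchanged with objective 0", {
  w <- two_food_world()
  mod <- build_model(w$diets["P1", ], w$foods, w$limits,
                     minimal_constraints(), model_params())
  res <- optimize_diet(mod)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 0, tolerance = 1e-10)
  expect_equal(unname(res$diet), unname(w$diets["P1", ]), tolerance = 1e-8)
  expect_equal(unname(res$departures), c(0, 0), tolerance = 1e-8)
})

test_that("contradictory nutrient bounds make the model infeasible", {
  w <- two_food_world()
  cons <- minimal_constraints()
  cons$nutritional <- rbind(cons$nutritional, data.frame(
    id = "vit_c_min", kind = "nutrient_min", nutrient = "vit_c",
    bound = 1e6, basis = "absolute_per_day", stringsAsFactors = FALSE))
  mod <- build_model(w$diets["P1", ], w$foods, w$limits, cons, model_params())
  res <- optimize_diet(mod)
  expect_equal(res$status, "infeasible")
  expect_error(extract_duals(res), "optimal")
})

test_that("the conditional free-sugar rule switches on the observed share", {
  pop <- tiny_population()
  foods <- pop$foods
  dv <- build_diet_vector(pop$events, foods)
  lim <- population_limits(dv$diet, foods)
  cons <- load_constraints()
  ik <- compute_intakes(dv$diet, foods)
  shares <- free_sugar_share(ik[, "free_sugars"], ik[, "energy"])
  hi <- which.max(shares); lo <- which.min(shares)
  stopifnot(shares[hi] > 10, shares[lo] <= 10)
  mod_hi <- build_model(dv$diet[hi, ], foods, lim, cons)
  r <- which(mod_hi$constraint_ids == "free_sugars_max")
  obs_fs <- sum(dv$diet[hi, mod_hi$foods] * foods$free_sugars[
    match(mod_hi$foods, foods$food_id)] / 100)
  expect_equal(mod_hi$rhs[r] + obs_fs, 0.10 * mod_hi$energy / 4,
               tolerance = 1e-9)
  mod_lo <- build_model(dv$diet[lo, ], foods, lim, cons)
  r2 <- which(mod_lo$constraint_ids == "free_sugars_max")
  obs_fs2 <- sum(dv$diet[lo, mod_lo$foods] * foods$free_sugars[
    match(mod_lo$foods, foods$food_id)] / 100)
  expect_equal(mod_lo$rhs[r2] + obs_fs2, obs_fs2, tolerance = 1e-9)
})

test_that("diet-model duals are sensitivities of the optimum to the bounds", {
  pop <- tiny_population()
  dv <- build_diet_vector(pop$events, pop$foods)
  lim <- population_limits(dv$diet, pop$foods)
  mod <- build_model(dv$diet[1, ], pop$foods, lim, load_constraints())
  res <- optimize_diet(mod)
  skip_if(res$status != "optimal", "first individual infeasible")
  # the LP value function is convex and piecewise linear in each bound, so
  # the reported (basic) dual must lie between the one-sided slopes; at
  # non-degenerate rows the two slopes coincide with the dual
  for (row_id in c("sodium_max", "sfa_max", "free_sugars_max")) {
    j <- which(mod$constraint_ids == row_id)
    d <- 1e-4 * max(1, abs(mod$rhs[j]))
    up <- lp_solve(mod$obj, mod$A, mod$dir,
                   mod$rhs + d * (seq_along(mod$rhs) == j), ub = mod$ub)
    dn <- lp_solve(mod$obj, mod$A, mod$dir,
                   mod$rhs - d * (seq_along(mod$rhs) == j), ub = mod$ub)
    if (up$status != "optimal" || dn$status != "optimal") next
    slope_plus <- (up$objective - res$objective) / d
    slope_minus <- (res$objective - dn$objective) / d
    tol <- 1e-4 * max(1, abs(res$duals[row_id]))
    expect_gte(unname(res$duals[row_id]), slope_minus - tol)
    expect_lte(unname(res$duals[row_id]), slope_plus + tol)
  }
  # complementary slackness on every row, from the deviation-space solution
  xdev <- numeric(length(mod$obj))
  xdev[mod$v$dp] <- pmax(res$diet[mod$rep_idx] - mod$observed[mod$rep_idx], 0)
  xdev[mod$v$dm] <- pmax(mod$observed[mod$rep_idx] - res$diet[mod$rep_idx], 0)
  xdev[mod$v$q] <- res$diet[mod$non_idx]
  act <- as.vector(mod$A %*% xdev)
  slack <- abs(act - mod$rhs)
  loose <- mod$dir != "=" & slack > 1e-6 * pmax(1, abs(mod$rhs))
  expect_true(all(abs(res$duals[loose]) <= 1e-6))
})

test_that("raising the non-repertoire penalty never adds non-repertoire food", {
  pop <- tiny_population()
  dv <- build_diet_vector(pop$events, pop$foods)
  lim <- population_limits(dv$diet, pop$foods)
  cons <- load_constraints()
  grams <- c()
  for (p in c(1, 5, 25)) {
    mod <- build_model(dv$diet[2, ], pop$foods, lim, cons,
                       model_params(pi_nonrep = p))
    res <- optimize_diet(mod)
    skip_if(res$status != "optimal", "individual infeasible")
    grams <- c(grams, sum(res$diet[mod$non_idx]))
  }
  expect_true(all(diff(grams) <= 1e-6))
})

test_that("binding ranking orders constraints by share of non-null duals", {
  mk <- function(duals) structure(list(status = "optimal",
                                       duals = duals), class = "fsdiet_opt")
  res <- list(mk(c(energy_equality = -2, sodium_max = 0, b2_min = 0.5)),
              mk(c(energy_equality = 1, sodium_max = 0, b2_min = 0)),
              mk(c(energy_equality = 0.3, sodium_max = 0, b2_min = 0)))
  br <- rank_binding(res)
  expect_equal(br$constraint_id[1], "energy_equality")
  expect_equal(br$pct_binding[1], 100)
  expect_equal(br$pct_binding[br$constraint_id == "sodium_max"], 0)
  expect_equal(br$constraint_id[3], "sodium_max")  # ranked last
  expect_error(rank_binding(list()), "no optimal")
  infeas <- structure(list(status = "infeasible"), class = "fsdiet_opt")
  expect_equal(rank_binding(c(res, list(infeas)))$pct_binding[1], 100)
})

test_that("optimal diets satisfy iso-energy and the free-sugar direction", {
  pop <- tiny_population()
  pr <- run_pipeline(pop)
  expect_gte(pr$feasible_rate, 0.9)
  obs <- pr$optimization$observed; opt <- pr$optimization$optimized
  iko <- compute_intakes(obs, pop$foods)
  ikq <- compute_intakes(opt, pop$foods)
  expect_lt(max(abs(ikq[, "energy"] - iko[, "energy"]) / iko[, "energy"]),
            1e-8)
  grp <- classify_fs_group(iko[, "free_sugars"], iko[, "energy"])
  shq <- free_sugar_share(ikq[, "free_sugars"], ikq[, "energy"])
  expect_true(all(shq[grp == "FS_EXCESS"] <= 10 + 1e-6))
  expect_true(all(ikq[grp == "FS_ACCEPTABLE", "free_sugars"] <=
                  iko[grp == "FS_ACCEPTABLE", "free_sugars"] + 1e-6))
  expect_true(all(opt >= -1e-9))
})
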