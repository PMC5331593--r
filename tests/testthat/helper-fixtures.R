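# Shared fixtures: a small hand-written food table, diary builders, and an
# independent brute-force LP oracle (basic-solution enumeration).

# food table with hand-set contents; micronutrients default to a flat
# moderate density so validation and intake roll-ups have known values
fixture_foods <- function() {
  micros <- setdiff(fsdiet_nutrients(),
                    c("energy", "protein", "fat", "sfa", "carb", "starch",
                      "sugars", "free_sugars", "fiber", "cholesterol",
                      "sodium"))
  f <- data.frame(
    food_id = c("bread", "apple", "cola", "water", "cake", "cheese",
                "fish", "sugar", "wine"),
    name = c("baguette", "apple", "cola", "tap water", "plain cake",
             "emmental", "cod", "white sugar", "red wine"),
    subcategory = c("Refined starchy foods", "Fresh fruits",
                    "Sugar-sweetened beverages", "Water",
                    "Cakes and pastries", "Cheese", "Fish", "Table sugar",
                    "Diet beverages"),
    is_alcoholic = c(rep(FALSE, 8), TRUE),
    unit_cost = c(0.2, 0.25, 0.15, 0.02, 0.7, 1.2, 1.4, 0.15, 0.5),
    energy = c(250, 52, 42, 0, 380, 330, 100, 400, 70),
    protein = c(8, 0.3, 0, 0, 5, 22, 22, 0, 0),
    fat = c(1.5, 0.2, 0, 0, 15, 26, 1, 0, 0),
    sfa = c(0.3, 0.05, 0, 0, 7, 16, 0.2, 0, 0),
    carb = c(50, 12, 10.5, 0, 52, 2, 0, 100, 1),
    starch = c(48, 1, 0, 0, 24, 1, 0, 0, 0),
    sugars = c(2, 11, 10.5, 0, 28, 1, 0, 100, 1),
    free_sugars = c(0.3, 0, 10.5, 0, 24, 0, 0, 100, 1),
    fiber = c(3, 2.4, 0, 0, 1.5, 0, 0, 0, 0),
    cholesterol = c(0, 0, 0, 0, 60, 100, 50, 0, 0),
    sodium = c(500, 2, 8, 1, 300, 750, 80, 0, 5),
    stringsAsFactors = FALSE)
  tax <- load_taxonomy()
  f$category <- tax$category[match(f$subcategory, tax$subcategory)]
  f$is_beverage <- tax$is_beverage[match(f$subcategory, tax$subcategory)]
  for (m in micros) f[[m]] <- c(1, 2, 0, 0, 0.5, 3, 4, 0, 0)
  f$is_energy_free_drink <- f$is_beverage & f$energy < 4
  validate_food_table(f, tax)
  f
}

# one-individual diary: each row of `spec` is (day, moment, food_id, grams)
fixture_events <- function(spec, id = "P1") {
  data.frame(individual_id = id,
             day = as.integer(spec[[1]]), moment = spec[[2]],
             food_id = spec[[3]], amount_g = as.numeric(spec[[4]]),
             stringsAsFactors = FALSE)
}

# full 7-day one-person diary eating `grams` of each food every day at the
# given moment
fixture_week <- function(foods_g, moment = "lunch", id = "P1") {
  data.frame(individual_id = id,
             day = rep(1:7, each = length(foods_g)),
             moment = moment,
             food_id = rep(names(foods_g), 7),
             amount_g = rep(unname(foods_g), 7),
             stringsAsFactors = FALSE)
}

# Brute-force LP oracle: enumerates all basic solutions of
# {A x dir rhs, 0 <= x <= ub} by activating n constraints at a time and
# returns the optimal objective (NULL if infeasible). Independent of the
# simplex implementation.
lp_vertex_oracle <- function(obj, A, dir, rhs, ub = rep(Inf, length(obj)),
                             maximize = FALSE) {
  n <- length(obj)
  rows <- rbind(A, diag(n), diag(n))
  rhss <- c(rhs, rep(0, n), ub)
  feas <- function(x) {
    all(is.finite(x)) && all(x >= -1e-7) && all(x <= ub + 1e-7) &&
      all(ifelse(dir == "<=", A %*% x - rhs <= 1e-7,
          ifelse(dir == ">=", rhs - A %*% x <= 1e-7,
                 abs(A %*% x - rhs) <= 1e-7)))
  }
  idx <- which(is.finite(rhss))
  best <- NULL
  for (k in seq_len(ncol(combs <- utils::combn(idx, n)))) {
    M <- rows[combs[, k], , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, rhss[combs[, k]]), error = function(e) NULL)
    if (!is.null(x) && feas(x)) {
      z <- sum(obj * x)
      if (is.null(best) || (maximize && z > best) || (!maximize && z < best))
        best <- z
    }
  }
  best
}

# random diet-model-like LP used by oracle-equivalence property tests
random_small_lp <- function(n_max = 6, m_max = 8) {
  n <- sample(2:n_max, 1); m <- sample(2:m_max, 1)
  A <- matrix(stats::rnorm(m * n), m)
  dir <- sample(c("<=", ">=", "="), m, TRUE, prob = c(0.6, 0.3, 0.1))
  rhs <- stats::rnorm(m, 1, 1)
  ub <- ifelse(stats::runif(n) < 0.5, stats::runif(n, 0.5, 3), Inf)
  list(obj = stats::rnorm(n), A = A, dir = dir, rhs = rhs, ub = ub)
}

# small synthetic survey shared across test files (generated once per run)
tiny_population <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      cfg <- generator_config(n_individuals = 30, n_foods = 70)
      pop <<- generate_population(cfg, generate_food_table(cfg, seed = 11),
                                  seed = 12)
    }
    pop
  }
})
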