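# Food composition table: taxonomy, free-sugar annotation, I/O.
#
# Free sugars follow the WHO definition: mono- and disaccharides added by the
# manufacturer, cook or consumer, plus sugars naturally present in honey,
# syrups, fruit juices and concentrates. Their content per 100 g is derived
# either directly (sugars == free sugars for beverages, honey, syrups), from
# an average recipe via converting factors, or from an explicit per-food
# expert value.

#' Nutrient identifiers handled by the package
#'
#' Order matters only for display. Units: energy kcal; protein, fat, sfa,
#' carb, starch, sugars, free_sugars, fiber in g; cholesterol mg; sodium mg;
#' vitamins/minerals in the units of the nutrient reference file.
#' @export
fsdiet_nutrients <- function() {
  c("energy", "protein", "fat", "sfa", "carb", "starch", "sugars",
    "free_sugars", "fiber", "cholesterol", "sodium",
    "vit_a", "vit_d", "vit_e", "vit_k", "vit_c",
    "b1", "b2", "b3", "b5", "b6", "b9", "b12",
    "calcium", "magnesium", "potassium", "iron", "zinc", "copper",
    "iodine", "selenium", "phosphorus", "manganese")
}

#' Load the food taxonomy
#'
#' The taxonomy is 9 food categories over 30 base sub-categories; the fruits,
#' milk and yogurts sub-categories are further split (fresh/processed,
#' plain/sweet), giving 33 leaf sub-categories. Foods are labelled at the
#' leaf level; the base level is retained for category accounting.
#'
#' @param path YAML file; default is the taxonomy shipped with the package.
#' @return data.frame with columns subcategory, category, base_subcategory,
#'   is_beverage (typical consumption form of the leaf).
#' @export
load_taxonomy <- function(path = fsdiet_file("taxonomy.yaml")) {
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(raw$categories, function(cat) {
    do.call(rbind, lapply(cat$subcategories, function(sc) {
      data.frame(subcategory = sc$name, category = cat$name,
                 base_subcategory = if (is.null(sc$base)) sc$name else sc$base,
                 is_beverage = isTRUE(sc$beverage),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (anyDuplicated(rows$subcategory))
    stop("taxonomy: duplicated sub-category names")
  rows
}

#' Path to a file shipped in the package's extdata
#' @param file file name under inst/extdata.
#' @export
fsdiet_file <- function(file) {
  p <- system.file("extdata", file, package = "fsdiet")
  if (!nzchar(p)) {
    # during development (package not installed) fall back to source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("cannot find packaged file: ", file)
  p
}

#' Load the sugar converting-factor table
#'
#' Maps sugar-bearing recipe ingredients to the fraction of their weight
#' counted as equivalent (free) sugar: 1.0 for white sugar, 0.8 for honey;
#' syrup and concentrate factors are configurable defaults. Ingredients
#' absent from the table count 0.
#'
#' @param path YAML file; default shipped table.
#' @return named numeric vector, ingredient_id -> fraction in [0, 1].
#' @export
load_sugar_conversion <- function(path = fsdiet_file("sugar_conversion.yaml")) {
  conv <- unlist(yaml::read_yaml(path)$converting_factors)
  if (any(conv < 0 | conv > 1)) stop("converting factors must lie in [0, 1]")
  conv
}

#' Estimate free sugar content of a food from its recipe
#'
#' Free sugars per 100 g are the summed recipe weights of assimilated sugar
#' ingredients scaled by their converting factors: 100 g of a recipe that is
#' 10% honey carries 100 x 0.10 x 0.8 = 8 g free sugars.
#'
#' @param recipe data.frame with columns ingredient_id, weight_fraction
#'   (fractions of the finished food's weight; need not sum to 1, water loss
#'   or gain during preparation is allowed).
#' @param conv named converting-factor vector, see [load_sugar_conversion()].
#' @return free sugars, g per 100 g of food.
#' @export
estimate_free_sugars <- function(recipe, conv) {
  stopifnot(is.data.frame(recipe),
            all(c("ingredient_id", "weight_fraction") %in% names(recipe)))
  if (any(recipe$weight_fraction < 0))
    stop("recipe weight fractions must be non-negative")
  f <- conv[recipe$ingredient_id]
  f[is.na(f)] <- 0
  val <- 100 * sum(recipe$weight_fraction * f)
  min(val, 100)
}

#' Set the free sugar content of one food according to its rule class
#'
#' Rule classes mirror how a composition table is annotated in practice:
#' \describe{
#'   \item{sugars_equal_free}{free sugars := total sugars (beverages, honey,
#'     syrups).}
#'   \item{recipe}{free sugars from [estimate_free_sugars()] on the food's
#'     recipe.}
#'   \item{expert_zero}{free sugars := 0 (mono-ingredient raw foods).}
#'   \item{expert_value}{free sugars := an explicit per-food override.}
#' }
#' The invariant free_sugars <= sugars is enforced by clipping with a warning.
#'
#' @param food one-row data.frame (or list) with at least \code{sugars}; for
#'   expert_value also \code{free_sugar_override}.
#' @param rule_class one of the four classes above.
#' @param recipe recipe data.frame (required for class "recipe").
#' @param conv converting-factor vector (required for class "recipe").
#' @return the food with \code{free_sugars} set.
#' @export
apply_whole_food_rule <- function(food, rule_class, recipe = NULL, conv = NULL) {
  rule_class <- match.arg(rule_class,
    c("sugars_equal_free", "recipe", "expert_zero", "expert_value"))
  fs <- switch(rule_class,
    sugars_equal_free = food$sugars,
    expert_zero = 0,
    expert_value = {
      if (is.null(food$free_sugar_override) || is.na(food$free_sugar_override))
        stop("expert_value rule needs a free_sugar_override for food ",
             food$food_id)
      food$free_sugar_override
    },
    recipe = {
      if (is.null(recipe)) stop("no recipe on file for food ", food$food_id)
      estimate_free_sugars(recipe, conv)
    })
  if (fs > food$sugars + 1e-9) {
    warning("free sugars (", signif(fs, 4), ") exceed total sugars (",
            signif(food$sugars, 4), ") for food ", food$food_id,
            "; clipped", call. = FALSE)
    fs <- food$sugars
  }
  food$free_sugars <- max(fs, 0)
  food
}

validate_food_table <- function(foods, taxonomy, eps = 0.02) {
  req <- c("food_id", "name", "category", "subcategory", "is_beverage",
           "is_alcoholic", "unit_cost", fsdiet_nutrients())
  miss <- setdiff(req, names(foods))
  if (length(miss))
    stop("food table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(foods$food_id))
    stop("duplicated food_id in food table")
  bad <- !(foods$subcategory %in% taxonomy$subcategory)
  if (any(bad))
    stop("unknown sub-category for food(s): ",
         paste(foods$food_id[bad], collapse = ", "))
  expect_cat <- taxonomy$category[match(foods$subcategory, taxonomy$subcategory)]
  mism <- foods$category != expect_cat
  if (any(mism))
    stop("category/sub-category mismatch for food(s): ",
         paste(foods$food_id[mism], collapse = ", "))
  if (any(foods$free_sugars < -1e-9 | foods$free_sugars > foods$sugars + 1e-6))
    stop("invariant violated (0 <= free_sugars <= sugars) for food(s): ",
         paste(foods$food_id[foods$free_sugars < -1e-9 |
                             foods$free_sugars > foods$sugars + 1e-6],
               collapse = ", "))
  over <- foods$starch + foods$sugars > foods$carb * (1 + eps) + 1e-6
  if (any(over))
    stop("starch + sugars exceed carbohydrate for food(s): ",
         paste(foods$food_id[over], collapse = ", "))
  invisible(foods)
}

#' Load a food composition table from CSV
#'
#' One row per food, per-100 g contents. A \code{free_sugar_rule} column
#' (sugars_equal_free / recipe / expert_zero / expert_value) triggers
#' annotation of \code{free_sugars} where that column is absent or NA;
#' tables that already carry \code{free_sugars} are validated as-is.
#' The energy-free-drink flag (beverage under 4 kcal/100 mL, densities
#' taken as 1 g/mL) is always recomputed.
#'
#' @param path CSV file.
#' @param taxonomy taxonomy data.frame from [load_taxonomy()].
#' @param recipes optional recipe data.frame (food_id, ingredient_id,
#'   weight_fraction) for rule class "recipe".
#' @param conv converting factors; default shipped table.
#' @return validated food table (data.frame) with logical flags and
#'   \code{free_sugars} filled.
#' @export
load_food_table <- function(path, taxonomy = load_taxonomy(), recipes = NULL,
                            conv = load_sugar_conversion()) {
  foods <- utils::read.csv(path, stringsAsFactors = FALSE)
  foods$is_beverage <- as.logical(foods$is_beverage)
  foods$is_alcoholic <- as.logical(foods$is_alcoholic)
  if (!"free_sugars" %in% names(foods)) foods$free_sugars <- NA_real_
  need <- which(is.na(foods$free_sugars))
  if (length(need)) {
    if (!"free_sugar_rule" %in% names(foods))
      stop("free_sugars missing and no free_sugar_rule column to derive them")
    for (i in need) {
      rec <- if (!is.null(recipes))
        recipes[recipes$food_id == foods$food_id[i], , drop = FALSE]
      if (!is.null(rec) && nrow(rec) == 0) rec <- NULL
      foods[i, ] <- apply_whole_food_rule(foods[i, , drop = FALSE],
                                          foods$free_sugar_rule[i],
                                          recipe = rec, conv = conv)
    }
  }
  foods$is_energy_free_drink <- foods$is_beverage & foods$energy < 4
  validate_food_table(foods, taxonomy)
  foods
}

#' Write a food table to CSV (round-trips with [load_food_table()])
#' @param foods validated food table.
#' @param path output CSV path.
#' @export
write_food_table <- function(foods, path) {
  utils::write.csv(foods, path, row.names = FALSE)
  invisible(path)
}
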