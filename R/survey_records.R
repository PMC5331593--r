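# 7-day diet diaries: validation, diet vectors, nutrient intakes,
# under-reporter screening and free-sugar group classification.

#' Diary consumption moments
#'
#' Three main meals and three between-meal snacking occasions.
#' @export
fsdiet_moments <- function() {
  c("breakfast", "lunch", "dinner",
    "morning_snack", "afternoon_snack", "evening_snack")
}

snack_moments <- function() c("morning_snack", "afternoon_snack", "evening_snack")

#' Validate diary events and individual records
#'
#' Enforces the record-level contract: amounts non-negative, days in 1..7,
#' known moments, every food resolvable in the composition table, and every
#' retained individual present on all 7 distinct diary days.
#'
#' @param events data.frame: individual_id, day, moment, food_id, amount_g.
#' @param individuals data.frame: individual_id, age, gender, weight, height,
#'   physical_activity, survey_weight.
#' @param foods validated food table.
#' @param age_bounds retained age range (years).
#' @return list(events, individuals) restricted to valid records; individuals
#'   gains an \code{n_days} column. Structural violations error; individuals
#'   failing the 7-day or age rule are dropped with a message.
#' @export
validate_survey <- function(events, individuals, foods, age_bounds = c(20, 75)) {
  stopifnot(all(c("individual_id", "day", "moment", "food_id", "amount_g")
                %in% names(events)),
            all(c("individual_id", "survey_weight") %in% names(individuals)))
  if (any(events$amount_g < 0)) stop("negative diary amounts")
  if (any(!(events$day %in% 1:7))) stop("diary days must lie in 1..7")
  if (any(!(events$moment %in% fsdiet_moments())))
    stop("unknown consumption moment(s): ",
         paste(unique(setdiff(events$moment, fsdiet_moments())), collapse = ", "))
  unknown <- setdiff(events$food_id, foods$food_id)
  if (length(unknown))
    stop("diary references unknown food(s): ", paste(unknown, collapse = ", "))
  if (any(individuals$survey_weight <= 0)) stop("survey weights must be positive")
  nd <- tapply(events$day, events$individual_id, function(d) length(unique(d)))
  individuals$n_days <- as.integer(nd[as.character(individuals$individual_id)])
  individuals$n_days[is.na(individuals$n_days)] <- 0L
  keep <- individuals$n_days == 7L
  if ("age" %in% names(individuals))
    keep <- keep & individuals$age >= age_bounds[1] & individuals$age <= age_bounds[2]
  if (any(!keep))
    message(sum(!keep), " individual(s) dropped (incomplete week or age out of range)")
  individuals <- individuals[keep, , drop = FALSE]
  events <- events[events$individual_id %in% individuals$individual_id, , drop = FALSE]
  list(events = events, individuals = individuals)
}

#' Build mean daily diet vectors from diary events
#'
#' Aggregates each individual's events to mean g/day per food over the 7
#' diary days. Alcoholic beverages are excluded (they are not optimizable
#' and nutrient recommendations apply to non-alcoholic intakes); their
#' grams are returned separately.
#'
#' @param events diary events (one or many individuals).
#' @param foods validated food table.
#' @return list: \code{diet} matrix (individuals x foods, g/day, columns in
#'   \code{foods$food_id} order), \code{alcohol_g} named vector of excluded
#'   mean daily alcoholic grams.
#' @export
build_diet_vector <- function(events, foods) {
  unknown <- setdiff(events$food_id, foods$food_id)
  if (length(unknown))
    stop("events reference unknown food(s): ", paste(unknown, collapse = ", "))
  ids <- unique(events$individual_id)
  alc <- foods$food_id[foods$is_alcoholic]
  ev_alc <- events[events$food_id %in% alc, , drop = FALSE]
  ev <- events[!(events$food_id %in% alc), , drop = FALSE]
  diet <- matrix(0, length(ids), nrow(foods),
                 dimnames = list(as.character(ids), foods$food_id))
  if (nrow(ev)) {
    agg <- rowsum(ev$amount_g,
                  group = paste(ev$individual_id, ev$food_id, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    diet[cbind(vapply(key, `[`, "", 1L), vapply(key, `[`, "", 2L))] <- agg[, 1] / 7
  }
  alcohol_g <- stats::setNames(rep(0, length(ids)), as.character(ids))
  if (nrow(ev_alc)) {
    a <- rowsum(ev_alc$amount_g, group = as.character(ev_alc$individual_id)) / 7
    alcohol_g[rownames(a)] <- a[, 1]
  }
  list(diet = diet, alcohol_g = alcohol_g)
}

#' Nutrient intakes of a diet vector
#'
#' Linear roll-up of per-100 g contents: intake_n = sum_f amount_f x
#' content_fn / 100. Adds the derived quantity non_free_sugars =
#' sugars - free_sugars.
#'
#' @param diet numeric vector (one diet, foods in table order or named by
#'   food_id) or an individuals x foods matrix.
#' @param foods validated food table.
#' @return named vector of mean daily intakes, or a matrix with one row per
#'   individual.
#' @export
compute_intakes <- function(diet, foods) {
  N <- as.matrix(foods[, fsdiet_nutrients()])
  if (is.matrix(diet)) {
    out <- diet[, foods$food_id, drop = FALSE] %*% N / 100
  } else {
    if (!is.null(names(diet))) {
      v <- stats::setNames(rep(0, nrow(foods)), foods$food_id)
      v[names(diet)] <- diet
      diet <- v
    }
    out <- drop(diet %*% N) / 100
  }
  if (is.matrix(out)) {
    cbind(out, non_free_sugars = out[, "sugars"] - out[, "free_sugars"])
  } else {
    c(out, non_free_sugars = unname(out["sugars"] - out["free_sugars"]))
  }
}

#' Per-moment energy and free-sugar sub-totals
#'
#' Splits mean daily energy and free sugars into main-meal and snacking
#' components from the raw events (before any aggregation), so that
#' meals + snacking always reproduces the daily total exactly.
#'
#' @param events diary events.
#' @param foods validated food table.
#' @return data.frame per individual: energy_meals, energy_snacks,
#'   fs_meals, fs_snacks (kcal/day and g/day). Alcoholic drinks excluded.
#' @export
moment_subtotals <- function(events, foods) {
  ev <- events[!(events$food_id %in% foods$food_id[foods$is_alcoholic]), ,
               drop = FALSE]
  idx <- match(ev$food_id, foods$food_id)
  e <- ev$amount_g * foods$energy[idx] / 100
  fs <- ev$amount_g * foods$free_sugars[idx] / 100
  snack <- ev$moment %in% snack_moments()
  ids <- unique(as.character(ev$individual_id))
  z <- function(x, sel) {
    out <- stats::setNames(rep(0, length(ids)), ids)
    if (any(sel)) {
      a <- rowsum(x[sel], group = as.character(ev$individual_id[sel]))
      out[rownames(a)] <- a[, 1]
    }
    out / 7
  }
  data.frame(individual_id = ids,
             energy_meals = z(e, !snack), energy_snacks = z(e, snack),
             fs_meals = z(fs, !snack), fs_snacks = z(fs, snack),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Goldberg screen for energy under-reporting
#'
#' Compares reported energy intake with predicted basal metabolic rate:
#' the ratio EI/BMR is tested against the one-sided Goldberg lower cut-off
#' \deqn{PAL \times \exp(-sd_{min} S / 100), \quad
#'       S = \sqrt{CV^2_{wEI}/d + CV^2_{wB} + CV^2_{tP}}}
#' with d diary days. BMR comes from Schofield-type age/gender equations
#' given in the parameter list (weight in kg; a height coefficient slot is
#' provided for weight-height variants, zero in the defaults).
#'
#' @param individuals data.frame with age, gender ("male"/"female"), weight,
#'   height, physical_activity ("low"/"moderate"/"high").
#' @param reported_energy kcal/day, same order as \code{individuals}.
#' @param params see [goldberg_params()].
#' @return character vector: "plausible", "under_reporter", or
#'   "unscreenable" when anthropometrics are missing.
#' @export
goldberg_screen <- function(individuals, reported_energy,
                            params = goldberg_params()) {
  stopifnot(nrow(individuals) == length(reported_energy))
  bmr <- schofield_bmr(individuals$age, individuals$gender,
                       individuals$weight, individuals$height, params)
  pal <- unname(params$pal_by_activity[individuals$physical_activity])
  s <- sqrt(params$cv_wei^2 / params$days + params$cv_wb^2 + params$cv_tp^2)
  cutoff <- pal * exp(-params$sd_min * s / 100)
  out <- ifelse(reported_energy / bmr < cutoff, "under_reporter", "plausible")
  out[is.na(bmr) | is.na(pal)] <- "unscreenable"
  out
}

#' Default Goldberg screening parameters
#'
#' Within-subject CV of energy intake 23%, CV of BMR estimation 8.5%, CV of
#' PAL 15%, 7 diary days, 2-SD one-sided cut-off; PAL 1.45/1.6/1.75 for
#' low/moderate/high physical activity; Schofield weight-based BMR
#' coefficients (kcal/day).
#' @export
goldberg_params <- function() {
  list(cv_wei = 23, cv_wb = 8.5, cv_tp = 15, days = 7, sd_min = 2,
       pal_by_activity = c(low = 1.45, moderate = 1.6, high = 1.75),
       bmr_equations = data.frame(
         gender = rep(c("male", "female"), each = 3),
         age_min = rep(c(18, 30, 60), 2),
         age_max = rep(c(30, 60, 120), 2),
         coef_weight = c(15.057, 11.472, 11.711, 14.818, 8.126, 9.082),
         coef_height = 0,
         intercept = c(692.2, 873.1, 587.7, 486.6, 845.6, 658.5),
         stringsAsFactors = FALSE))
}

schofield_bmr <- function(age, gender, weight, height, params = goldberg_params()) {
  eq <- params$bmr_equations
  out <- rep(NA_real_, length(age))
  for (i in seq_len(nrow(eq))) {
    sel <- !is.na(age) & !is.na(weight) & !is.na(height) &
      gender == eq$gender[i] & age >= eq$age_min[i] & age < eq$age_max[i]
    out[sel] <- eq$coef_weight[i] * weight[sel] +
      eq$coef_height[i] * height[sel] + eq$intercept[i]
  }
  out
}

#' Free-sugar energy share of a diet
#'
#' @param free_sugars_g g/day of free sugars.
#' @param energy_kcal kcal/day (non-alcoholic).
#' @param kcal_per_g energy density of sugars (Atwater, 4 kcal/g).
#' @return percent of energy from free sugars.
#' @export
free_sugar_share <- function(free_sugars_g, energy_kcal, kcal_per_g = 4) {
  if (any(energy_kcal <= 0)) stop("energy must be positive to compute a share")
  100 * kcal_per_g * free_sugars_g / energy_kcal
}

#' Classify individuals against the WHO free-sugar threshold
#'
#' Individuals whose observed free-sugar energy share exceeds 10% form the
#' FS-EXCESS group; a share lower than or equal to 10% is FS-ACCEPTABLE
#' (the boundary itself is acceptable).
#'
#' @inheritParams free_sugar_share
#' @param threshold percent-of-energy boundary (default 10).
#' @return character vector: "FS_ACCEPTABLE" or "FS_EXCESS".
#' @export
classify_fs_group <- function(free_sugars_g, energy_kcal, threshold = 10,
                              kcal_per_g = 4) {
  share <- free_sugar_share(free_sugars_g, energy_kcal, kcal_per_g)
  ifelse(share > threshold, "FS_EXCESS", "FS_ACCEPTABLE")
}
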