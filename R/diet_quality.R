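# Diet quality indicators: solid energy density, variety, MAR, MER, PANDiet.

#' Load nutrient reference values
#'
#' @param path YAML file; default is the reconstruction of French adult
#'   reference values shipped with the package.
#' @return data.frame with one row per nutrient: id, role, rni, ear, cv,
#'   max_value, basis, unit and membership flags (mar, mer, pandiet).
#' @export
load_nutrient_references <- function(path = fsdiet_file("nutrient_references.yaml")) {
  raw <- yaml::read_yaml(path)$nutrients
  take <- function(x, field, default = NA)
    if (is.null(x[[field]])) default else x[[field]]
  refs <- do.call(rbind, lapply(raw, function(x) {
    data.frame(id = x$id, role = x$role,
               rni = as.numeric(take(x, "rni")),
               ear = as.numeric(take(x, "ear")),
               cv = as.numeric(take(x, "cv")),
               max_value = as.numeric(take(x, "max_value")),
               basis = as.character(take(x, "basis", "absolute")),
               unit = x$unit,
               mar = isTRUE(x$mar), mer = isTRUE(x$mer),
               pandiet = isTRUE(x$pandiet),
               stringsAsFactors = FALSE)
  }))
  bad_adeq <- refs$role == "adequacy" & (is.na(refs$rni) | is.na(refs$ear))
  bad_mod <- refs$role == "moderation" & is.na(refs$max_value)
  if (any(bad_adeq | bad_mod))
    stop("incomplete nutrient reference(s): ",
         paste(refs$id[bad_adeq | bad_mod], collapse = ", "))
  refs
}

#' Solid energy density of a diet
#'
#' Energy provided by solid foods divided by their weight, in kcal/100 g.
#' Solid means not typically consumed as a beverage: soups count as solid;
#' water, milk, juices and soft drinks are excluded.
#'
#' @param diet diet vector (g/day), named by food_id or in table order.
#' @param foods validated food table.
#' @return kcal/100 g, or NA (with a warning) for an all-beverage diet.
#' @export
solid_energy_density <- function(diet, foods) {
  if (!is.null(names(diet))) {
    v <- stats::setNames(rep(0, nrow(foods)), foods$food_id)
    v[names(diet)] <- diet
    diet <- v
  }
  solid <- !foods$is_beverage
  grams <- sum(diet[solid])
  if (grams <= 0) {
    warning("no solid foods in diet; solid energy density undefined")
    return(NA_real_)
  }
  100 * sum(diet[solid] * foods$energy[solid] / 100) / grams
}

#' Food variety over the diary week
#'
#' Number of different foods declared as consumed during the 7 days.
#' Beverages count; water counts unless excluded; alcoholic beverages do
#' not (they sit outside the food analyses).
#'
#' @param events one individual's diary events.
#' @param foods validated food table.
#' @param include_water count drinking water as a food (default TRUE).
#' @return integer count.
#' @export
variety <- function(events, foods, include_water = TRUE) {
  drop_ids <- foods$food_id[foods$is_alcoholic]
  if (!include_water)
    drop_ids <- c(drop_ids, foods$food_id[foods$subcategory == "Water"])
  length(unique(setdiff(events$food_id, drop_ids)))
}

#' Mean adequacy ratio (MAR)
#'
#' Mean over the 23 key nutrients of the percentage of the recommended
#' intake reached over the week, each percentage capped at 100.
#'
#' @param intakes named vector of mean daily intakes (from
#'   [compute_intakes()]).
#' @param refs nutrient references; rows with \code{mar = TRUE} are used.
#' @return MAR in percent, in [0, 100].
#' @export
mar <- function(intakes, refs = load_nutrient_references()) {
  r <- refs[refs$mar, ]
  missing <- setdiff(r$id, names(intakes))
  if (length(missing))
    stop("intakes are missing MAR nutrient(s): ", paste(missing, collapse = ", "))
  mean(pmin(100, 100 * intakes[r$id] / r$rni))
}

#' Mean excess ratio (MER)
#'
#' Mean over sodium, saturated fatty acids and sugars of the percentage
#' points by which the weekly mean intake exceeds its maximum recommended
#' value; nutrients below their maximum contribute 0, so MER >= 0 and 0
#' means no excess. The sugars term uses free sugars against the 10%-energy
#' reference by default. Percent-energy maxima are converted to g/day with
#' the individual's energy intake (9 kcal/g for fats, 4 kcal/g otherwise).
#'
#' @param intakes named vector of mean daily intakes.
#' @param energy_kcal mean daily (non-alcoholic) energy, used for
#'   percent-energy references.
#' @param refs nutrient references; rows with \code{mer = TRUE} are used.
#' @return MER in percent, >= 0.
#' @export
mer <- function(intakes, energy_kcal, refs = load_nutrient_references()) {
  r <- refs[r_idx <- refs$mer, ]
  maxima <- moderation_reference(r, energy_kcal)
  if (any(maxima <= 0)) stop("non-positive moderation maximum in references")
  missing <- setdiff(r$id, names(intakes))
  if (length(missing))
    stop("intakes are missing MER nutrient(s): ", paste(missing, collapse = ", "))
  mean(pmax(0, 100 * intakes[r$id] / maxima - 100))
}

kcal_per_g <- function(nutrient) {
  ifelse(nutrient %in% c("fat", "sfa"), 9,
  ifelse(nutrient %in% c("protein", "carb", "sugars", "free_sugars"), 4,
         NA_real_))
}

moderation_reference <- function(refs, energy_kcal) {
  ifelse(refs$basis == "percent_energy",
         refs$max_value / 100 * energy_kcal / kcal_per_g(refs$id),
         refs$max_value)
}

#' PANDiet diet-quality score
#'
#' Probability-based score over 25 nutrients: the adequacy sub-score
#' averages, over adequacy nutrients, the probability that usual intake
#' meets the average requirement; the moderation sub-score averages the
#' probability that usual intake stays below the reference maximum
#' (sodium, saturated fatty acids, free sugars). Probabilities come from a
#' Gaussian model,
#' \deqn{P = \Phi\left((\bar{x} - EAR) / \sqrt{(cv \cdot EAR)^2 + s^2_w/d}\right)}
#' with \eqn{s^2_w} the within-person day-to-day variance estimated from
#' the d = 7 diary days (and the mirrored expression for moderation).
#' PANDiet = 100 x (adequacy + moderation) / 2.
#'
#' @param daily_intakes matrix of daily intakes, days x nutrients (at least
#'   2 days), columns named by nutrient id.
#' @param energy_kcal mean daily energy (for percent-energy references).
#' @param refs nutrient references; rows with \code{pandiet = TRUE} are used.
#' @return list: pandiet (0-100), adequacy, moderation sub-scores (0-1),
#'   and per-nutrient probabilities.
#' @export
pandiet <- function(daily_intakes, energy_kcal,
                    refs = load_nutrient_references()) {
  stopifnot(is.matrix(daily_intakes), nrow(daily_intakes) >= 2)
  r <- refs[refs$pandiet, ]
  missing <- setdiff(r$id, colnames(daily_intakes))
  if (length(missing))
    stop("daily intakes missing PANDiet nutrient(s): ",
         paste(missing, collapse = ", "))
  d <- nrow(daily_intakes)
  xbar <- colMeans(daily_intakes[, r$id, drop = FALSE])
  s2w <- apply(daily_intakes[, r$id, drop = FALSE], 2, stats::var)
  gauss_p <- function(mean_minus_thr, sd) {
    ifelse(sd > 0, stats::pnorm(mean_minus_thr / sd),
           ifelse(mean_minus_thr == 0, 0.5, as.numeric(mean_minus_thr > 0)))
  }
  adeq <- r$role == "adequacy"
  p <- numeric(nrow(r))
  names(p) <- r$id
  if (any(adeq)) {
    thr <- r$ear[adeq]
    sd_tot <- sqrt((r$cv[adeq] * thr)^2 + s2w[adeq] / d)
    p[adeq] <- gauss_p(xbar[adeq] - thr, sd_tot)
  }
  if (any(!adeq)) {
    thr <- moderation_reference(r[!adeq, ], energy_kcal)
    sd_tot <- sqrt((r$cv[!adeq] * thr)^2 + s2w[!adeq] / d)
    p[!adeq] <- gauss_p(thr - xbar[!adeq], sd_tot)
  }
  adequacy <- mean(p[adeq])
  moderation <- mean(p[!adeq])
  list(pandiet = 100 * (adequacy + moderation) / 2,
       adequacy = adequacy, moderation = moderation, probabilities = p)
}

#' All five quality indicators for every individual in a survey
#'
#' Convenience roll-up across a population: SED, variety, MAR, MER and
#' PANDiet per individual, plus energy, free sugars and group label.
#'
#' @param events diary events for the population.
#' @param foods validated food table.
#' @param refs nutrient references.
#' @return data.frame, one row per individual.
#' @export
quality_scores <- function(events, foods, refs = load_nutrient_references()) {
  dv <- build_diet_vector(events, foods)
  intakes <- compute_intakes(dv$diet, foods)
  ids <- rownames(dv$diet)
  nut <- c(fsdiet_nutrients(), "non_free_sugars")
  daily <- daily_intake_array(events, foods)
  nonalc <- events[!(events$food_id %in% foods$food_id[foods$is_alcoholic]), ]
  var_count <- tapply(nonalc$food_id, as.character(nonalc$individual_id),
                      function(f) length(unique(f)))
  out <- lapply(seq_along(ids), function(i) {
    en <- intakes[i, "energy"]
    pd <- pandiet(daily[[ids[i]]], en, refs)
    data.frame(
      individual_id = ids[i],
      energy = en,
      free_sugars = intakes[i, "free_sugars"],
      fs_share = free_sugar_share(intakes[i, "free_sugars"], en),
      fs_group = classify_fs_group(intakes[i, "free_sugars"], en),
      sed = suppressWarnings(solid_energy_density(dv$diet[i, ], foods)),
      variety = as.integer(var_count[[ids[i]]]),
      mar = mar(intakes[i, nut], refs),
      mer = mer(intakes[i, nut], en, refs),
      pandiet = pd$pandiet,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-individual list of 7 x nutrient daily intake matrices
daily_intake_array <- function(events, foods) {
  ev <- events[!(events$food_id %in% foods$food_id[foods$is_alcoholic]), ,
               drop = FALSE]
  N <- as.matrix(foods[, fsdiet_nutrients()])
  rownames(N) <- foods$food_id
  ids <- unique(as.character(ev$individual_id))
  out <- vector("list", length(ids))
  names(out) <- ids
  key <- split(seq_len(nrow(ev)), as.character(ev$individual_id))
  for (id in ids) {
    e <- ev[key[[id]], , drop = FALSE]
    m <- matrix(0, 7, nrow(foods), dimnames = list(NULL, foods$food_id))
    agg <- rowsum(e$amount_g, group = paste(e$day, e$food_id, sep = "\r"))
    k <- strsplit(rownames(agg), "\r", fixed = TRUE)
    m[cbind(as.integer(vapply(k, `[`, "", 1L)),
            match(vapply(k, `[`, "", 2L), foods$food_id))] <- agg[, 1]
    day_nut <- m %*% N / 100
    day_nut <- cbind(day_nut,
                     non_free_sugars = day_nut[, "sugars"] - day_nut[, "free_sugars"])
    out[[id]] <- day_nut
  }
  out
}
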