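# Survey-weighted descriptive comparison of observed vs. optimized diets:
# food-category weight changes and the total/free/non-free sugar balance
# decomposition. Comparisons are weighted means and differences only;
# model-adjusted inference (GLM with survey design) is deliberately out of
# scope here.

#' Survey-weighted mean and SD
#'
#' Hajek (ratio) weighted mean; the weighted SD uses the frequency-style
#' normalization \eqn{\sum w (x - \bar x)^2 / (\sum w - \sum w^2 / \sum w)},
#' which reduces to the ordinary n-1 sample SD under equal weights and is
#' invariant to rescaling all weights. A single observation has a defined
#' mean and an NA SD.
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @return c(mean, sd).
#' @export
weighted_summary <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights))
    stop("values and weights must have the same length")
  if (any(weights <= 0)) stop("weights must be positive")
  m <- sum(weights * values) / sum(weights)
  denom <- sum(weights) - sum(weights^2) / sum(weights)
  s <- if (denom > 0) sqrt(sum(weights * (values - m)^2) / denom) else NA_real_
  c(mean = m, sd = s)
}

#' Weighted mean comparison of a variable between FS groups
#'
#' @param values per-individual values.
#' @param groups group labels per individual.
#' @param weights survey weights.
#' @return data.frame: one row per group with weighted mean/SD, plus the
#'   weighted between-group difference (EXCESS - ACCEPTABLE) when both
#'   groups are present.
#' @export
group_comparison <- function(values, groups, weights = rep(1, length(values))) {
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    ws <- weighted_summary(values[groups == g], weights[groups == g])
    data.frame(group = g, mean = ws["mean"], sd = ws["sd"],
               n = sum(groups == g), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (all(c("FS_ACCEPTABLE", "FS_EXCESS") %in% out$group))
    attr(out, "difference") <- out$mean[out$group == "FS_EXCESS"] -
      out$mean[out$group == "FS_ACCEPTABLE"]
  out
}

#' Food-category and sub-category weight changes after optimization
#'
#' Per-individual differences (optimized - observed, g/day) rolled up by
#' leaf sub-category and category, then survey-weight averaged per group.
#' Category changes equal the sum of their sub-category changes by
#' construction.
#'
#' @param observed,optimized individuals x foods matrices over the same
#'   individual set.
#' @param foods validated food table.
#' @param groups group label per individual (rows of the matrices).
#' @param weights survey weights per individual.
#' @return list of two data.frames, \code{category} and \code{subcategory}:
#'   group, level name, weighted mean change.
#' @export
weight_changes <- function(observed, optimized, foods, groups,
                           weights = rep(1, nrow(observed))) {
  stopifnot(identical(dim(observed), dim(optimized)),
            identical(rownames(observed), rownames(optimized)))
  miss <- setdiff(colnames(observed), foods$food_id)
  if (length(miss)) stop("foods missing taxonomy: ", paste(miss, collapse = ", "))
  delta <- optimized - observed
  roll <- function(labels) {
    M <- t(rowsum(t(delta), group = labels[match(colnames(delta), foods$food_id)]))
    do.call(rbind, lapply(sort(unique(groups)), function(g) {
      sel <- groups == g
      data.frame(group = g, name = colnames(M),
                 delta_g = apply(M[sel, , drop = FALSE], 2, function(x)
                   weighted_summary(x, weights[sel])["mean"]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  list(category = roll(foods$category), subcategory = roll(foods$subcategory))
}

#' Sugar-balance decomposition of the optimization
#'
#' Changes (optimized - observed, g/day) in total, free and non-free sugars
#' per food category and overall, survey-weight averaged per group. The
#' identity delta_total = delta_free + delta_non_free holds exactly at every
#' aggregation level, and category changes sum to the overall change.
#'
#' @inheritParams weight_changes
#' @return data.frame: group, category ("ALL" for the overall row),
#'   delta_total, delta_free, delta_non_free.
#' @export
sugar_balance <- function(observed, optimized, foods, groups,
                          weights = rep(1, nrow(observed))) {
  stopifnot(identical(dim(observed), dim(optimized)))
  idx <- match(colnames(observed), foods$food_id)
  per_cat <- function(contents) {
    g_mat <- (optimized - observed) *
      rep(contents[idx] / 100, each = nrow(observed))
    t(rowsum(t(g_mat), group = foods$category[idx]))
  }
  d_tot <- per_cat(foods$sugars)
  d_fre <- per_cat(foods$free_sugars)
  d_non <- d_tot - d_fre
  out <- list()
  for (g in sort(unique(groups))) {
    sel <- groups == g
    wmean <- function(M) apply(M[sel, , drop = FALSE], 2, function(x)
      weighted_summary(x, weights[sel])["mean"])
    cats <- colnames(d_tot)
    df <- data.frame(group = g, category = c(cats, "ALL"),
                     delta_total = c(wmean(d_tot), sum(wmean(d_tot))),
                     delta_free = c(wmean(d_fre), sum(wmean(d_fre))),
                     delta_non_free = c(wmean(d_non), sum(wmean(d_non))),
                     row.names = NULL, stringsAsFactors = FALSE)
    out[[g]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Published survey reference values
#'
#' Survey-weighted group summary values published for French adults (INCA2
#' 2006-2007): group sizes, energy and free sugars overall and by
#' meal/snacking moment, and the sugar-balance changes after optimization.
#' Used for desk-arithmetic consistency checks against printed results.
#'
#' @return data.frame: group, variable, value, unit.
#' @export
reference_values <- function() {
  utils::read.csv(fsdiet_file("inca2_reference_values.csv"),
                  stringsAsFactors = FALSE)
}

ref_value <- function(refs, group, variable) {
  v <- refs$value[refs$group == group & refs$variable == variable]
  if (length(v) != 1) stop("reference value not found: ", group, "/", variable)
  v
}

#' Meal-to-snacking free-sugar ratio from the published group means
#'
#' Ratio of mean free sugars consumed at main meals to snacking occasions,
#' computed from the published survey-weighted means for each group.
#'
#' @param refs reference table (default [reference_values()]).
#' @return named vector of ratios for FS_ACCEPTABLE and FS_EXCESS.
#' @export
published_meal_snack_ratio <- function(refs = reference_values()) {
  vapply(c("FS_ACCEPTABLE", "FS_EXCESS"), function(g)
    ref_value(refs, g, "free_sugars_main_meals") /
      ref_value(refs, g, "free_sugars_snacking"), numeric(1))
}

#' Total-sugar change implied by the published free/non-free changes
#'
#' Sums the published per-group changes in free and non-free sugars; by the
#' sugar-balance identity this must reproduce the published total-sugar
#' change.
#'
#' @param refs reference table (default [reference_values()]).
#' @return named vector of implied total changes (g/day) per group.
#' @export
published_sugar_balance_total <- function(refs = reference_values()) {
  vapply(c("FS_ACCEPTABLE", "FS_EXCESS"), function(g)
    ref_value(refs, g, "delta_free_sugars") +
      ref_value(refs, g, "delta_non_free_sugars"), numeric(1))
}
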