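# End-to-end convenience wrapper: generate (or accept) a survey, compute
# intakes and classifications, optimize every individual and summarize.

#' Run the full individual diet-modeling pipeline
#'
#' Classifies every individual by observed free-sugar energy share, solves
#' one iso-energy diet model per individual, and produces the
#' binding-constraint ranking, the food-group weight changes and the
#' sugar-balance decomposition by group.
#'
#' @param population an \code{fsdiet_population} (or compatible list with
#'   foods, individuals, events).
#' @param constraints from [load_constraints()].
#' @param params from [model_params()].
#' @return list: intakes (per-individual data.frame with fs_group),
#'   optimization (from [optimize_population()]), binding report,
#'   weight_changes, sugar_balance, feasible_rate.
#' @export
run_pipeline <- function(population, constraints = load_constraints(),
                         params = model_params()) {
  foods <- population$foods
  val <- validate_survey(population$events, population$individuals, foods)
  dv <- build_diet_vector(val$events, foods)
  intk <- compute_intakes(dv$diet, foods)
  ids <- rownames(dv$diet)
  grp <- classify_fs_group(intk[, "free_sugars"], intk[, "energy"])
  w <- val$individuals$survey_weight[match(ids, val$individuals$individual_id)]

  opt <- optimize_population(dv$diet, foods, constraints, params)
  feas <- names(opt$status)[opt$status == "optimal"]
  sel <- match(feas, ids)
  wc <- weight_changes(opt$observed, opt$optimized, foods,
                       groups = grp[sel], weights = w[sel])
  sb <- sugar_balance(opt$observed, opt$optimized, foods,
                      groups = grp[sel], weights = w[sel])
  list(intakes = data.frame(individual_id = ids,
                            energy = intk[, "energy"],
                            free_sugars = intk[, "free_sugars"],
                            fs_share = free_sugar_share(intk[, "free_sugars"],
                                                        intk[, "energy"]),
                            fs_group = grp, survey_weight = w,
                            stringsAsFactors = FALSE),
       optimization = opt,
       binding = opt$binding,
       weight_changes = wc,
       sugar_balance = sb,
       feasible_rate = opt$feasible_rate)
}
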