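# Individual diet models: iso-energy linear programs that meet the full
# nutritional constraint set while departing least from the observed diet.
#
# For individual i with observed diet o_f (g/day), repertoire foods
# (o_f > 0) get a deviation split q_f = o_f + d+_f - d-_f and non-repertoire
# foods enter as penalized variables. The objective
#   sum_rep (w+ d+_f + w- d-_f)/o_f  +  pi * sum_nonrep q_f/m_f
# expresses the model's three aims: prefer repertoire foods, penalize
# reductions of them more than additions (w- >= w+), and control the entry
# of non-repertoire foods (scaled by the population mean consumption m_f
# among consumers, which is also their cap).

#' Default individual-diet-model parameters
#'
#' @param w_plus weight on relative increases of repertoire foods.
#' @param w_minus weight on relative decreases (>= w_plus).
#' @param pi_nonrep penalty per population-mean unit of non-repertoire food.
#' @param dual_tolerance |dual| above which a constraint counts as binding.
#' @param solver_tolerance feasibility tolerance for accepting a solution.
#' @export
model_params <- function(w_plus = 1, w_minus = 2, pi_nonrep = 5,
                         dual_tolerance = 1e-6, solver_tolerance = 1e-8) {
  stopifnot(w_plus > 0, w_minus >= w_plus, pi_nonrep > 0, dual_tolerance > 0)
  list(w_plus = w_plus, w_minus = w_minus, pi_nonrep = pi_nonrep,
       dual_tolerance = dual_tolerance, solver_tolerance = solver_tolerance)
}

#' Load the constraint configuration
#'
#' @param path YAML constraint file; the default ships 33 nutritional rows
#'   plus structural settings.
#' @return list(nutritional = data.frame, structural = list).
#' @export
load_constraints <- function(path = fsdiet_file("constraints_adults.yaml")) {
  raw <- yaml::read_yaml(path)
  nut <- do.call(rbind, lapply(raw$nutritional_constraints, function(x)
    data.frame(id = x$id, kind = x$kind, nutrient = x$nutrient,
               bound = as.numeric(x$bound), basis = x$basis,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(nut$id)) stop("duplicated constraint ids")
  list(nutritional = nut, structural = raw$structural_constraints)
}

#' Population consumption limits for acceptability constraints
#'
#' From the population's observed diet matrix: per-food and per-sub-category
#' acceptability maxima (a quantile of consumption among consumers) and the
#' population mean consumption among consumers m_f used to scale and cap
#' non-repertoire foods. Foods never consumed in the population are flagged
#' out (they are not model variables).
#'
#' @param diet_matrix individuals x foods matrix (g/day).
#' @param foods validated food table.
#' @param q acceptability quantile (default 0.95).
#' @return list: food_max, m_f (named by food_id, NA where never consumed),
#'   group_max (named by leaf sub-category).
#' @export
population_limits <- function(diet_matrix, foods, q = 0.95) {
  stopifnot(ncol(diet_matrix) == nrow(foods))
  food_max <- m_f <- stats::setNames(rep(NA_real_, nrow(foods)), foods$food_id)
  for (j in seq_len(ncol(diet_matrix))) {
    x <- diet_matrix[, j]
    x <- x[x > 0]
    if (length(x)) {
      food_max[j] <- stats::quantile(x, q, names = FALSE)
      m_f[j] <- mean(x)
    }
  }
  subs <- unique(foods$subcategory)
  group_max <- stats::setNames(rep(NA_real_, length(subs)), subs)
  for (s in subs) {
    tot <- rowSums(diet_matrix[, foods$subcategory == s, drop = FALSE])
    tot <- tot[tot > 0]
    if (length(tot)) group_max[s] <- stats::quantile(tot, q, names = FALSE)
  }
  mean_energy <- mean(as.vector(diet_matrix %*% foods$energy) / 100)
  list(food_max = food_max, m_f = m_f, group_max = group_max,
       mean_energy = mean_energy)
}

#' Build the LP for one individual's diet model
#'
#' Rows: iso-energy equality at the observed non-alcoholic energy;
#' the 33 nutritional rows (percent-energy bounds rewritten as linear rows
#' at the fixed energy target; the free-sugar row switches between the
#' 10%-energy cap and a no-increase bound on the observed share); leaf
#' sub-category acceptability maxima; total diet weight (energy-free drinks
#' excluded) and total diet cost. Per-food acceptability maxima and
#' non-repertoire caps are variable bounds. Bounds that the observed diet
#' already exceeds are relaxed to the observed value so the individual's own
#' diet is never excluded by acceptability alone.
#'
#' @param observed named diet vector (g/day) over \code{foods$food_id}.
#' @param foods validated food table.
#' @param limits population limits from [population_limits()].
#' @param constraints from [load_constraints()].
#' @param params from [model_params()].
#' @return model list consumed by [optimize_diet()].
#' @export
build_model <- function(observed, foods, limits, constraints = load_constraints(),
                        params = model_params()) {
  stopifnot(length(observed) == nrow(foods))
  o <- stats::setNames(as.numeric(observed), foods$food_id)
  if (all(o <= 0)) stop("observed diet is empty")
  usable <- !foods$is_alcoholic & (o > 0 | !is.na(limits$m_f))
  o <- o[usable]
  fd <- foods[usable, , drop = FALSE]
  energy <- sum(o * fd$energy) / 100
  if (energy <= 0) stop("observed non-alcoholic energy must be positive")

  rep_idx <- which(o > 0)
  non_idx <- which(o == 0)
  m_f <- limits$m_f[fd$food_id]
  if (any(is.na(m_f[non_idx])))
    stop("missing population mean consumption for non-repertoire food(s): ",
         paste(fd$food_id[non_idx][is.na(m_f[non_idx])], collapse = ", "))
  nR <- length(rep_idx); nN <- length(non_idx)
  nv <- 2L * nR + nN
  # variable layout: d+ (nR) | d- (nR) | q_nonrep (nN)
  v_dp <- seq_len(nR); v_dm <- nR + seq_len(nR); v_q <- 2L * nR + seq_len(nN)

  obj <- c(params$w_plus / o[rep_idx], params$w_minus / o[rep_idx],
           params$pi_nonrep / m_f[non_idx])

  # acceptability caps scale with the individual's energy requirement:
  # portion ceilings observed on the population refer to its mean energy
  # level, and an iso-energy model for a high-energy individual must be
  # allowed proportionally larger amounts
  esc <- if (!is.null(limits$mean_energy) && limits$mean_energy > 0)
    max(1, energy / limits$mean_energy) else 1
  food_ub <- pmax(esc * limits$food_max[fd$food_id], o, na.rm = TRUE)
  ub <- c(food_ub[rep_idx] - o[rep_idx],  # d+ <= max - observed
          o[rep_idx],                      # d- <= observed
          pmin(m_f, food_ub)[non_idx])     # non-repertoire cap

  # a row over diets q translates to deviations: coef(d+) = a, coef(d-) = -a,
  # coef(q_non) = a, rhs reduced by a . o
  nut_mat <- as.matrix(fd[, fsdiet_nutrients()]) / 100  # per g
  row_for <- function(coef_per_g) {
    c(coef_per_g[rep_idx], -coef_per_g[rep_idx], coef_per_g[non_idx])
  }
  A <- list(); dir <- character(); rhs <- numeric(); ids <- character()
  add_row <- function(coef_per_g, sense, bound, id) {
    A[[length(A) + 1L]] <<- row_for(coef_per_g)
    dir[length(dir) + 1L] <<- sense
    rhs[length(rhs) + 1L] <<- bound - sum(coef_per_g * o)
    ids[length(ids) + 1L] <<- id
  }

  add_row(nut_mat[, "energy"], "=", energy, "energy_equality")

  obs_intake <- as.vector(o %*% nut_mat)
  names(obs_intake) <- colnames(nut_mat)
  obs_fs_share <- free_sugar_share(obs_intake["free_sugars"], energy)
  for (k in seq_len(nrow(constraints$nutritional))) {
    cs <- constraints$nutritional[k, ]
    coef <- nut_mat[, cs$nutrient]
    if (cs$kind == "free_sugar_conditional") {
      bound <- if (obs_fs_share > cs$bound)
        cs$bound / 100 * energy / 4 else obs_intake["free_sugars"]
      add_row(coef, "<=", unname(bound), cs$id)
    } else {
      bound <- if (cs$basis == "percent_energy")
        cs$bound / 100 * energy / kcal_per_g(cs$nutrient) else cs$bound
      add_row(coef, if (cs$kind == "nutrient_min") ">=" else "<=", bound, cs$id)
    }
  }

  for (s in names(limits$group_max)) {
    gm <- limits$group_max[s]
    if (is.na(gm)) next
    sel <- as.numeric(fd$subcategory == s)
    if (!any(sel > 0)) next
    add_row(sel, "<=", max(esc * gm, sum(sel * o)), paste0("group_max:", s))
  }

  wsel <- as.numeric(!fd$is_energy_free_drink)
  add_row(wsel, "<=",
          constraints$structural$total_weight_multiplier * sum(wsel * o),
          "weight_max")
  csel <- fd$unit_cost / 100
  add_row(csel, "<=",
          constraints$structural$total_cost_multiplier * sum(csel * o),
          "cost_max")

  list(obj = obj, A = do.call(rbind, A), dir = dir, rhs = rhs, ub = ub,
       constraint_ids = ids, foods = fd$food_id, observed = o,
       rep_idx = rep_idx, non_idx = non_idx, v = list(dp = v_dp, dm = v_dm, q = v_q),
       energy = energy, obs_fs_share = unname(obs_fs_share), params = params)
}

#' Solve one individual diet model
#'
#' Runs the simplex on a model from [build_model()], maps the solution back
#' to a diet vector and verifies every row within the solver tolerance.
#'
#' @param model from [build_model()].
#' @return OptimizationResult: list with status ("optimal", "infeasible" or
#'   "solver_error"), optimized diet (named g/day), objective, duals (named
#'   by constraint id, d objective / d bound), departures (optimized -
#'   observed), energy, iterations.
#' @export
optimize_diet <- function(model) {
  sol <- tryCatch(
    lp_solve(model$obj, model$A, model$dir, model$rhs, ub = model$ub),
    error = function(e) list(status = "solver_error", message = conditionMessage(e)))
  if (sol$status == "infeasible")
    return(structure(list(status = "infeasible", diet = NULL,
                          objective = NA_real_, duals = NULL,
                          foods = model$foods), class = "fsdiet_opt"))
  if (sol$status != "optimal")
    return(structure(list(status = "solver_error", diet = NULL,
                          objective = NA_real_, duals = NULL,
                          foods = model$foods,
                          message = sol$message %||% sol$status),
                     class = "fsdiet_opt"))
  x <- sol$x
  q <- model$observed
  q[model$rep_idx] <- q[model$rep_idx] + x[model$v$dp] - x[model$v$dm]
  q[model$non_idx] <- x[model$v$q]
  q <- pmax(q, 0)
  ok <- lp_row_satisfied(model$A, model$dir, model$rhs, x,
                         tol = model$params$solver_tolerance)
  if (!all(ok))
    return(structure(list(status = "solver_error", diet = NULL,
                          objective = NA_real_, duals = NULL,
                          foods = model$foods,
                          message = paste("rows violated:",
                                          paste(model$constraint_ids[!ok],
                                                collapse = ", "))),
                     class = "fsdiet_opt"))
  structure(list(status = "optimal",
                 diet = q,
                 objective = sol$objective,
                 duals = stats::setNames(sol$duals, model$constraint_ids),
                 departures = q - model$observed,
                 energy = model$energy,
                 iterations = sol$iterations,
                 foods = model$foods), class = "fsdiet_opt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fsdiet_opt <- function(x, ...) {
  cat("Individual diet model:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective:", signif(x$objective, 5),
        " binding rows:", sum(abs(x$duals) > 1e-6), "/", length(x$duals), "\n")
  }
  invisible(x)
}

#' Dual values of an optimal diet model
#'
#' @param result an optimal OptimizationResult.
#' @return named numeric vector of duals (d objective / d bound); zero for
#'   inactive constraints by complementary slackness.
#' @export
extract_duals <- function(result) {
  if (result$status != "optimal")
    stop("duals are only defined for optimal results (status: ",
         result$status, ")")
  result$duals
}

#' Rank constraints by their share of non-null dual values
#'
#' For each constraint, the percentage of individuals whose optimal diet
#' model carries a dual exceeding the tolerance in absolute value; sorted
#' in decreasing order (ties broken by constraint id). The most binding
#' constraints are the ones active for the largest share of the population.
#'
#' @param results list of OptimizationResults (infeasible ones are skipped).
#' @param dual_tolerance binding threshold on |dual|.
#' @return data.frame: constraint_id, pct_binding, rank.
#' @export
rank_binding <- function(results, dual_tolerance = 1e-6) {
  ok <- Filter(function(r) r$status == "optimal", results)
  if (!length(ok)) stop("no optimal results to rank")
  all_ids <- sort(unique(unlist(lapply(ok, function(r) names(r$duals)))))
  cnt <- stats::setNames(numeric(length(all_ids)), all_ids)
  tot <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (r in ok) {
    b <- abs(r$duals) > dual_tolerance
    cnt[names(b)] <- cnt[names(b)] + b
    tot[names(b)] <- tot[names(b)] + 1
  }
  pct <- 100 * cnt / pmax(tot, 1)
  ord <- order(-pct, all_ids)
  data.frame(constraint_id = all_ids[ord], pct_binding = unname(pct[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Optimize every individual in a survey
#'
#' Builds and solves one diet model per individual. Individuals whose model
#' is infeasible are reported as such and excluded from downstream
#' summaries, mirroring how infeasible survey respondents are dropped from
#' the analysis sample.
#'
#' @param diet_matrix individuals x foods observed diet matrix (g/day).
#' @param foods validated food table.
#' @param constraints from [load_constraints()].
#' @param params from [model_params()].
#' @param limits optional precomputed [population_limits()].
#' @return list: results (per individual), optimized matrix (optimal rows
#'   only), observed matrix, status vector, binding report.
#' @export
optimize_population <- function(diet_matrix, foods,
                                constraints = load_constraints(),
                                params = model_params(), limits = NULL) {
  if (is.null(limits))
    limits <- population_limits(diet_matrix, foods,
                                q = constraints$structural$acceptability_quantile %||% 0.95)
  ids <- rownames(diet_matrix)
  results <- vector("list", length(ids))
  names(results) <- ids
  opt <- matrix(NA_real_, nrow(diet_matrix), ncol(diet_matrix),
                dimnames = dimnames(diet_matrix))
  for (i in seq_along(ids)) {
    mod <- build_model(diet_matrix[i, ], foods, limits, constraints, params)
    res <- optimize_diet(mod)
    results[[i]] <- res
    if (res$status == "optimal") {
      opt[i, ] <- 0
      opt[i, res$foods] <- res$diet
    }
  }
  status <- vapply(results, function(r) r$status, "")
  feas <- status == "optimal"
  list(results = results,
       optimized = opt[feas, , drop = FALSE],
       observed = diet_matrix[feas, , drop = FALSE],
       status = status,
       feasible_rate = mean(feas),
       binding = if (any(feas)) rank_binding(results[feas],
                                             params$dual_tolerance))
}
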