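#!/usr/bin/env Rscript
# Step 3 — individual diet models.
#
# Solves one iso-energy LP per individual (33 nutrient rows + acceptability,
# weight and cost constraints, minimizing departure from the observed diet),
# writes observed/optimized amounts and per-individual duals, and prints the
# binding-constraint ranking (share of non-null dual values).

suppressMessages(library(fsdiet))

foods <- load_food_table("results/survey/foods.csv")
events <- utils::read.csv("results/survey/events.csv", stringsAsFactors = FALSE)
individuals <- utils::read.csv("results/survey/individuals.csv",
                               stringsAsFactors = FALSE)
v <- validate_survey(events, individuals, foods)
dv <- build_diet_vector(v$events, foods)

t0 <- Sys.time()
opt <- optimize_population(dv$diet, foods)
cat(sprintf("Optimized %d individuals in %.1f min; feasible: %.1f%%\n",
            nrow(dv$diet), as.numeric(Sys.time() - t0, units = "mins"),
            100 * opt$feasible_rate))
print(table(opt$status))

# long results: one row per (individual, food) with observed and optimized
ids <- rownames(opt$observed)
long <- data.frame(
  individual_id = rep(ids, each = ncol(opt$observed)),
  food_id = rep(colnames(opt$observed), times = length(ids)),
  observed_g = as.vector(t(opt$observed)),
  optimized_g = as.vector(t(opt$optimized)), stringsAsFactors = FALSE)
long <- long[long$observed_g > 0 | long$optimized_g > 1e-9, ]
utils::write.csv(long, "results/optimized_diets.csv", row.names = FALSE)

duals <- do.call(rbind, lapply(ids, function(id) {
  d <- opt$results[[id]]$duals
  data.frame(individual_id = id, constraint_id = names(d), dual = unname(d),
             stringsAsFactors = FALSE)
}))
utils::write.csv(duals, "results/duals.csv", row.names = FALSE)
utils::write.csv(opt$binding, "results/binding_report.csv", row.names = FALSE)

cat("\nMost binding constraints (% of individuals with non-null duals):\n")
print(head(opt$binding, 10), row.names = FALSE)
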