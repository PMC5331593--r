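#!/usr/bin/env Rscript
# Step 4 — observed vs. optimized comparison.
#
# Survey-weighted food-category weight changes and the total/free/non-free
# sugar-balance decomposition per FS group, with the identity
# delta_total = delta_free + delta_non_free checked at every level, and a
# side-by-side with the published sugar-balance changes.

suppressMessages(library(fsdiet))

foods <- load_food_table("results/survey/foods.csv")
individuals <- utils::read.csv("results/survey/individuals.csv",
                               stringsAsFactors = FALSE)
long <- utils::read.csv("results/optimized_diets.csv", stringsAsFactors = FALSE)

ids <- unique(long$individual_id)
to_mat <- function(col) {
  m <- matrix(0, length(ids), nrow(foods),
              dimnames = list(ids, foods$food_id))
  m[cbind(long$individual_id, long$food_id)] <- long[[col]]
  m
}
obs <- to_mat("observed_g")
opt <- to_mat("optimized_g")

ik <- compute_intakes(obs, foods)
grp <- classify_fs_group(ik[, "free_sugars"], ik[, "energy"])
w <- individuals$survey_weight[match(ids, individuals$individual_id)]

wc <- weight_changes(obs, opt, foods, grp, w)
utils::write.csv(wc$category, "results/weight_changes_category.csv",
                 row.names = FALSE)
utils::write.csv(wc$subcategory, "results/weight_changes_subcategory.csv",
                 row.names = FALSE)
cat("Weight changes by food category (g/day, optimized - observed):\n")
wide <- stats::reshape(wc$category, idvar = "name", timevar = "group",
                       direction = "wide")
print(within(wide, {
  delta_g.FS_ACCEPTABLE <- round(delta_g.FS_ACCEPTABLE, 1)
  delta_g.FS_EXCESS <- round(delta_g.FS_EXCESS, 1)
}), row.names = FALSE)

sb <- sugar_balance(obs, opt, foods, grp, w)
stopifnot(all(abs(sb$delta_total - (sb$delta_free + sb$delta_non_free)) < 1e-9))
utils::write.csv(sb, "results/sugar_balance.csv", row.names = FALSE)

cat("\nSugar balance, overall rows (g/day):\n")
print(within(sb[sb$category == "ALL", ], {
  delta_total <- round(delta_total, 1)
  delta_free <- round(delta_free, 1)
  delta_non_free <- round(delta_non_free, 1)
}), row.names = FALSE)

refs <- reference_values()
cat("\nPublished changes for comparison (g/day):\n")
print(refs[refs$variable %in% c("delta_free_sugars", "delta_non_free_sugars",
                                "delta_total_sugars_printed"), ],
      row.names = FALSE)
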