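#!/usr/bin/env Rscript
# Stage 5 -- descriptive profiles of the velocity classes: maternal and
# neonatal comparisons (ANOVA / chi-square with Ryan pairwise tests),
# body-proportion trajectories, and examiner homogeneity.
suppressPackageStartupMessages(library(fetalvelo))

cohort <- read_cohort("results/cohort")
zgrid <- utils::read.csv("results/weekly_z.csv")
post <- utils::read.csv("results/assignments.csv")
assignment <- stats::setNames(post$class, post$subject_id)

tab <- class_comparison_table(cohort$maternal, cohort$neonatal, assignment)
utils::write.csv(tab, "results/class_comparisons.csv", row.names = FALSE)
cat("Class comparisons (one row per characteristic):\n")
print(tab, row.names = FALSE, digits = 3)

ratios <- ratio_trajectories(zgrid, assignment)
utils::write.csv(ratios, "results/ratio_trajectories.csv",
                 row.names = FALSE)

ex <- examiner_homogeneity(assignment, primary_examiner(cohort$visits))
if (isTRUE(ex$skipped)) {
  cat("Examiner homogeneity skipped:", ex$reason, "\n")
} else {
  cat(sprintf("Examiner homogeneity (%d examiners with >= 100 subjects):",
              length(ex$examiners)))
  cat(sprintf(" chi-square = %.2f, p = %.3f\n", ex$statistic, ex$p))
}
cat("Profiles written under results/\n")
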