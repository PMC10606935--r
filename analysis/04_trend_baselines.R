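#!/usr/bin/env Rscript
# Compare the adaptive stepwise trend algorithm against ordinary
# polynomial curve-fitting baselines (degrees 2-4): the same cohort is
# re-featurized under each detrending method and the classifier suite
# re-evaluated. Writes results/trend_baselines.csv.

library(gaitropy)

cohort <- read_cohort("results/cohort")
methods <- c("stepwise", "poly2", "poly3", "poly4")

rows <- lapply(methods, function(m) {
  feats <- feature_table(cohort, method = m)
  report <- train_evaluate(feats, eval_config(rng_seed = 7))
  acc <- vapply(report$classifiers, function(cl) cl$metrics$accuracy, 0)
  data.frame(method = m,
             best_classifier = names(acc)[which.max(acc)],
             best_accuracy_pct = 100 * max(acc),
             svm_gaussian_pct = 100 * acc[["svm_gaussian"]],
             logistic_regression_pct = 100 * acc[["logistic_regression"]],
             knn_cosine_pct = 100 * acc[["knn_cosine"]])
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/trend_baselines.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nThe stepwise algorithm adapts to each subject's habitual waveform;\n")
cat("fixed polynomials leave habit mismatch in the residual and typically\n")
cat("lose accuracy. Wrote results/trend_baselines.csv\n")
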