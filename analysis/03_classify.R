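#!/usr/bin/env Rscript
# Train and 10-fold cross-validate the classifier suite on the
# 16-feature table, with "diseased" as the positive class. Writes
# per-classifier metrics, pooled confusion matrices and ROC points
# under results/.

library(gaitropy)

feats <- read.csv("results/features.csv")
report <- train_evaluate(feats, eval_config(rng_seed = 7))
print(report)

metrics <- do.call(rbind, lapply(names(report$classifiers), function(name) {
  cl <- report$classifiers[[name]]
  m <- cl$metrics
  data.frame(classifier = name,
             accuracy_pct = 100 * m$accuracy,
             sensitivity_pct = 100 * m$sensitivity,
             specificity_pct = 100 * m$specificity,
             f1 = m$f1, mcc = m$mcc, auc = cl$auc)
}))
write.csv(metrics[order(-metrics$accuracy_pct), ],
          "results/metrics.csv", row.names = FALSE)

cms <- do.call(rbind, lapply(names(report$classifiers), function(name) {
  cm <- report$classifiers[[name]]$confusion
  data.frame(classifier = name, tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp)
}))
write.csv(cms, "results/confusion_matrices.csv", row.names = FALSE)

roc <- do.call(rbind, lapply(names(report$classifiers), function(name) {
  cbind(classifier = name, report$classifiers[[name]]$roc)
}))
write.csv(roc, "results/roc_points.csv", row.names = FALSE)

best <- metrics$classifier[which.max(metrics$accuracy_pct)]
cat(sprintf("\nBest classifier: %s at %.1f%% accuracy (pooled over folds).\n",
            best, max(metrics$accuracy_pct)))
cat("Wrote results/metrics.csv, results/confusion_matrices.csv, results/roc_points.csv\n")
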