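#' Evaluation configuration for the classifier suite
#'
#' @param scheme `"kfold"` cross-validation (default) or a single
#'   stratified `"holdout"` split.
#' @param k Number of folds.
#' @param holdout_fraction Test fraction for the holdout scheme (0.25
#'   of 60 subjects gives a 45/15 train/test split).
#' @param stratified Preserve class balance across folds.
#' @param rng_seed Integer seed; the whole evaluation is deterministic
#'   given the config.
#' @param classifiers Subset of [classifier_roster()].
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(scheme = c("kfold", "holdout"),
                        k = 10L,
                        holdout_fraction = 0.25,
                        stratified = TRUE,
                        rng_seed = 1L,
                        classifiers = classifier_roster()) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  }
  unknown <- setdiff(classifiers, classifier_roster())
  if (length(unknown)) {
    stop("unknown classifier(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(scheme = scheme, k = k,
                 holdout_fraction = holdout_fraction,
                 stratified = isTRUE(stratified),
                 rng_seed = as.integer(rng_seed),
                 classifiers = classifiers),
            class = "eval_config")
}

#' Names of the available classifiers
#'
#' The suite mirrors the model families commonly offered by point-and-
#' click learner tools: Gaussian-kernel SVM, logistic regression,
#' cosine-distance KNN (10 neighbours), a wide single-hidden-layer
#' neural network (100 units), a decision tree, kernel-density naive
#' Bayes, quadratic discriminant analysis, bagged trees, and a second
#' RBF-kernel SVM implementation.
#'
#' @return Character vector of classifier names.
#' @export
classifier_roster <- function() {
  c("svm_gaussian", "logistic_regression", "knn_cosine", "neural_net_wide",
    "decision_tree", "naive_bayes_kernel", "quadratic_discriminant",
    "ensemble_bagged_tree", "kernel_svm")
}

# Each fitter takes standardized train/test matrices and a two-level
# factor (healthy, diseased) and returns list(pred = factor levels of y,
# score = numeric, larger = more diseased).
fit_predict <- function(name, x_train, y_train, x_test) {
  lv <- levels(y_train)
  switch(name,
    svm_gaussian = {
      m <- e1071::svm(x_train, y_train, kernel = "radial", probability = TRUE)
      pr <- stats::predict(m, x_test, probability = TRUE)
      sc <- attr(pr, "probabilities")[, "diseased"]
      list(pred = factor(as.character(pr), levels = lv), score = sc)
    },
    logistic_regression = {
      df <- data.frame(y = y_train, x_train)
      m <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      sc <- suppressWarnings(
        stats::predict(m, newdata = data.frame(x_test), type = "response"))
      list(pred = factor(ifelse(sc >= 0.5, lv[2], lv[1]), levels = lv), score = sc)
    },
    knn_cosine = knn_cosine_predict(x_train, y_train, x_test, k = 10L),
    neural_net_wide = {
      m <- nnet::nnet(x_train, as.numeric(y_train == "diseased"),
                      size = 100L, decay = 0.05, maxit = 300L,
                      MaxNWts = 10000L, trace = FALSE)
      sc <- as.numeric(stats::predict(m, x_test))
      list(pred = factor(ifelse(sc >= 0.5, lv[2], lv[1]), levels = lv), score = sc)
    },
    decision_tree = {
      df <- data.frame(y = y_train, x_train)
      m <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(minsplit = 5L, cp = 0.01))
      sc <- stats::predict(m, data.frame(x_test), type = "prob")[, "diseased"]
      list(pred = factor(ifelse(sc >= 0.5, lv[2], lv[1]), levels = lv), score = sc)
    },
    naive_bayes_kernel = naive_bayes_kernel_predict(x_train, y_train, x_test),
    quadratic_discriminant = {
      m <- tryCatch(MASS::qda(x_train, y_train),
                    error = function(e) MASS::lda(x_train, y_train))
      pr <- stats::predict(m, x_test)
      list(pred = factor(as.character(pr$class), levels = lv),
           score = pr$posterior[, "diseased"])
    },
    ensemble_bagged_tree = {
      m <- randomForest::randomForest(x_train, y_train,
                                      mtry = ncol(x_train), ntree = 200L)
      sc <- stats::predict(m, x_test, type = "prob")[, "diseased"]
      list(pred = factor(ifelse(sc >= 0.5, lv[2], lv[1]), levels = lv), score = sc)
    },
    kernel_svm = {
      m <- kernlab::ksvm(x_train, y_train, kernel = "rbfdot", C = 1)
      sc <- kernlab::predict(m, x_test, type = "decision")[, 1]
      # decision value sign depends on level order seen at fit time
      if (m@lev[1] == "diseased") sc <- -sc
      list(pred = factor(ifelse(sc >= 0, lv[2], lv[1]), levels = lv), score = sc)
    },
    stop("unknown classifier: ", name, call. = FALSE)
  )
}

# Cosine-distance k-nearest-neighbour vote. Score = fraction of
# diseased neighbours; 5-5 ties go to the nearest neighbour's class.
knn_cosine_predict <- function(x_train, y_train, x_test, k = 10L) {
  lv <- levels(y_train)
  k <- min(k, nrow(x_train))
  nrm <- function(m) {
    n <- sqrt(rowSums(m^2))
    n[n == 0] <- 1
    m / n
  }
  sim <- nrm(x_test) %*% t(nrm(x_train)) # cosine similarity
  pred <- character(nrow(x_test))
  score <- numeric(nrow(x_test))
  for (i in seq_len(nrow(x_test))) {
    ord <- order(sim[i, ], decreasing = TRUE)
    nb <- y_train[ord[seq_len(k)]]
    frac <- mean(nb == "diseased")
    score[i] <- frac
    pred[i] <- if (frac > 0.5) lv[2]
               else if (frac < 0.5) lv[1]
               else as.character(nb[1])
  }
  list(pred = factor(pred, levels = lv), score = score)
}

# Naive Bayes with per-feature kernel density estimates per class.
naive_bayes_kernel_predict <- function(x_train, y_train, x_test) {
  lv <- levels(y_train)
  eps <- 1e-9
  loglik <- sapply(lv, function(cl) {
    xs <- x_train[y_train == cl, , drop = FALSE]
    ll <- rep(log(mean(y_train == cl)), nrow(x_test))
    for (j in seq_len(ncol(x_train))) {
      v <- xs[, j]
      bw <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
      if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(v), 1e-3)
      d <- stats::density(v, bw = bw, from = min(c(v, x_test[, j])) - 3 * bw,
                          to = max(c(v, x_test[, j])) + 3 * bw, n = 512L)
      f <- stats::approx(d$x, d$y, xout = x_test[, j], rule = 2)$y
      ll <- ll + log(pmax(f, eps))
    }
    ll
  })
  post <- exp(loglik - apply(loglik, 1L, max))
  post <- post / rowSums(post)
  sc <- post[, "diseased"]
  list(pred = factor(ifelse(sc >= 0.5, lv[2], lv[1]), levels = lv), score = sc)
}

# Stratified fold assignment (or holdout: fold 1 = test, 0 = train).
assign_folds <- function(labels, config) {
  n <- length(labels)
  fold <- integer(n)
  if (config$scheme == "kfold") {
    if (config$stratified) {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(config$k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(config$k), n)
    }
  } else {
    # hit round(n * fraction) exactly, allocating per class by largest
    # fractional remainder
    total_test <- round(n * config$holdout_fraction)
    sizes <- vapply(levels(labels), function(cl) sum(labels == cl), 0L)
    base <- floor(sizes * config$holdout_fraction)
    extra <- total_test - sum(base)
    if (extra > 0) {
      ord <- order(sizes * config$holdout_fraction - base, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
    }
    for (cl in levels(labels)) {
      fold[sample(which(labels == cl), base[[cl]])] <- 1L
    }
  }
  fold
}

#' Train and cross-validate the classifier suite
#'
#' Features are median-imputed and standardized using training-fold
#' statistics only; each requested classifier is fitted and evaluated
#' per fold. "Diseased" is the positive class throughout. The whole
#' procedure is deterministic given `config$rng_seed`.
#'
#' @param features Data frame / tibble with a two-level `label` column
#'   (healthy, diseased) and numeric feature columns (an optional
#'   `subject_id` column is carried along but not used as a feature).
#' @param config An [eval_config()].
#' @return An `evaluation_report`: per classifier, the pooled confusion
#'   matrix, per-fold confusion matrices, metrics
#'   (accuracy/sensitivity/specificity/F1/MCC, plus mean per-fold
#'   accuracy), ROC points and AUC.
#' @export
train_evaluate <- function(features, config = eval_config()) {
  labels <- features$label
  if (is.null(labels)) stop("features must have a 'label' column", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("healthy", "diseased"))
  if (any(table(labels) < 2L)) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  feat_cols <- setdiff(names(features), c("subject_id", "label"))
  x_all <- as.matrix(features[, feat_cols])
  storage.mode(x_all) <- "double"

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)
  fold <- assign_folds(labels, config)
  test_folds <- if (config$scheme == "kfold") seq_len(config$k) else 1L
  for (tf in test_folds) {
    if (length(unique(labels[fold != tf])) < 2L ||
        length(labels[fold == tf]) == 0L) {
      stop("stratification failed: a fold lost a class; ",
           "reduce k or add subjects per class", call. = FALSE)
    }
  }

  out <- lapply(stats::setNames(nm = config$classifiers), function(name) {
    pred <- factor(rep(NA_character_, length(labels)),
                   levels = levels(labels))
    score <- rep(NA_real_, length(labels))
    fold_cms <- list()
    for (tf in test_folds) {
      tr <- fold != tf
      te <- fold == tf
      prep <- standardize_impute(x_all[tr, , drop = FALSE],
                                 x_all[te, , drop = FALSE])
      set.seed(config$rng_seed + 1009L * tf +
                 101L * match(name, classifier_roster()))
      fp <- fit_predict(name, prep$train, labels[tr], prep$test)
      pred[te] <- fp$pred
      score[te] <- fp$score
      fold_cms[[length(fold_cms) + 1L]] <-
        confusion_counts(labels[te], fp$pred)
    }
    seen <- !is.na(pred)
    cm <- confusion_counts(labels[seen], pred[seen])
    metrics <- compute_metrics(cm)
    metrics$mean_fold_accuracy <- mean(vapply(fold_cms, function(m) {
      compute_metrics(m)$accuracy
    }, 0))
    roc <- roc_curve(score[seen], labels[seen])
    list(confusion = cm, fold_confusions = fold_cms, metrics = metrics,
         roc = roc$points, auc = roc$auc)
  })
  structure(list(classifiers = out, config = config,
                 n = length(labels), folds = fold),
            class = "evaluation_report")
}

# Median imputation (train statistics) + z-standardization.
standardize_impute <- function(x_train, x_test) {
  for (j in seq_len(ncol(x_train))) {
    med <- stats::median(x_train[, j], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    x_train[is.na(x_train[, j]), j] <- med
    x_test[is.na(x_test[, j]), j] <- med
  }
  mu <- colMeans(x_train)
  sd_ <- apply(x_train, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(train = sweep(sweep(x_train, 2L, mu), 2L, sd_, "/"),
       test = sweep(sweep(x_test, 2L, mu), 2L, sd_, "/"))
}

#' Confusion-matrix counts
#'
#' @param truth,pred Factors with levels healthy, diseased ("diseased"
#'   is the positive class).
#' @return A `confusion_matrix`: list with counts `tn`, `fp`, `fn`, `tp`.
#' @export
confusion_counts <- function(truth, pred) {
  structure(list(
    tn = sum(truth == "healthy" & pred == "healthy"),
    fp = sum(truth == "healthy" & pred == "diseased"),
    fn = sum(truth == "diseased" & pred == "healthy"),
    tp = sum(truth == "diseased" & pred == "diseased")
  ), class = "confusion_matrix")
}

#' Metrics of a 2x2 confusion matrix
#'
#' Accuracy, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, F1 for
#' the positive (diseased) class, and the Matthews correlation
#' coefficient. All returned as proportions in \[0, 1\] (MCC in
#' \[-1, 1\]); undefined ratios (zero denominators) come back as `NA`.
#'
#' @param cm A `confusion_matrix` (or list/vector with `tn, fp, fn, tp`).
#' @return List of metrics.
#' @export
compute_metrics <- function(cm) {
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  total <- tn + fp + fn + tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- safe_div(tp, tp + fp)
  sens <- safe_div(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  list(accuracy = (tp + tn) / total,
       sensitivity = sens,
       specificity = safe_div(tn, tn + fp),
       precision = prec,
       f1 = f1,
       mcc = mcc)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds run through the unique score values (ties grouped); each
#' yields one (FPR, TPR) point for the rule "score >= threshold predicts
#' diseased". AUC is the trapezoidal area under the resulting curve.
#'
#' @param scores Numeric scores, larger = more diseased.
#' @param labels Factor with levels healthy, diseased; both present.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("healthy", "diseased"))
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels == "diseased")
  n_neg <- sum(labels == "healthy")
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == "diseased") / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == "healthy") / n_neg, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation (%s, seed %d, n = %d):\n",
              if (x$config$scheme == "kfold") sprintf("%d-fold CV", x$config$k)
              else sprintf("%.0f%% holdout", 100 * x$config$holdout_fraction),
              x$config$rng_seed, x$n))
  tab <- t(vapply(x$classifiers, function(cl) {
    m <- cl$metrics
    c(accuracy_pct = 100 * m$accuracy,
      sensitivity_pct = 100 * m$sensitivity,
      specificity_pct = 100 * m$specificity,
      F1 = m$f1, MCC = m$mcc, AUC = cl$auc)
  }, numeric(6)))
  print(round(tab[order(-tab[, "accuracy_pct"]), , drop = FALSE], digits))
  invisible(x)
}
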