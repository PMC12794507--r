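#' Repeated stratified cross-validation plan
#'
#' @param k_folds folds per repeat (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed for the fold assignments.
#' @return a `cv_plan` list.
#' @export
cv_plan <- function(k_folds = 5L, repeats = 10L, seed = 1L) {
  structure(list(k_folds = check_count(k_folds, "k_folds", min = 2L),
                 repeats = check_count(repeats, "repeats"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "cv_plan")
}

# F1 (positive class = second dimension level) and Cohen's kappa from a
# 2x2 confusion matrix with truth in rows, prediction in columns.
confusion_metrics <- function(conf) {
  tp <- conf[2L, 2L]; fp <- conf[1L, 2L]; fn <- conf[2L, 1L]
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(F1 = f1, kappa = kappa, precision = precision, recall = recall)
}

#' Evaluate a gene-set feature matrix as a disease classifier
#'
#' L2-regularized logistic regression (fixed small ridge penalty for
#' stability) under repeated stratified k-fold cross-validation. Features
#' are standardized per fold with training-fold statistics only (no
#' leakage). F1 (positive class = disease) and Cohen's kappa are computed
#' on the pooled out-of-fold predictions of each repeat, then averaged
#' over repeats.
#'
#' @param features samples x genes numeric matrix.
#' @param labels two-level factor or character per sample; the positive
#'   (disease) class is `positive`, defaulting to the second sorted level.
#' @param plan a [cv_plan()].
#' @param positive positive class label.
#' @param lambda ridge penalty (default 1e-3).
#' @return a `classifier_report` list: `F1`, `kappa` (means over repeats),
#'   `per_repeat` (data.frame repeat, F1, kappa), `confusion` (summed over
#'   all repeats), `plan`.
#' @export
evaluate_classifier <- function(features, labels, plan = cv_plan(),
                                positive = NULL, lambda = 1e-3) {
  stopifnot(inherits(plan, "cv_plan"))
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  positive <- positive %||% classes[2L]
  if (!positive %in% classes) stop_invalid("positive", "not a label level")
  negative <- setdiff(classes, positive)
  y <- factor(labels, levels = c(negative, positive))
  if (min(table(y)) < plan$k_folds) {
    stop(sprintf("smallest class has %d samples < k_folds = %d; reduce k_folds",
                 min(table(y)), plan$k_folds), call. = FALSE)
  }
  if (ncol(features) < 2L) {
    features <- cbind(features, pad0 = 0)  # ridge solver needs >= 2 columns
  }
  seeds <- derive_seeds(plan$seed, plan$repeats)
  per_repeat <- vector("list", plan$repeats)
  conf_total <- matrix(0, 2L, 2L, dimnames = list(truth = levels(y),
                                                  pred = levels(y)))
  for (r in seq_len(plan$repeats)) {
    folds <- with_seed(seeds[r], {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(plan$k_folds), length(idx)))
      }
      f
    })
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (k in seq_len(plan$k_folds)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) {
        stop("a training fold contains a single class; reduce k_folds",
             call. = FALSE)
      }
      mu <- colMeans(features[tr, , drop = FALSE])
      sdv <- apply(features[tr, , drop = FALSE], 2L, sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      xtr <- sweep(sweep(features[tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
      xte <- sweep(sweep(features[!tr, , drop = FALSE], 2L, mu), 2L, sdv, `/`)
      if (all(apply(xtr, 2L, sd) == 0)) {
        # degenerate predictors: intercept-only model, majority class
        prob <- rep(mean(y[tr] == levels(y)[2L]), sum(!tr))
      } else {
        fit <- glmnet::glmnet(xtr, y[tr], family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE)
        prob <- as.numeric(predict(fit, xte, type = "response"))
      }
      pred[!tr] <- levels(y)[1L + (prob > 0.5)]
    }
    conf <- table(truth = y, pred = pred)
    conf_total <- conf_total + conf
    m <- confusion_metrics(conf)
    per_repeat[[r]] <- data.frame(rep = r, F1 = m$F1, kappa = m$kappa)
  }
  per_repeat <- do.call(rbind, per_repeat)
  structure(list(F1 = mean(per_repeat$F1), kappa = mean(per_repeat$kappa),
                 per_repeat = per_repeat, confusion = conf_total,
                 positive = positive, plan = plan, lambda = lambda),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> F1 = %.3f, kappa = %.3f (positive = '%s', %d repeats x %d folds)\n",
              x$F1, x$kappa, x$positive, x$plan$repeats, x$plan$k_folds))
  invisible(x)
}

#' Compare module features against CV2-selected control features
#'
#' Runs [evaluate_classifier()] once with the module genes and once with an
#' equally sized CV2-selected control gene set on the same samples.
#'
#' @param expr genes x samples matrix.
#' @param labels per-sample class labels (two levels).
#' @param module_genes a [gene_set()] or character vector.
#' @param plan a [cv_plan()].
#' @param ... passed to [evaluate_classifier()].
#' @return data.frame (feature_set, F1, kappa).
#' @export
compare_feature_sets <- function(expr, labels, module_genes,
                                 plan = cv_plan(), ...) {
  mod <- intersect(as_genes(module_genes), rownames(expr))
  if (!length(mod)) stop("no module genes present in the matrix", call. = FALSE)
  ctrl <- cv2_select(expr, n_genes = length(mod))
  reports <- list(
    module = evaluate_classifier(t(expr[mod, , drop = FALSE]), labels, plan, ...),
    cv2_control = evaluate_classifier(t(expr[ctrl$genes, , drop = FALSE]),
                                      labels, plan, ...))
  data.frame(feature_set = names(reports),
             F1 = vapply(reports, `[[`, 0, "F1"),
             kappa = vapply(reports, `[[`, 0, "kappa"),
             row.names = NULL, stringsAsFactors = FALSE)
}
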