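# Event classification: three-feature representation, class balancing,
# one-vs-one Gaussian-kernel SVM, stratified cross-validation and reporting.

#' Build the classifier feature representation
#'
#' Maps per-event parameters to the feature triplet `(I_B, log10(t_D / 1 us),
#' i_rms)`. The logarithmic dwell time compresses the wide dwell range so no
#' single feature dominates the kernel.
#'
#' @param events `data.frame` with columns `I_B`, `t_D_us` and `i_rms_nA`
#'   (as produced by [sample_event_features()] or [extract_features()]).
#' @param label Optional class labels (length 1, recycled, or one per row);
#'   defaults to the `class_label` column when present.
#' @return Object of class `"feature_set"`: list with matrix `x`
#'   (columns `I_B`, `log10_tD`, `i_rms`), factor `label` (or `NULL`) and a
#'   standardization record `std` (`NULL` until fitted).
#' @export
build_features <- function(events, label = NULL) {
  need <- c("I_B", "t_D_us", "i_rms_nA")
  if (!all(need %in% names(events)))
    stop("events must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(events$t_D_us <= 0))
    stop("all dwell times must be > 0", call. = FALSE)
  x <- cbind(I_B = events$I_B,
             log10_tD = log10(events$t_D_us),
             i_rms = events$i_rms_nA)
  if (any(!is.finite(x))) stop("features contain missing or non-finite values",
                               call. = FALSE)
  if (is.null(label) && "class_label" %in% names(events))
    label <- events$class_label
  if (!is.null(label)) label <- factor(rep_len(label, nrow(x)))
  structure(list(x = x, label = label, std = NULL), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d events x %d features%s\n", nrow(x$x),
              ncol(x$x),
              if (is.null(x$label)) "" else
                paste0("; classes: ",
                       paste(sprintf("%s=%d", levels(x$label),
                                     tabulate(x$label)), collapse = ", "))))
  invisible(x)
}

#' Fit a z-score standardization on training features
#' @param x Numeric feature matrix.
#' @return List with per-column `center` and `scale`.
#' @export
fit_standardization <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale <= 0))
    stop("zero-variance feature; standardization undefined", call. = FALSE)
  list(center = center, scale = scale)
}

#' Apply a stored standardization to (possibly new) features
#' @param x Numeric feature matrix.
#' @param std A [fit_standardization()] record, reused at prediction time.
#' @return Standardized matrix.
#' @export
apply_standardization <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Balance class representation by downsampling
#'
#' Shuffles rows with the given seed and downsamples every class without
#' replacement to the minority-class count, ensuring equal representation of
#' each sample in training and cross-validation.
#'
#' @param fs A labeled [build_features()] set with >= 2 classes.
#' @param seed Optional integer seed.
#' @return A `"feature_set"` with equal class counts.
#' @export
balance_classes <- function(fs, seed = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  if (is.null(fs$label) || nlevels(fs$label) < 2)
    stop("balancing needs a labeled set with >= 2 classes", call. = FALSE)
  counts <- tabulate(fs$label, nlevels(fs$label))
  if (any(counts == 0)) stop("class with zero rows: ",
                             levels(fs$label)[which(counts == 0)[1]],
                             call. = FALSE)
  m <- min(counts)
  with_seed(seed, {
    perm <- sample(nrow(fs$x))
    lab_p <- fs$label[perm]
    keep <- unlist(lapply(levels(fs$label),
                          function(l) which(lab_p == l)[seq_len(m)]))
    keep <- sort(keep) # preserve shuffled order
    structure(list(x = fs$x[perm, , drop = FALSE][keep, , drop = FALSE],
                   label = droplevels(lab_p[keep]), std = fs$std),
              class = "feature_set")
  })
}

#' SVM configuration
#'
#' @param kernel_scale Gaussian kernel scale `s`; the kernel is
#'   `K(x, y) = exp(-||x - y||^2 / s^2)` on standardized features
#'   (equivalently `gamma = 1 / s^2`). Default 2 ("fine" Gaussian kernel).
#' @param cost Box constraint C.
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed controlling folds and any tie randomization.
#' @return Object of class `"svm_config"`.
#' @export
svm_config <- function(kernel_scale = 2, cost = 1, n_folds = 5, seed = 1) {
  stopifnot(kernel_scale > 0, cost > 0, n_folds >= 2)
  structure(list(kernel_scale = kernel_scale, cost = cost,
                 n_folds = as.integer(n_folds), seed = seed),
            class = "svm_config")
}

#' Train the one-vs-one Gaussian-kernel SVM
#'
#' Standardizes the training features (the record is stored for reuse at
#' prediction time) and fits a one-vs-one RBF-kernel SVM with
#' `gamma = 1 / kernel_scale^2`.
#'
#' @param fs A labeled `"feature_set"` (>= 2 classes, >= 5 rows per class).
#' @param cfg An [svm_config()].
#' @return Object of class `"svm_artifact"`.
#' @export
train_svm <- function(fs, cfg = svm_config()) {
  stopifnot(inherits(fs, "feature_set"), inherits(cfg, "svm_config"))
  if (is.null(fs$label) || nlevels(droplevels(fs$label)) < 2)
    stop("training requires >= 2 classes", call. = FALSE)
  lab <- droplevels(fs$label)
  if (min(tabulate(lab)) < 5)
    stop("training requires >= 5 rows per class", call. = FALSE)
  std <- fs$std %||% fit_standardization(fs$x)
  z <- apply_standardization(fs$x, std)
  model <- e1071::svm(x = z, y = lab, type = "C-classification",
                      kernel = "radial", gamma = 1 / cfg$kernel_scale^2,
                      cost = cfg$cost, scale = FALSE)
  structure(list(model = model, std = std, levels = levels(lab),
                 features = colnames(fs$x), cfg = cfg,
                 schema_version = "1"),
            class = "svm_artifact")
}

#' Predict event classes and per-class decision scores
#'
#' Applies the stored standardization, evaluates all pairwise decision
#' values, and aggregates them into one score per class (sum of signed
#' pairwise margins). The predicted label is the score argmax, which breaks
#' one-vs-one voting ties deterministically; the scores are suitable for
#' one-vs-rest ROC analysis.
#'
#' @param object An [train_svm()] artifact.
#' @param events Feature input: a `"feature_set"`, a feature matrix, or an
#'   event `data.frame` accepted by [build_features()].
#' @param ... Unused.
#' @return List with factor `label` and numeric matrix `scores`
#'   (events x classes).
#' @export
predict.svm_artifact <- function(object, events, ...) {
  x <- if (inherits(events, "feature_set")) events$x
       else if (is.matrix(events)) events
       else build_features(events)$x
  if (!identical(colnames(x), object$features))
    stop("feature schema mismatch: expected ",
         paste(object$features, collapse = ", "), call. = FALSE)
  z <- apply_standardization(x, object$std)
  pr <- stats::predict(object$model, z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lv <- object$levels
  scores <- matrix(0, nrow(z), length(lv), dimnames = list(NULL, lv))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, j]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, j]
  }
  label <- factor(lv[max.col(scores, ties.method = "first")], levels = lv)
  list(label = label, scores = scores)
}

# Stratified fold assignment: within each class, a seeded shuffle followed by
# round-robin fold labels.
stratified_folds <- function(label, n_folds, seed) {
  folds <- integer(length(label))
  with_seed(seed, {
    for (l in levels(label)) {
      idx <- which(label == l)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

#' Stratified k-fold cross-validation with out-of-fold reporting
#'
#' Splits the data into seeded stratified folds, refits the feature
#' standardization inside each training fold (no leakage into the held-out
#' fold), trains the one-vs-one SVM, and aggregates out-of-fold predictions
#' into a confusion matrix, per-class TPR/FNR, overall accuracy and
#' one-vs-rest AUCs.
#'
#' @param fs A labeled `"feature_set"`.
#' @param cfg An [svm_config()]; `cfg$n_folds` must not exceed the minority
#'   class count.
#' @param fold_standardize Refit standardization per training fold (default
#'   `TRUE`); `FALSE` fits once on the full set, which leaks test-fold
#'   statistics and exists for diagnostic comparison.
#' @return Object of class `"eval_report"`: `confusion` (true rows x
#'   predicted columns), `tpr`, `fnr`, `accuracy_pct`, `auc` (per-class
#'   one-vs-rest), `macro_auc`, `folds`, `oof_label`, `oof_scores`.
#' @export
cross_validate <- function(fs, cfg = svm_config(), fold_standardize = TRUE) {
  stopifnot(inherits(fs, "feature_set"), inherits(cfg, "svm_config"))
  if (is.null(fs$label)) stop("cross-validation requires labels", call. = FALSE)
  lab <- droplevels(fs$label)
  if (cfg$n_folds > min(tabulate(lab)))
    stop("n_folds exceeds the minority class count", call. = FALSE)
  folds <- stratified_folds(lab, cfg$n_folds, cfg$seed)
  n <- nrow(fs$x)
  lv <- levels(lab)
  oof_label <- factor(rep(NA_character_, n), levels = lv)
  oof_scores <- matrix(NA_real_, n, length(lv), dimnames = list(NULL, lv))
  global_std <- fit_standardization(fs$x)
  for (k in seq_len(cfg$n_folds)) {
    tr <- folds != k
    fs_tr <- structure(list(x = fs$x[tr, , drop = FALSE], label = lab[tr],
                            std = if (fold_standardize) NULL else global_std),
                       class = "feature_set")
    art <- train_svm(fs_tr, cfg)
    pr <- predict(art, fs$x[!tr, , drop = FALSE])
    oof_label[!tr] <- pr$label
    oof_scores[!tr, ] <- pr$scores
  }
  confusion <- table(true = lab, predicted = oof_label)
  tpr <- diag(confusion) / rowSums(confusion)
  auc <- vapply(lv, function(l) auc_rank(oof_scores[, l], lab == l),
                numeric(1))
  structure(list(confusion = confusion, tpr = tpr, fnr = 1 - tpr,
                 accuracy_pct = 100 * sum(diag(confusion)) / n,
                 auc = auc, macro_auc = mean(auc), folds = folds,
                 oof_label = oof_label, oof_scores = oof_scores),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.1f%%, macro AUC %.3f\n",
              x$accuracy_pct, x$macro_auc))
  print(x$confusion)
  cat("TPR:", paste(sprintf("%s=%.3f", names(x$tpr), x$tpr), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-class one-vs-rest AUC from out-of-fold scores
#'
#' @param fs A labeled `"feature_set"`.
#' @param cfg An [svm_config()].
#' @return Named per-class AUC vector with attribute `macro` (their mean).
#' @export
roc_auc <- function(fs, cfg = svm_config()) {
  rep <- cross_validate(fs, cfg)
  structure(rep$auc, macro = rep$macro_auc)
}

#' Fraction of events flagged as carrying structural features
#'
#' The structural-feature class is the high-i_rms (mtDNA-like) class. With a
#' trained classifier the rate is the fraction of events assigned to that
#' class; with a plain threshold it is the fraction of events whose `i_rms`
#' exceeds it.
#'
#' @param events Feature input accepted by [predict.svm_artifact()], or a
#'   `data.frame` with `i_rms_nA` when `threshold` is used.
#' @param artifact Optional trained [train_svm()] artifact.
#' @param structural_class Label of the structural class (default `"mtDNA"`).
#' @param threshold Optional i_rms threshold, nA (used when no artifact).
#' @return Fraction in `[0, 1]`.
#' @export
structural_feature_rate <- function(events, artifact = NULL,
                                    structural_class = "mtDNA",
                                    threshold = NULL) {
  n <- if (inherits(events, "feature_set")) nrow(events$x) else nrow(events)
  if (is.null(n) || n == 0L) stop("no events", call. = FALSE)
  if (!is.null(artifact)) {
    pr <- predict(artifact, events)
    return(mean(pr$label == structural_class))
  }
  if (is.null(threshold))
    stop("provide a classifier artifact or an i_rms threshold", call. = FALSE)
  irms <- if (inherits(events, "feature_set")) events$x[, "i_rms"]
          else events$i_rms_nA
  mean(irms > threshold)
}
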