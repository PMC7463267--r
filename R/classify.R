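#' Fit a min-max feature scaler on training data
#'
#' Stores per-feature training min and max; [apply_scaler()] maps each
#' feature affinely onto `[-1, 1]`.  Features constant on the training data
#' map to 0 everywhere, including unseen test values.  Fit the scaler on
#' training rows only.
#'
#' @param train_matrix Numeric matrix with feature-id column names.
#' @return A `FeatureScaler` list with `min`, `max`, `feature_ids`.
#' @export
fit_scaler <- function(train_matrix) {
  if (!is.matrix(train_matrix) || nrow(train_matrix) == 0L)
    stop("cannot fit a scaler on an empty matrix", call. = FALSE)
  structure(list(min = apply(train_matrix, 2L, min),
                 max = apply(train_matrix, 2L, max),
                 feature_ids = colnames(train_matrix)),
            class = "FeatureScaler")
}

#' @rdname fit_scaler
#' @param params A `FeatureScaler` from [fit_scaler()].
#' @param matrix Matrix with the same columns (by name if named).
#' @return The scaled matrix.
#' @export
apply_scaler <- function(params, matrix) {
  stopifnot(inherits(params, "FeatureScaler"))
  if (!is.null(colnames(matrix)) && !is.null(params$feature_ids))
    matrix <- matrix[, params$feature_ids, drop = FALSE]
  rng <- params$max - params$min
  out <- sweep(matrix, 2L, params$min)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}

# Squared Euclidean distances between rows of A and rows of B.
sqdist <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

rbf_kernel <- function(A, B, gamma) exp(-gamma * sqdist(A, B))

# Train the K(K-1)/2 pairwise machines on a precomputed kernel.
# Convention: for the pair (a, b) with a before b in class_labels, label a
# is coded +1.
ovo_fit_kernel <- function(K, labels, C, class_labels) {
  machines <- list()
  for (ai in seq_len(length(class_labels) - 1L)) {
    for (bi in seq.int(ai + 1L, length(class_labels))) {
      idx <- which(labels %in% class_labels[c(ai, bi)])
      y <- ifelse(labels[idx] == class_labels[ai], 1, -1)
      fit <- smo_solve(K[idx, idx, drop = FALSE], y, C)
      machines[[length(machines) + 1L]] <-
        list(pos = class_labels[ai], neg = class_labels[bi],
             idx = idx, coef = fit$alpha * y, b = fit$b)
    }
  }
  machines
}

# Predict from pairwise machines given the cross-kernel rows(new) x cols(train).
# Vote ties: largest summed pairwise decision margin, then first in
# lexicographic label order.
ovo_predict_kernel <- function(machines, Kcross, class_labels) {
  m <- nrow(Kcross)
  votes <- matrix(0L, m, length(class_labels),
                  dimnames = list(NULL, class_labels))
  margin <- matrix(0, m, length(class_labels),
                   dimnames = list(NULL, class_labels))
  for (mc in machines) {
    d <- drop(Kcross[, mc$idx, drop = FALSE] %*% mc$coef) + mc$b
    pos <- d >= 0
    votes[, mc$pos] <- votes[, mc$pos] + pos
    votes[, mc$neg] <- votes[, mc$neg] + !pos
    margin[, mc$pos] <- margin[, mc$pos] + d
    margin[, mc$neg] <- margin[, mc$neg] - d
  }
  lex <- order(class_labels)
  vapply(seq_len(m), function(r) {
    tied <- which(votes[r, ] == max(votes[r, ]))
    if (length(tied) > 1L) {
      best <- tied[margin[r, tied] == max(margin[r, tied])]
      if (length(best) > 1L) best <- best[order(match(best, lex))][1]
      class_labels[best[1]]
    } else class_labels[tied]
  }, character(1))
}

stratified_folds <- function(labels, folds, seed) {
  withr::with_seed(seed, {
    fold_of <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_of
  })
}

#' Grid-tuned one-vs-one RBF-SVM fold classifier
#'
#' Searches the grid `(C, Gamma) = (2^a, 2^b)` for `a` in `c_exponents` and
#' `b` in `gamma_exponents` by stratified k-fold cross-validation and refits
#' on all data with the winning pair.  Min-max scaling — and, when
#' `selection` is supplied, information-gain band selection — are re-fit
#' inside each training fold so no test information leaks into them.  Grid
#' ties are broken toward smaller C, then smaller Gamma.
#'
#' @param data A [labeled_dataset()] with >= 2 classes.
#' @param c_exponents,gamma_exponents Integer vectors of base-2 exponents
#'   (the classical grid is -14..14).
#' @param folds Number of CV folds (default 10); reduced with a warning if
#'   some class has fewer members.
#' @param seed Integer seed controlling fold assignment.
#' @param selection `NULL` for no feature selection, or a list with
#'   `n_bins`, `band_fraction` and optionally `leaky = TRUE` to select once
#'   on the full dataset (mimics whole-dataset selection; default FALSE).
#' @return A `FoldModel` with the tuned machines, the scaler, the selected
#'   feature ids, and a `cv_table` data frame (`c_exp`, `gamma_exp`,
#'   `cv_accuracy`).
#' @export
grid_search_train <- function(data, c_exponents = -14:14,
                              gamma_exponents = -14:14, folds = 10L,
                              seed = 1L, selection = NULL) {
  stopifnot(inherits(data, "LabeledDataset"))
  class_labels <- unique(data$labels)
  if (length(class_labels) < 2L)
    stop("training needs at least 2 classes", call. = FALSE)
  if (length(c_exponents) == 0L || length(gamma_exponents) == 0L)
    stop("empty hyper-parameter grid", call. = FALSE)
  folds <- as.integer(folds)
  min_class <- min(table(data$labels))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    folds, min_class))
    folds <- max(2L, as.integer(min_class))
  }

  sel_cfg <- if (!is.null(selection))
    modifyList(list(n_bins = 10L, band_fraction = 0.5, leaky = FALSE),
               selection)
  leaky_keep <- NULL
  if (!is.null(sel_cfg) && isTRUE(sel_cfg$leaky)) {
    rk <- rank_and_select(data, sel_cfg$n_bins, sel_cfg$band_fraction)
    leaky_keep <- rk$feature_ids[rk$selected_mask]
  }

  fold_of <- stratified_folds(data$labels, folds, seed)
  acc <- array(NA_real_,
               dim = c(folds, length(c_exponents), length(gamma_exponents)))
  for (f in seq_len(folds)) {
    tr <- fold_of != f; te <- !tr
    keep <- colnames(data$matrix)
    if (!is.null(sel_cfg)) {
      keep <- if (!is.null(leaky_keep)) leaky_keep else {
        sub <- labeled_dataset(data$matrix[tr, , drop = FALSE],
                               data$protein_ids[tr], data$labels[tr])
        rk <- rank_and_select(sub, sel_cfg$n_bins, sel_cfg$band_fraction)
        rk$feature_ids[rk$selected_mask]
      }
    }
    sc <- fit_scaler(data$matrix[tr, keep, drop = FALSE])
    Xtr <- apply_scaler(sc, data$matrix[tr, keep, drop = FALSE])
    Xte <- apply_scaler(sc, data$matrix[te, keep, drop = FALSE])
    Dtr <- sqdist(Xtr, Xtr); Dte <- sqdist(Xte, Xtr)
    ytr <- data$labels[tr]; yte <- data$labels[te]
    for (gi in seq_along(gamma_exponents)) {
      g <- 2^gamma_exponents[gi]
      Ktr <- exp(-g * Dtr); Kte <- exp(-g * Dte)
      for (ci in seq_along(c_exponents)) {
        machines <- ovo_fit_kernel(Ktr, ytr, 2^c_exponents[ci], class_labels)
        pred <- ovo_predict_kernel(machines, Kte, class_labels)
        acc[f, ci, gi] <- mean(pred == yte)
      }
    }
  }
  mean_acc <- apply(acc, c(2, 3), mean)
  cv_table <- data.frame(
    c_exp = rep(c_exponents, times = length(gamma_exponents)),
    gamma_exp = rep(gamma_exponents, each = length(c_exponents)),
    cv_accuracy = as.vector(mean_acc))
  # best pair; ties -> smaller C then smaller Gamma
  ord <- order(-cv_table$cv_accuracy, cv_table$c_exp, cv_table$gamma_exp)
  best <- cv_table[ord[1L], ]

  keep <- colnames(data$matrix)
  ranking <- NULL
  if (!is.null(sel_cfg)) {
    ranking <- rank_and_select(data, sel_cfg$n_bins, sel_cfg$band_fraction)
    keep <- ranking$feature_ids[ranking$selected_mask]
  }
  sc <- fit_scaler(data$matrix[, keep, drop = FALSE])
  X <- apply_scaler(sc, data$matrix[, keep, drop = FALSE])
  K <- rbf_kernel(X, X, 2^best$gamma_exp)
  machines <- ovo_fit_kernel(K, data$labels, 2^best$c_exp, class_labels)

  structure(list(selected_feature_ids = keep,
                 scaler = sc,
                 C = 2^best$c_exp, gamma = 2^best$gamma_exp,
                 c_exp = best$c_exp, gamma_exp = best$gamma_exp,
                 class_labels = class_labels,
                 machines = machines,
                 train_X = X,
                 cv_accuracy = best$cv_accuracy,
                 cv_table = cv_table,
                 ranking = ranking,
                 meta = list(seed = seed, folds = folds,
                             c_exponents = c_exponents,
                             gamma_exponents = gamma_exponents,
                             selection = sel_cfg)),
            class = "FoldModel")
}

#' @export
print.FoldModel <- function(x, ...) {
  cat(sprintf(
    "FoldModel: %d classes, %d features, C = 2^%d, gamma = 2^%d, CV accuracy %.3f\n",
    length(x$class_labels), length(x$selected_feature_ids),
    x$c_exp, x$gamma_exp, x$cv_accuracy))
  invisible(x)
}

#' Predict fold labels
#'
#' One-vs-one majority vote across the pairwise machines; vote ties are
#' broken by the tied class with the largest summed pairwise decision
#' margin, then by lexicographic label order.
#'
#' @param object A `FoldModel`.
#' @param newdata A [labeled_dataset()], `FeatureVector`, or numeric matrix
#'   whose columns (by name) include all selected features.
#' @param ... Unused.
#' @return Character vector of predicted fold labels.
#' @export
predict.FoldModel <- function(object, newdata, ...) {
  if (inherits(newdata, "LabeledDataset")) newdata <- newdata$matrix
  if (inherits(newdata, "FeatureVector"))
    newdata <- matrix(newdata$values, 1L,
                      dimnames = list(NULL, newdata$feature_ids))
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$selected_feature_ids, colnames(newdata))
  if (length(missing))
    stop("input lacks selected features: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
         call. = FALSE)
  X <- apply_scaler(object$scaler,
                    newdata[, object$selected_feature_ids, drop = FALSE])
  Kc <- rbf_kernel(X, object$train_X, object$gamma)
  ovo_predict_kernel(object$machines, Kc, object$class_labels)
}

#' Per-class evaluation of fold predictions
#'
#' Builds the K x K confusion matrix (rows = truth, columns = prediction)
#' and per-class one-vs-rest sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)` and `F1 = 2TP/(2TP+FP+FN)`, all as fractions in `[0, 1]`,
#' plus their macro averages and the overall accuracy.  A class absent from
#' the truth has undefined sensitivity; it is reported as 0 and flagged in
#' `undefined_classes`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_labels Label universe (defaults to the union, in
#'   first-appearance order of the truth then predictions).
#' @return An `EvaluationReport` list: `confusion_matrix`, `per_class`
#'   (data frame), `macro_sensitivity`, `macro_precision`, `macro_f1`,
#'   `accuracy`, `undefined_classes`.
#' @export
evaluate <- function(true_labels, predicted_labels, class_labels = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (is.null(class_labels))
    class_labels <- unique(c(true_labels, predicted_labels))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_labels)
  if (length(bad))
    stop("labels outside class_labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(true_labels, levels = class_labels)
  pf <- factor(predicted_labels, levels = class_labels)
  cm <- table(true = tf, predicted = pf)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  structure(list(confusion_matrix = unclass(cm),
                 per_class = data.frame(class = class_labels,
                                        sensitivity = unname(sens),
                                        precision = unname(prec),
                                        f1 = unname(f1),
                                        support = unname(rowSums(cm))),
                 macro_sensitivity = mean(sens),
                 macro_precision = mean(prec),
                 macro_f1 = mean(f1),
                 accuracy = sum(tp) / length(true_labels),
                 undefined_classes = class_labels[rowSums(cm) == 0]),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: accuracy %.4f (%.1f%%)\n",
              x$accuracy, 100 * x$accuracy))
  cat(sprintf("macro: sensitivity %.4f, precision %.4f, F1 %.4f\n",
              x$macro_sensitivity, x$macro_precision, x$macro_f1))
  print(x$confusion_matrix)
  invisible(x)
}

#' Save / load a fold model as a portable JSON archive
#'
#' The archive directory holds `model.json` (feature ids, scaler, C, Gamma,
#' class labels, machines, scaled training matrix, metadata) and
#' `manifest.json` with an md5 of the payload, verified on load.
#'
#' @param model A `FoldModel`.
#' @param dir Archive directory (created if needed).
#' @return `dir` (write) or the restored `FoldModel` (read).
#' @export
write_fold_model <- function(model, dir) {
  stopifnot(inherits(model, "FoldModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    selected_feature_ids = model$selected_feature_ids,
    scaler = list(min = unname(model$scaler$min),
                  max = unname(model$scaler$max),
                  feature_ids = model$scaler$feature_ids),
    c_exp = model$c_exp, gamma_exp = model$gamma_exp,
    class_labels = model$class_labels,
    machines = lapply(model$machines, function(m)
      list(pos = m$pos, neg = m$neg, idx = m$idx, coef = m$coef, b = m$b)),
    train_X = apply(model$train_X, 1L, identity, simplify = FALSE),
    cv_accuracy = model$cv_accuracy,
    meta = model$meta)
  mp <- file.path(dir, "model.json")
  jsonlite::write_json(payload, mp, digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(format = "pssmfold-model", version = 1L,
                            md5 = unname(tools::md5sum(mp))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_fold_model
#' @export
read_fold_model <- function(dir) {
  mp <- file.path(dir, "model.json")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(unname(tools::md5sum(mp))[[1]], man$md5))
    stop("model archive corrupted: manifest md5 mismatch", call. = FALSE)
  pl <- jsonlite::read_json(mp, simplifyVector = TRUE)
  X <- if (is.matrix(pl$train_X)) pl$train_X else do.call(rbind, pl$train_X)
  colnames(X) <- pl$selected_feature_ids
  scaler <- structure(list(min = stats::setNames(pl$scaler$min, pl$scaler$feature_ids),
                           max = stats::setNames(pl$scaler$max, pl$scaler$feature_ids),
                           feature_ids = pl$scaler$feature_ids),
                      class = "FeatureScaler")
  machines <- if (is.data.frame(pl$machines)) {
    lapply(seq_len(nrow(pl$machines)), function(i)
      list(pos = pl$machines$pos[i], neg = pl$machines$neg[i],
           idx = pl$machines$idx[[i]], coef = pl$machines$coef[[i]],
           b = pl$machines$b[i]))
  } else pl$machines
  structure(list(selected_feature_ids = pl$selected_feature_ids,
                 scaler = scaler,
                 C = 2^pl$c_exp, gamma = 2^pl$gamma_exp,
                 c_exp = pl$c_exp, gamma_exp = pl$gamma_exp,
                 class_labels = pl$class_labels,
                 machines = machines,
                 train_X = X,
                 cv_accuracy = pl$cv_accuracy,
                 cv_table = NULL, ranking = NULL,
                 meta = pl$meta),
            class = "FoldModel")
}
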