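#' Feature extraction configuration
#'
#' @param LG Largest lag of the auto-cross-covariance transform (default 4).
#' @param k Dimer separation for the separated-dimer transform (default 4).
#' @param normalization Score normalization applied before extraction, see
#'   [normalize_profile()].
#' @return A `FeatureConfig` list.
#' @export
feature_config <- function(LG = 4L, k = 4L,
                           normalization = c("raw", "sigmoid")) {
  LG <- as.integer(LG); k <- as.integer(k)
  stopifnot(length(LG) == 1L, LG >= 1L, length(k) == 1L, k >= 1L)
  structure(list(LG = LG, k = k, normalization = match.arg(normalization)),
            class = "FeatureConfig")
}

new_feature_vector <- function(values, feature_ids, source_protein) {
  stopifnot(length(values) == length(feature_ids))
  if (!all(is.finite(values)))
    stop(sprintf("non-finite feature values for protein '%s'", source_protein),
         call. = FALSE)
  structure(list(values = as.numeric(values),
                 feature_ids = feature_ids,
                 source_protein = source_protein),
            class = "FeatureVector")
}

#' @export
print.FeatureVector <- function(x, ...) {
  cat(sprintf("FeatureVector of '%s': %d features (%s ... %s)\n",
              x$source_protein, length(x$values),
              x$feature_ids[1], x$feature_ids[length(x$feature_ids)]))
  invisible(x)
}

check_length <- function(p, lag, what) {
  L <- nrow(p$scores)
  if (L <= lag)
    stop(sprintf("protein '%s' has length %d, need L > %s = %d",
                 p$protein_id, L, what, lag), call. = FALSE)
  L
}

# Ordered (i1, i2) pairs of distinct columns, i1-major.
cc_pairs <- function() {
  i1 <- rep(1:20, each = 19L)
  i2 <- unlist(lapply(1:20, function(i) setdiff(1:20, i)), use.names = FALSE)
  cbind(i1, i2)
}

#' Auto-covariance (AC) features
#'
#' For each amino-acid column i and lag lg in 1..LG,
#' `AC(i, lg) = sum_{j=1}^{L-lg} (P[j,i] - mean_i) (P[j+lg,i] - mean_i) / (L - lg)`
#' where `mean_i` is the column mean over all L positions.  Output is
#' lag-major: all 20 columns at lag 1, then lag 2, ...; 20*LG values.
#'
#' @param p A `PSSMProfile` with L > LG.
#' @param LG Largest lag.
#' @return A `FeatureVector` of length `20 * LG` with ids `AC:<aa>:lg=<lg>`.
#' @export
ac_features <- function(p, LG = 4L) {
  stopifnot(inherits(p, "PSSMProfile"))
  LG <- as.integer(LG)
  L <- check_length(p, LG, "LG")
  Xc <- sweep(p$scores, 2L, colMeans(p$scores))
  vals <- numeric(0); ids <- character(0)
  for (lg in seq_len(LG)) {
    v <- colSums(Xc[seq_len(L - lg), , drop = FALSE] *
                 Xc[seq.int(1L + lg, L), , drop = FALSE]) / (L - lg)
    vals <- c(vals, v)
    ids <- c(ids, sprintf("AC:%s:lg=%d", PSSM_ALPHABET, lg))
  }
  new_feature_vector(vals, ids, p$protein_id)
}

#' Cross-covariance (CC) features
#'
#' For each ordered pair of distinct columns (i1, i2) and lag lg,
#' `CC(i1, i2, lg) = sum_{j=1}^{L-lg} (P[j,i1] - mean_i1) (P[j+lg,i2] - mean_i2) / (L - lg)`.
#' Both orderings are emitted (CC is not symmetric).  Output is lag-major,
#' pairs in (i1, i2) lexicographic order; 380*LG values.
#'
#' @inheritParams ac_features
#' @return A `FeatureVector` of length `380 * LG`,
#'   ids `CC:<aa1>:<aa2>:lg=<lg>`.
#' @export
cc_features <- function(p, LG = 4L) {
  stopifnot(inherits(p, "PSSMProfile"))
  LG <- as.integer(LG)
  L <- check_length(p, LG, "LG")
  Xc <- sweep(p$scores, 2L, colMeans(p$scores))
  pr <- cc_pairs()
  vals <- numeric(0); ids <- character(0)
  for (lg in seq_len(LG)) {
    M <- crossprod(Xc[seq_len(L - lg), , drop = FALSE],
                   Xc[seq.int(1L + lg, L), , drop = FALSE]) / (L - lg)
    vals <- c(vals, M[pr])
    ids <- c(ids, sprintf("CC:%s:%s:lg=%d",
                          PSSM_ALPHABET[pr[, 1]], PSSM_ALPHABET[pr[, 2]], lg))
  }
  new_feature_vector(vals, ids, p$protein_id)
}

#' Auto-cross-covariance (ACC) features
#'
#' Concatenation of the AC block then the CC block: `400 * LG` values
#' (1600 at the default LG = 4).
#'
#' @inheritParams ac_features
#' @return A `FeatureVector` of length `400 * LG`.
#' @export
acc_features <- function(p, LG = 4L) {
  a <- ac_features(p, LG); cc <- cc_features(p, LG)
  new_feature_vector(c(a$values, cc$values),
                     c(a$feature_ids, cc$feature_ids), p$protein_id)
}

#' Separated-dimer (SD) features
#'
#' For every ordered amino-acid pair (m, n),
#' `F[m, n](k) = sum_{i=1}^{L-k} P[i, m] * P[i+k, n]`: the score-weighted
#' propensity of the dimer (m, n) at sequence separation k.  The 400 values
#' are m-major: F(1,1), F(1,2), ..., F(20,20).
#'
#' @param p A `PSSMProfile` with L > k.
#' @param k Dimer separation.
#' @return A `FeatureVector` of length 400 with ids `SD:<aa1>:<aa2>:k=<k>`.
#' @export
sd_features <- function(p, k = 4L) {
  stopifnot(inherits(p, "PSSMProfile"))
  k <- as.integer(k)
  L <- check_length(p, k, "k")
  X <- p$scores
  M <- crossprod(X[seq_len(L - k), , drop = FALSE],
                 X[seq.int(1L + k, L), , drop = FALSE])
  idx <- cbind(rep(1:20, each = 20L), rep(1:20, times = 20L))
  new_feature_vector(M[idx],
                     sprintf("SD:%s:%s:k=%d",
                             PSSM_ALPHABET[idx[, 1]], PSSM_ALPHABET[idx[, 2]], k),
                     p$protein_id)
}

#' Fuse ACC and SD feature vectors
#'
#' Concatenates the ACC block then the SD block of the same protein
#' (default lengths 1600 + 400 = 2000); feature identifiers are preserved.
#'
#' @param acc,sd `FeatureVector`s from the same protein.
#' @return A `FeatureVector`.
#' @export
fuse <- function(acc, sd) {
  stopifnot(inherits(acc, "FeatureVector"), inherits(sd, "FeatureVector"))
  if (!identical(acc$source_protein, sd$source_protein))
    stop(sprintf("cannot fuse vectors from different proteins ('%s' vs '%s')",
                 acc$source_protein, sd$source_protein), call. = FALSE)
  new_feature_vector(c(acc$values, sd$values),
                     c(acc$feature_ids, sd$feature_ids), acc$source_protein)
}

#' Extract the fused feature vector of one profile
#'
#' @param p A `PSSMProfile`.
#' @param cfg A [feature_config()].
#' @param blocks Which feature blocks to emit: `"fused"` (default),
#'   `"acc"`, or `"sd"`.
#' @return A `FeatureVector`.
#' @export
extract_features <- function(p, cfg = feature_config(),
                             blocks = c("fused", "acc", "sd")) {
  blocks <- match.arg(blocks)
  p <- normalize_profile(p, cfg$normalization)
  switch(blocks,
         acc = acc_features(p, cfg$LG),
         sd = sd_features(p, cfg$k),
         fused = fuse(acc_features(p, cfg$LG), sd_features(p, cfg$k)))
}

#' Labeled feature dataset
#'
#' @param matrix Numeric N x D matrix, column names = feature ids.
#' @param protein_ids Length-N character vector.
#' @param labels Length-N fold labels.
#' @return A `LabeledDataset` list with fields `matrix`, `protein_ids`,
#'   `labels`, `feature_ids`.
#' @export
labeled_dataset <- function(matrix, protein_ids, labels) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(protein_ids),
            nrow(matrix) == length(labels), !is.null(colnames(matrix)))
  if (!all(is.finite(matrix)))
    stop("feature matrix contains non-finite entries", call. = FALSE)
  structure(list(matrix = matrix,
                 protein_ids = as.character(protein_ids),
                 labels = as.character(labels),
                 feature_ids = colnames(matrix)),
            class = "LabeledDataset")
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d proteins x %d features, %d folds\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$labels))))
  invisible(x)
}

#' Build the feature matrix of a profile collection
#'
#' Fails fast if any profile is too short for the configured lags, listing
#' every offending id (silent zero-padding would poison the information-gain
#' ranking downstream).
#'
#' @param profiles List of `PSSMProfile`s.
#' @param labels Fold labels, parallel to `profiles`.
#' @param cfg A [feature_config()].
#' @param blocks Passed to [extract_features()].
#' @return A [labeled_dataset()] with rows in input order.
#' @export
build_feature_matrix <- function(profiles, labels, cfg = feature_config(),
                                 blocks = "fused") {
  stopifnot(length(profiles) == length(labels), length(profiles) >= 1L)
  min_len <- switch(blocks, acc = cfg$LG, sd = cfg$k, max(cfg$LG, cfg$k))
  lens <- vapply(profiles, function(p) nrow(p$scores), integer(1))
  short <- lens <= min_len
  if (any(short))
    stop("profiles too short for feature extraction (need L > ", min_len,
         "): ", paste(vapply(profiles[short], `[[`, "", "protein_id"),
                      collapse = ", "), call. = FALSE)
  fvs <- lapply(profiles, extract_features, cfg = cfg, blocks = blocks)
  M <- do.call(rbind, lapply(fvs, `[[`, "values"))
  colnames(M) <- fvs[[1]]$feature_ids
  labeled_dataset(M, vapply(profiles, `[[`, "", "protein_id"), labels)
}
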