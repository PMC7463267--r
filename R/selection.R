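#' Shannon entropy of a discrete sequence
#'
#' `I(X) = -sum_i P(x_i) log2 P(x_i)` with empirical probabilities and the
#' convention 0 * log 0 = 0.
#'
#' @param x Non-empty discrete sequence (any atomic type).
#' @return Entropy in bits.
#' @export
entropy <- function(x) {
  if (length(x) == 0L) stop("entropy of an empty sequence", call. = FALSE)
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Conditional entropy I(X | Y)
#'
#' `I(X|Y) = -sum_j P(y_j) sum_i P(x_i|y_j) log2 P(x_i|y_j)` with empirical
#' probabilities.
#'
#' @param x,y Discrete sequences of equal length.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("conditional entropy of empty sequences",
                            call. = FALSE)
  yf <- factor(y)
  w <- tabulate(as.integer(yf)) / length(y)
  hx <- vapply(split(x, yf), entropy, numeric(1))
  sum(w * hx)
}

#' Information gain IG(X | Y)
#'
#' `IG(X|Y) = I(X) - I(X|Y)`: the mutual information between X and Y in
#' bits.  Values within 1e-12 below zero (floating-point cancellation) are
#' clipped to 0.
#'
#' @inheritParams conditional_entropy
#' @return Information gain in bits, >= 0.
#' @export
information_gain <- function(x, y) {
  ig <- entropy(x) - conditional_entropy(x, y)
  if (ig < 0 && ig > -1e-12) ig <- 0
  ig
}

#' Equal-width discretization
#'
#' Bins real values into `n_bins` equal-width intervals over
#' `[min(values), max(values)]`; intervals are right-closed and the lowest
#' is closed on both ends, so the maximum lands in the top bin.  A constant
#' feature collapses to a single bin (and hence carries zero information
#' gain downstream).
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins, >= 2.
#' @return Integer bin codes in 1..n_bins.
#' @export
discretize <- function(values, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  if (!all(is.finite(values)))
    stop("cannot discretize non-finite values", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  # right-closed intervals; the lowest is closed on both ends
  b <- cut(values, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
           include.lowest = TRUE, right = TRUE, labels = FALSE)
  as.integer(b)
}

#' Rank features by information gain and band-select
#'
#' Each feature column is discretized ([discretize()]) and scored by its
#' information gain against the fold labels.  Features whose score falls in
#' the closed band `[band_fraction * max_IG, max_IG]` are selected; ties at
#' the lower edge are included, and the maximum always qualifies.
#'
#' @param data A [labeled_dataset()] with at least two distinct labels.
#' @param n_bins Bins for discretization (default 10).
#' @param band_fraction Lower edge of the selection band as a fraction of
#'   the maximum score (default 0.5).
#' @return An `IGRanking`: list with `ig_scores` (named, bits),
#'   `selected_mask`, `band` = c(lower, upper), `n_bins`, `feature_ids`.
#' @export
rank_and_select <- function(data, n_bins = 10L, band_fraction = 0.5) {
  stopifnot(inherits(data, "LabeledDataset"))
  if (length(unique(data$labels)) < 2L)
    stop("information-gain selection needs at least 2 classes", call. = FALSE)
  stopifnot(band_fraction >= 0, band_fraction <= 1)
  y <- factor(data$labels)
  ig <- apply(data$matrix, 2L, function(col)
    information_gain(discretize(col, n_bins), y))
  names(ig) <- data$feature_ids
  lower <- band_fraction * max(ig)
  mask <- ig >= lower
  structure(list(ig_scores = ig,
                 selected_mask = mask,
                 band = c(lower = lower, upper = max(ig)),
                 n_bins = n_bins,
                 feature_ids = data$feature_ids),
            class = "IGRanking")
}

#' @export
print.IGRanking <- function(x, ...) {
  cat(sprintf("IGRanking: %d features, max IG %.4f bits, band [%.4f, %.4f], %d selected\n",
              length(x$ig_scores), x$band[["upper"]], x$band[["lower"]],
              x$band[["upper"]], sum(x$selected_mask)))
  invisible(x)
}

#' Keep only the selected feature columns
#'
#' @param data A [labeled_dataset()].
#' @param ranking An `IGRanking` from [rank_and_select()].
#' @return A reduced [labeled_dataset()].
#' @export
apply_selection <- function(data, ranking) {
  stopifnot(inherits(data, "LabeledDataset"), inherits(ranking, "IGRanking"))
  keep <- ranking$feature_ids[ranking$selected_mask]
  missing <- setdiff(keep, data$feature_ids)
  if (length(missing))
    stop("dataset lacks selected features: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  labeled_dataset(data$matrix[, keep, drop = FALSE],
                  data$protein_ids, data$labels)
}

#' Write a ranking as TSV (feature_id, ig_bits, selected), descending IG
#' @param ranking An `IGRanking`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  ord <- order(ranking$ig_scores, decreasing = TRUE)
  df <- data.frame(feature_id = ranking$feature_ids[ord],
                   ig_bits = unname(ranking$ig_scores[ord]),
                   selected = unname(ranking$selected_mask[ord]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
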