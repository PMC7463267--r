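#' Specification of a synthetic labeled PSSM dataset
#'
#' Describes a dataset of L x 20 score matrices whose classes differ in two
#' orthogonal ways, mirroring what the two feature families detect:
#'
#' * **lagged autocorrelation structure** — each class marks a few
#'   signature columns that follow an AR(1) process along the sequence, so
#'   their lagged auto/cross-covariances (the ACC block) deviate from the
#'   white-noise background.  Because ACC is mean-centered this signal is
#'   invisible to column means.
#' * **dimer coupling** — each class carries a signed mean offset pattern
#'   on a few (m, n) column pairs, which shifts the raw lag-k products that
#'   the SD block sums.  Because pure column-mean shifts cancel in the
#'   mean-centered ACC transform, this signal is (to first order) visible
#'   only to SD.
#'
#' Separation presets map to documented effect sizes
#' (AR(1) coefficient rho, mean-offset c in score units):
#' `low` rho = 0, c = 0 (pure noise); `medium` rho = 0.45, c = 1;
#' `high` rho = 0.7, c = 2.
#'
#' @param n_classes Number of folds (>= 2).
#' @param n_per_class Proteins per fold.
#' @param length_range Inclusive integer range of sequence lengths; default
#'   50-150, typical of single protein domains.
#' @param separation `"low"`, `"medium"` or `"high"`.
#' @param noise_sd Standard deviation of the per-entry score noise, in
#'   log-odds units (default 2, about the spread of real PSSM columns).
#' @param acc_signal,sd_signal Logical switches to zero out one signal
#'   family (for complementarity experiments).
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_classes = 3L, n_per_class = 40L,
                           length_range = c(50L, 150L),
                           separation = c("high", "medium", "low"),
                           noise_sd = 2, acc_signal = TRUE, sd_signal = TRUE,
                           seed = 1L) {
  separation <- match.arg(separation)
  stopifnot(n_classes >= 2L, n_per_class >= 1L,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            noise_sd > 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 separation = separation, noise_sd = noise_sd,
                 acc_signal = isTRUE(acc_signal),
                 sd_signal = isTRUE(sd_signal),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

separation_effects <- function(separation) {
  switch(separation,
         low = list(rho = 0, shift = 0),
         medium = list(rho = 0.45, shift = 1),
         high = list(rho = 0.7, shift = 2))
}

#' Generate a labeled synthetic PSSM dataset
#'
#' Scores are built as background Gaussian noise (mean -1, sd `noise_sd`)
#' plus the class signals described in [synthetic_spec()], then rounded to
#' integers and clamped to the typical PSI-BLAST log-odds range
#' `[-10, 12]`.  Sequences are i.i.d. letters — they only satisfy the file
#' formats; every feature formula reads the score matrix alone.
#'
#' @param spec A [synthetic_spec()].
#' @param cfg A [feature_config()]; used to check `L_min > max(LG, k)` and
#'   to place the dimer coupling at separation `k`.
#' @return List with `profiles` (list of `PSSMProfile`), `labels`
#'   (character, `fold01`...), and `spec`.
#' @export
generate_dataset <- function(spec, cfg = feature_config()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$length_range[1] <= max(cfg$LG, cfg$k))
    stop(sprintf("L_min = %d must exceed max(LG, k) = %d",
                 spec$length_range[1], max(cfg$LG, cfg$k)), call. = FALSE)
  eff <- separation_effects(spec$separation)
  k <- cfg$k
  n_sig_cols <- 6L; n_pairs <- 5L

  withr::with_seed(spec$seed, {
    classes <- lapply(seq_len(spec$n_classes), function(ci) {
      list(acc_cols = sample(20L, n_sig_cols),
           rho = if (spec$acc_signal) eff$rho * runif(n_sig_cols, 0.7, 1) else
             numeric(n_sig_cols),
           pair_m = sample(20L, n_pairs),
           pair_n = sample(20L, n_pairs),
           pair_sign = sample(c(-1, 1), n_pairs, replace = TRUE))
    })
    profiles <- vector("list", spec$n_classes * spec$n_per_class)
    labels <- character(length(profiles))
    idx <- 0L
    for (ci in seq_len(spec$n_classes)) {
      cl <- classes[[ci]]
      for (pi in seq_len(spec$n_per_class)) {
        idx <- idx + 1L
        L <- sample(seq.int(spec$length_range[1], spec$length_range[2]), 1L)
        X <- matrix(rnorm(L * 20L, mean = -1, sd = spec$noise_sd), L, 20L)
        if (spec$acc_signal && eff$rho > 0) {
          for (s in seq_len(n_sig_cols)) {
            j <- cl$acc_cols[s]; rho <- cl$rho[s]
            e <- rnorm(L, sd = spec$noise_sd * sqrt(1 - rho^2))
            x <- numeric(L); x[1] <- rnorm(1, sd = spec$noise_sd)
            for (t in 2:L) x[t] <- rho * x[t - 1] + e[t]
            X[, j] <- -1 + x
          }
        }
        if (spec$sd_signal && eff$shift > 0) {
          for (s in seq_len(n_pairs)) {
            X[, cl$pair_m[s]] <- X[, cl$pair_m[s]] + eff$shift
            X[, cl$pair_n[s]] <- X[, cl$pair_n[s]] +
              cl$pair_sign[s] * eff$shift
          }
        }
        X <- pmin(pmax(round(X), -10), 12)
        colnames(X) <- PSSM_ALPHABET
        seq_letters <- paste(sample(PSSM_ALPHABET, L, replace = TRUE),
                             collapse = "")
        lab <- sprintf("fold%02d", ci)
        profiles[[idx]] <- new_pssm_profile(
          sprintf("syn_%s_p%03d", lab, pi), seq_letters, X)
        labels[idx] <- lab
      }
    }
    list(profiles = profiles, labels = labels, spec = spec)
  })
}

#' Write a synthetic dataset as on-disk fixtures
#'
#' Emits exactly the three formats the readers consume: one ASCII PSSM per
#' protein (`<id>.pssm`, parseable by [parse_pssm()]), one FASTA of the
#' sequences (`sequences.fasta`) and a headerless label TSV (`labels.tsv`).
#'
#' @param profiles List of `PSSMProfile`s.
#' @param labels Parallel fold labels.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(profiles, labels, directory) {
  stopifnot(length(profiles) == length(labels))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  ids <- vapply(profiles, `[[`, "", "protein_id")
  for (p in profiles)
    writeLines(format_pssm(p), file.path(directory,
                                         paste0(p$protein_id, ".pssm")))
  fasta <- unlist(lapply(profiles, function(p)
    c(paste0(">", p$protein_id), p$sequence)))
  writeLines(fasta, file.path(directory, "sequences.fasta"))
  write.table(data.frame(ids, labels), file.path(directory, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(directory)
}
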