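#' PSSM profile container
#'
#' Bundles one protein's sequence with its L x 20 position-specific scoring
#' matrix (log-odds substitution scores, one row per residue, one column per
#' amino acid in the canonical PSI-BLAST order `A R N D C Q E G H I L K M F
#' P S T W Y V`).
#'
#' @param protein_id Character scalar identifying the protein.
#' @param sequence Amino-acid string of length L (single-letter codes;
#'   non-standard letters such as `X` are allowed).
#' @param scores Numeric L x 20 matrix of per-position substitution scores.
#'   Columns must be named with the 20 standard amino acids; they are
#'   reordered to the canonical order on construction.
#' @return An object of class `PSSMProfile`: a list with elements
#'   `protein_id`, `sequence`, `scores` and `column_order`.
#' @examples
#' m <- matrix(0, 3, 20, dimnames = list(NULL, pssm_alphabet()))
#' new_pssm_profile("toy", "ACD", m)
#' @export
new_pssm_profile <- function(protein_id, sequence, scores) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.matrix(scores) || ncol(scores) != 20L)
    stop("'scores' must be a matrix with exactly 20 columns", call. = FALSE)
  L <- nchar(sequence)
  if (L < 1L || nrow(scores) != L)
    stop(sprintf("profile '%s': %d score rows but sequence length %d",
                 protein_id, nrow(scores), L), call. = FALSE)
  cn <- colnames(scores)
  if (is.null(cn)) {
    colnames(scores) <- PSSM_ALPHABET
  } else {
    if (!setequal(cn, PSSM_ALPHABET))
      stop("score columns must be named with the 20 standard amino acids",
           call. = FALSE)
    scores <- scores[, PSSM_ALPHABET, drop = FALSE]
  }
  storage.mode(scores) <- "double"
  if (!all(is.finite(scores)))
    stop(sprintf("profile '%s': non-finite score entries", protein_id),
         call. = FALSE)
  structure(list(protein_id = protein_id,
                 sequence = sequence,
                 scores = scores,
                 column_order = PSSM_ALPHABET),
            class = "PSSMProfile")
}

#' Canonical PSSM amino-acid column order
#'
#' @return The 20 one-letter amino-acid codes in the order used by the
#'   PSI-BLAST ASCII PSSM header (and by all feature blocks in this package).
#' @export
pssm_alphabet <- function() PSSM_ALPHABET

#' @export
print.PSSMProfile <- function(x, ...) {
  cat(sprintf("PSSMProfile '%s': L = %d residues, 20 score columns\n",
              x$protein_id, nrow(x$scores)))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the text written by `psiblast -out_ascii_pssm`.  Only the first
#' block of 20 numeric columns (the log-odds scores) is kept; the
#' weighted-percentage block and the trailing per-row statistics are
#' ignored.  The amino-acid column order is taken from the header line and
#' the matrix is reordered to the canonical order, so dialects that permute
#' columns parse correctly.
#'
#' @param text Either a path to a PSSM file or the file content as a
#'   character vector (one element per line, or a single string with
#'   embedded newlines).
#' @param protein_id Identifier stored in the profile; defaults to the file
#'   base name when `text` is a path, otherwise `"pssm"`.
#' @return A [new_pssm_profile()] object.
#' @examples
#' p <- generate_dataset(synthetic_spec(n_classes = 2, n_per_class = 1,
#'                                      seed = 1))$profiles[[1]]
#' txt <- format_pssm(p)
#' identical(parse_pssm(txt, p$protein_id)$scores, p$scores)
#' @export
parse_pssm <- function(text, protein_id = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    if (is.null(protein_id))
      protein_id <- sub("\\.[^.]*$", "", basename(text))
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(protein_id)) protein_id <- "pssm"

  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  is_letter <- function(v) grepl("^[A-Z]$", v)

  # Header: the first line made solely of >= 20 single letters.
  header_at <- which(vapply(toks, function(tk)
    length(tk) >= 20L && all(is_letter(tk)), logical(1)))[1]
  if (is.na(header_at))
    stop("not a PSI-BLAST ASCII PSSM: no amino-acid header line found",
         call. = FALSE)
  file_order <- toks[[header_at]][1:20]
  if (!setequal(file_order, PSSM_ALPHABET))
    stop("PSSM header does not list the 20 standard amino acids",
         call. = FALSE)

  rows <- list(); letters_seen <- character(0)
  for (ln in seq_len(length(lines) - header_at) + header_at) {
    tk <- toks[[ln]]
    if (length(tk) == 0L || identical(tk, "")) break
    if (!grepl("^[0-9]+$", tk[1])) break          # footer statistics
    if (length(tk) < 22L || !is_letter(tk[2]))
      stop(sprintf("malformed PSSM row at line %d: expected index, residue and 20 scores",
                   ln), call. = FALSE)
    sc <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(sc))
      stop(sprintf("malformed PSSM row at line %d: non-numeric score", ln),
           call. = FALSE)
    rows[[length(rows) + 1L]] <- sc
    letters_seen <- c(letters_seen, tk[2])
  }
  if (length(rows) == 0L)
    stop("empty PSSM: header present but no residue rows", call. = FALSE)

  scores <- do.call(rbind, rows)
  colnames(scores) <- file_order
  new_pssm_profile(protein_id, paste(letters_seen, collapse = ""), scores)
}

#' Format a profile as PSI-BLAST ASCII PSSM text
#'
#' Writes the same dialect [parse_pssm()] reads (header, indexed residue
#' rows with 20 log-odds columns followed by a dummy percentage block, then
#' footer), so write/parse round-trips exactly for integer scores.
#'
#' @param p A `PSSMProfile`.
#' @return A single string of PSSM text.
#' @export
format_pssm <- function(p) {
  stopifnot(inherits(p, "PSSMProfile"))
  L <- nrow(p$scores)
  head1 <- ""
  head2 <- "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"
  head3 <- paste0("            ", paste(sprintf("%3s", PSSM_ALPHABET), collapse = " "),
                  "   ", paste(sprintf("%3s", PSSM_ALPHABET), collapse = " "))
  aa <- strsplit(p$sequence, "")[[1]]
  body <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s  ", i, aa[i]),
           paste(sprintf("%3d", as.integer(round(p$scores[i, ]))), collapse = " "),
           "   ",
           paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
           "  0.00 0.00")
  }, character(1))
  foot <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1337     0.3176")
  paste(c(head1, head2, head3, body, foot), collapse = "\n")
}

#' Read a FASTA file with a sidecar fold-label table
#'
#' @param fasta Path to a FASTA file (multi-line sequences allowed) or its
#'   content as a character vector.
#' @param labels Path to a headerless two-column TSV `protein_id<TAB>fold`,
#'   or a data frame with columns `protein_id` and `fold_label`.
#' @return A `LabeledSequenceSet`: list with `entries` (data frame
#'   `protein_id`, `sequence`, `fold_label`, in FASTA order) and
#'   `fold_labels` (distinct labels in first-appearance order).
#' @export
read_labeled_fasta <- function(fasta, labels) {
  if (length(fasta) == 1L && !grepl("\n", fasta) && file.exists(fasta)) {
    lines <- readLines(fasta, warn = FALSE)
  } else {
    lines <- unlist(strsplit(fasta, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("empty FASTA: no records found", call. = FALSE)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste(gsub("[[:space:]]", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1))
  if (any(!nzchar(seqs)))
    stop("FASTA records with empty sequences: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)

  if (is.data.frame(labels)) {
    lab <- labels
  } else {
    lab <- read.table(labels, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      col.names = c("protein_id", "fold_label"))
  }
  stopifnot(all(c("protein_id", "fold_label") %in% names(lab)))
  missing <- setdiff(ids, lab$protein_id)
  if (length(missing))
    stop("FASTA ids missing from label table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  fold <- lab$fold_label[match(ids, lab$protein_id)]
  structure(list(entries = data.frame(protein_id = ids, sequence = seqs,
                                      fold_label = fold,
                                      stringsAsFactors = FALSE),
                 fold_labels = unique(fold)),
            class = "LabeledSequenceSet")
}

#' Normalize PSSM scores
#'
#' The covariance and dimer transforms can consume either the raw log-odds
#' scores (`mode = "raw"`, the default) or scores squashed elementwise into
#' (0, 1) by the logistic function `1 / (1 + exp(-x))` (`mode = "sigmoid"`).
#'
#' @param p A `PSSMProfile`.
#' @param mode `"raw"` or `"sigmoid"`.
#' @return A `PSSMProfile` with transformed scores.
#' @export
normalize_profile <- function(p, mode = c("raw", "sigmoid")) {
  stopifnot(inherits(p, "PSSMProfile"))
  mode <- match.arg(mode)
  if (mode == "raw") return(p)
  p$scores <- 1 / (1 + exp(-p$scores))
  p
}
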