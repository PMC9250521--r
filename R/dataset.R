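#' Remove short sequences
#'
#' Drops CDS shorter than `3 * min_aa` nucleotides (the coding-length
#' equivalent of a minimum protein length; a trailing stop codon is not
#' counted against the bound). The boundary is inclusive: `N = 3 * min_aa`
#' is kept.
#'
#' @param sequences Named character vector of CDS sequences.
#' @param min_aa Minimum protein length in amino acids (default 50).
#' @return The retained subset, original order preserved.
#' @export
filter_short <- function(sequences, min_aa = 50L) {
  sequences[nchar(sequences) >= 3L * min_aa]
}

# Global pairwise identity: matches / alignment length under a basic global
# (Needleman-Wunsch) alignment with match 1, mismatch 0, linear gap. A
# simple stand-in for a production redundancy tool (e.g. CD-HIT); inject a
# custom identity_fn for real curation.
default_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / aln_len
}

#' Remove redundant (highly similar) sequences
#'
#' Greedy filter in input order: a sequence is kept iff its pairwise
#' identity to every already-kept sequence is at or below `threshold`.
#'
#' @param sequences Named character vector.
#' @param threshold Maximum allowed identity fraction (default 0.40:
#'   sequences over 40 percent identical to a kept one are excluded).
#' @param identity_fn Function `(a, b) -> fraction in [0,1]`; defaults to
#'   matches / alignment-length under a basic global alignment (match 1,
#'   mismatch 0, linear gap) -- a stand-in, replaceable by e.g. a CD-HIT
#'   callback.
#' @return The retained subset, original order preserved.
#' @export
filter_redundant <- function(sequences, threshold = 0.40, identity_fn = NULL) {
  if (is.null(identity_fn)) identity_fn <- default_identity
  if (length(sequences) <= 1L) return(sequences)
  keep <- logical(length(sequences))
  keep[1L] <- TRUE
  for (i in seq_along(sequences)[-1L]) {
    ident <- vapply(which(keep), function(j)
      identity_fn(sequences[[i]], sequences[[j]]), numeric(1))
    keep[i] <- all(ident <= threshold)
  }
  sequences[keep]
}

#' Sample balanced random negative pairs
#'
#' Draws `n` unordered protein pairs uniformly at random from all candidate
#' pairs of distinct proteins, excluding known positives (unordered
#' identity) and duplicates, and labels them 0. When a localization map is
#' supplied, only pairs whose subcellular compartment sets are disjoint are
#' candidates (proteins in different compartments tend not to interact).
#' The default `n` equals the number of positives (balanced classes).
#'
#' @param proteins Character vector of protein ids.
#' @param positives Data.frame with columns `id_a`, `id_b` (known
#'   interacting pairs).
#' @param n Number of negatives (default `nrow(positives)`).
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @param localization Optional named list (or named character vector)
#'   mapping protein id to its compartment(s).
#' @param allow_self Allow self-pairs as candidates (default `FALSE`).
#' @return Data.frame `id_a`, `id_b`, `label` (all 0).
#' @export
sample_negatives <- function(proteins, positives, n = NULL, seed,
                             localization = NULL, allow_self = FALSE) {
  proteins <- unique(as.character(proteins))
  if (is.null(n)) n <- nrow(positives)
  idx <- utils::combn(length(proteins), 2L)
  cand_a <- proteins[idx[1L, ]]
  cand_b <- proteins[idx[2L, ]]
  if (allow_self) {
    cand_a <- c(cand_a, proteins)
    cand_b <- c(cand_b, proteins)
  }
  keys <- pair_key(cand_a, cand_b)
  pos_keys <- if (nrow(positives) > 0L) pair_key(positives$id_a, positives$id_b)
              else character(0)
  ok <- !(keys %in% pos_keys) & !duplicated(keys)
  if (!is.null(localization)) {
    loc <- lapply(localization, as.character)
    compartments_disjoint <- function(a, b) {
      la <- loc[[a]]
      lb <- loc[[b]]
      # unknown localization: not known to be disjoint, so excluded
      if (is.null(la) || is.null(lb)) return(FALSE)
      length(intersect(la, lb)) == 0L
    }
    ok <- ok & mapply(compartments_disjoint, cand_a, cand_b)
  }
  cand_a <- cand_a[ok]
  cand_b <- cand_b[ok]
  if (n > length(cand_a))
    stop("requested ", n, " negative pairs but only ", length(cand_a),
         " candidate pairs are available")
  pick <- with_seed(seed, sample.int(length(cand_a), n))
  data.frame(id_a = cand_a[pick], id_b = cand_b[pick],
             label = 0L, stringsAsFactors = FALSE)
}

#' Train/test split of labeled pairs
#'
#' Shuffles the pairs with `seed` and holds out `1/(ratio + 1)` of them as
#' the test set (`ratio = 5` gives the 5:1 train:test split; the test count
#' is rounded to the nearest integer). With `stratified = TRUE` (default)
#' the split is done per label with at least one test pair per class.
#'
#' @param pairs Data.frame `id_a`, `id_b`, `label` (no `NA` labels).
#' @param ratio Train:test ratio (default 5).
#' @param seed Integer seed.
#' @param stratified Stratify the split by label.
#' @return List of class `nvdt_split`: `train`, `test` (data.frames),
#'   `seed`, `ratio`.
#' @export
split_pairs <- function(pairs, ratio = 5, seed, stratified = TRUE) {
  stopifnot(nrow(pairs) >= 2L, !anyNA(pairs$label))
  take_test <- function(idx, n_test) {
    sh <- sample(idx)
    list(test = sh[seq_len(n_test)], train = sh[-seq_len(n_test)])
  }
  parts <- with_seed(seed, {
    if (stratified) {
      by_class <- split(seq_len(nrow(pairs)), pairs$label)
      if (any(lengths(by_class) < 2L))
        stop("stratified split needs at least 2 pairs per class")
      sel <- lapply(by_class, function(idx)
        take_test(idx, max(1L, round(length(idx) / (ratio + 1)))))
      list(test = unlist(lapply(sel, `[[`, "test"), use.names = FALSE),
           train = unlist(lapply(sel, `[[`, "train"), use.names = FALSE))
    } else {
      take_test(seq_len(nrow(pairs)), max(1L, round(nrow(pairs) / (ratio + 1))))
    }
  })
  structure(list(train = pairs[sort(parts$train), , drop = FALSE],
                 test = pairs[sort(parts$test), , drop = FALSE],
                 seed = seed, ratio = ratio),
            class = "nvdt_split")
}

#' k-fold partition of labeled pairs
#'
#' Partitions the rows of `pairs` into `k` disjoint folds whose sizes differ
#' by at most one, optionally stratified by label.
#'
#' @inheritParams split_pairs
#' @param k Number of folds (>= 2; default 5).
#' @return List of `k` integer vectors of row indices into `pairs`.
#' @export
kfold_pairs <- function(pairs, k = 5L, seed, stratified = TRUE) {
  n <- nrow(pairs)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of pairs (", n, ")")
  folds <- with_seed(seed, {
    ordered <- if (stratified) {
      # shuffle within class, then concatenate classes: the fold cycle below
      # spreads every class (and the total) maximally evenly
      unlist(lapply(split(seq_len(n), pairs$label), sample),
             use.names = FALSE)
    } else {
      sample(seq_len(n))
    }
    lapply(split(ordered, rep_len(seq_len(k), n)), sort)
  })
  unname(folds)
}

#' Write a dataset manifest
#'
#' TSV with columns `id_a`, `id_b`, `label`, `split` recording which pairs
#' are train vs test.
#'
#' @param bundle An `nvdt_split` from [split_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(bundle, path) {
  stopifnot(inherits(bundle, "nvdt_split"))
  df <- rbind(cbind(bundle$train[, c("id_a", "id_b", "label")], split = "train"),
              cbind(bundle$test[, c("id_a", "id_b", "label")], split = "test"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
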