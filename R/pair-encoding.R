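PAIR_SCHEMES <- c("Cod1", "Cod2", "Cod3", "Cod4", "Cod5")

#' Canonical order of a protein pair
#'
#' Returns the two ids in a deterministic (C-locale lexicographic) order so
#' that order-dependent encodings (Cod5) are reproducible run-to-run:
#' `(b, a)` and `(a, b)` always yield the same encoded vector. Self-pairs
#' are allowed.
#'
#' @param id_a,id_b Single ids.
#' @return Character vector of length 2.
#' @export
canonical_order <- function(id_a, id_b) {
  stopifnot(length(id_a) == 1L, length(id_b) == 1L)
  if (c_locale_min_first(id_a, id_b)) c(id_a, id_b) else c(id_b, id_a)
}

#' Encode a protein pair from two natural vectors
#'
#' Combines the per-protein feature vectors `A` and `B` into a single pair
#' feature under one of five schemes:
#' \describe{
#'   \item{Cod1}{`|A - B|` elementwise (symmetric).}
#'   \item{Cod2}{`A + B` (symmetric).}
#'   \item{Cod3}{concatenation `(|A - B|, A + B)` (halves symmetric).}
#'   \item{Cod4}{`A * B` elementwise (symmetric).}
#'   \item{Cod5}{concatenation `(A, B)` in the given order (default; callers
#'     wanting order-independence should pass the vectors in
#'     [canonical_order()]).}
#' }
#' Cod1/Cod2/Cod4 keep the input dimension (92 for NVDT); Cod3 and Cod5
#' double it (184 for NVDT).
#'
#' @param nv_a,nv_b Numeric feature vectors of equal length built with the
#'   same variant (an error otherwise).
#' @param scheme One of `"Cod1"`..`"Cod5"`.
#' @return Named numeric vector.
#' @export
encode_pair <- function(nv_a, nv_b, scheme = c("Cod5", "Cod1", "Cod2", "Cod3", "Cod4")) {
  scheme <- match.arg(scheme)
  if (length(nv_a) != length(nv_b))
    stop("feature vectors have different lengths (", length(nv_a), " vs ",
         length(nv_b), "); were they built with the same variant?")
  if (!is.null(names(nv_a)) && !is.null(names(nv_b)) &&
      !identical(names(nv_a), names(nv_b)))
    stop("feature vectors have different feature names; ",
         "were they built with the same variant?")
  fn <- names(nv_a)
  if (is.null(fn)) fn <- paste0("f", seq_along(nv_a))
  switch(scheme,
    Cod1 = stats::setNames(abs(nv_a - nv_b), fn),
    Cod2 = stats::setNames(nv_a + nv_b, fn),
    Cod3 = stats::setNames(c(abs(nv_a - nv_b), nv_a + nv_b),
                           c(paste0("diff_", fn), paste0("sum_", fn))),
    Cod4 = stats::setNames(nv_a * nv_b, fn),
    Cod5 = stats::setNames(c(nv_a, nv_b),
                           c(paste0("a_", fn), paste0("b_", fn))))
}

#' Pair-feature matrix for a table of protein pairs
#'
#' Looks up each pair's two natural vectors in `nv_matrix` and encodes them
#' under `scheme`. For order-dependent schemes the two vectors are taken in
#' [canonical_order()] unless `canonical = FALSE`. With
#' `augment_orders = TRUE` (training only) each pair is emitted in both
#' orders, doubling the rows.
#'
#' @param pairs Data.frame with columns `id_a`, `id_b` and optionally `label`.
#' @param nv_matrix Matrix from [natural_vector_matrix()] (rownames = ids).
#' @param scheme Pair-encoding scheme, see [encode_pair()].
#' @param canonical Order the two ids lexicographically before encoding.
#' @param augment_orders Emit both orders of every pair (rows are duplicated
#'   exactly for the symmetric schemes Cod1/Cod2/Cod4).
#' @return List with `x` (numeric matrix, one row per encoded pair),
#'   `label` (integer vector, `NA` where unlabeled) and `pairs` (the
#'   data.frame the rows correspond to).
#' @export
pair_feature_matrix <- function(pairs, nv_matrix,
                                scheme = c("Cod5", "Cod1", "Cod2", "Cod3", "Cod4"),
                                canonical = TRUE, augment_orders = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), rownames(nv_matrix))
  if (length(missing) > 0L)
    stop("no sequence features for id(s): ", paste(missing, collapse = ", "))
  if (augment_orders) {
    rev_pairs <- pairs
    rev_pairs$id_a <- pairs$id_b
    rev_pairs$id_b <- pairs$id_a
    pairs <- rbind(pairs, rev_pairs)
    canonical <- FALSE
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]
    b <- pairs$id_b[i]
    if (canonical) {
      ord <- canonical_order(a, b)
      a <- ord[1L]
      b <- ord[2L]
    }
    encode_pair(nv_matrix[a, ], nv_matrix[b, ], scheme = scheme)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- pair_key(pairs$id_a, pairs$id_b)
  label <- if ("label" %in% names(pairs)) as.integer(pairs$label)
           else rep(NA_integer_, nrow(pairs))
  list(x = x, label = label, pairs = pairs)
}

#' Featurize protein pairs from raw sequences
#'
#' Convenience wrapper: computes the natural-vector matrix for all ids used
#' by `pairs` and encodes every pair.
#'
#' @inheritParams pair_feature_matrix
#' @param sequences Named character vector of CDS sequences.
#' @param variant Natural-vector variant, see [natural_vector()].
#' @param kmer_normalize See [natural_vector()].
#' @return As [pair_feature_matrix()].
#' @export
featurize_pairs <- function(pairs, sequences,
                            variant = c("NVDT", "NV", "NVD", "NVT"),
                            scheme = c("Cod5", "Cod1", "Cod2", "Cod3", "Cod4"),
                            canonical = TRUE, augment_orders = FALSE,
                            kmer_normalize = FALSE) {
  variant <- match.arg(variant)
  scheme <- match.arg(scheme)
  ids <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(ids, names(sequences))
  if (length(missing) > 0L)
    stop("no sequence for id(s): ", paste(missing, collapse = ", "))
  nv <- natural_vector_matrix(sequences[ids], variant = variant,
                              kmer_normalize = kmer_normalize)
  pair_feature_matrix(pairs, nv, scheme = scheme, canonical = canonical,
                      augment_orders = augment_orders)
}
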