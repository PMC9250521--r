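BASES <- c("A", "C", "G", "T")

# All k-mers over {A,C,G,T} in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  grids <- rev(do.call(expand.grid,
                       c(rep(list(BASES), k),
                         list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))))
  apply(as.matrix(grids), 1L, paste, collapse = "")
}

DINUC <- all_kmers(2L)
TRINUC <- all_kmers(3L)

#' Feature names of a natural vector
#'
#' @param variant One of `"NVDT"` (92 features), `"NV"` (12), `"NVD"` (28),
#'   `"NVT"` (76).
#' @return Character vector of feature names in canonical order: counts
#'   `n_A..n_T`, mean positions `mu_A..mu_T`, second moments `D2_A..D2_T`,
#'   then dinucleotide (`AA..TT`) and/or trinucleotide (`AAA..TTT`) counts.
#' @export
nv_feature_names <- function(variant = c("NVDT", "NV", "NVD", "NVT")) {
  variant <- match.arg(variant)
  base12 <- c(paste0("n_", BASES), paste0("mu_", BASES), paste0("D2_", BASES))
  switch(variant,
    NV = base12,
    NVD = c(base12, DINUC),
    NVT = c(base12, TRINUC),
    NVDT = c(base12, DINUC, TRINUC))
}

# Split a sequence into its character vector once; shared by the ops below.
seq_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

#' Nucleotide counts
#'
#' Counts of A, C, G, T in the sequence (fixed order A, C, G, T). Positions
#' holding any other character (ambiguity codes under the `"mask"` policy)
#' are not counted.
#'
#' @param seq A single nucleotide sequence string.
#' @return Named integer vector of length 4; sums to the sequence length for
#'   a fully validated ACGT sequence.
#' @export
nucleotide_counts <- function(seq) {
  ch <- seq_chars(seq)
  cnt <- tabulate(factor(ch, levels = BASES), nbins = 4L)
  names(cnt) <- paste0("n_", BASES)
  cnt
}

#' Mean positions of each nucleotide
#'
#' The average 1-based position of each nucleotide in the sequence (the
#' first nucleotide is position 1). Nucleotides that do not occur get mean
#' position 0 by convention.
#'
#' @inheritParams nucleotide_counts
#' @return Named numeric vector `mu_A..mu_T`.
#' @export
mean_positions <- function(seq) {
  ch <- seq_chars(seq)
  mu <- vapply(BASES, function(b) {
    pos <- which(ch == b)
    if (length(pos) == 0L) 0 else mean(pos)
  }, numeric(1))
  names(mu) <- paste0("mu_", BASES)
  mu
}

#' Second normalized central moments of nucleotide positions
#'
#' For nucleotide k occurring at 1-based positions `p` with mean position
#' `mu_k`, the second normalized central moment is
#' `D2_k = sum((p - mu_k)^2) / (n_k * N)` where `n_k` is the count of k and
#' `N` the sequence length. `D2_k = 0` when k does not occur.
#'
#' @inheritParams nucleotide_counts
#' @return Named numeric vector `D2_A..D2_T`, all non-negative.
#' @export
second_central_moments <- function(seq) {
  ch <- seq_chars(seq)
  N <- length(ch)
  d2 <- vapply(BASES, function(b) {
    pos <- which(ch == b)
    if (length(pos) == 0L) return(0)
    mu <- mean(pos)
    sum((pos - mu)^2) / (length(pos) * N)
  }, numeric(1))
  names(d2) <- paste0("D2_", BASES)
  d2
}

#' Overlapping k-mer counts
#'
#' Counts of all overlapping windows of width `k` (stride 1; `N - k + 1`
#' windows) in lexicographic order with A < C < G < T. Raw counts, not
#' frequencies. Windows containing a non-ACGT character are skipped.
#'
#' @inheritParams nucleotide_counts
#' @param k Window width, 2 (dinucleotides, 16 counts) or 3 (trinucleotides,
#'   64 counts).
#' @return Named integer vector of length `4^k`; all zero (with a warning)
#'   when the sequence is shorter than `k`.
#' @export
kmer_counts <- function(seq, k) {
  stopifnot(k %in% c(2L, 3L))
  kmers <- if (k == 2L) DINUC else TRINUC
  N <- nchar(seq)
  if (N < k) {
    warning("sequence shorter than k = ", k, "; returning all-zero counts")
    cnt <- integer(length(kmers))
    names(cnt) <- kmers
    return(cnt)
  }
  win <- substring(seq, seq_len(N - k + 1L), k:N)
  cnt <- tabulate(factor(win, levels = kmers), nbins = length(kmers))
  names(cnt) <- kmers
  cnt
}

#' Natural vector of a gene sequence
#'
#' Computes the natural-vector representation of one CDS: nucleotide counts,
#' mean positions and second normalized central moments (the classic
#' 12-dimensional natural vector), optionally extended with the 16
#' dinucleotide and 64 trinucleotide counts (92 dimensions for `"NVDT"`).
#'
#' @inheritParams nucleotide_counts
#' @param variant Feature subset: `"NVDT"` (92 = 12 + 16 + 64, default),
#'   `"NV"` (12), `"NVD"` (28 = 12 + 16), `"NVT"` (76 = 12 + 64).
#' @param kmer_normalize If `TRUE`, k-mer counts are divided by the number
#'   of windows `N - k + 1` (frequencies instead of raw counts); off by
#'   default.
#' @return Named numeric vector in the canonical order of
#'   [nv_feature_names()].
#' @export
#' @examples
#' length(natural_vector("ACGTACGTACGT"))        # 92
#' natural_vector("AATA", variant = "NV")
natural_vector <- function(seq, variant = c("NVDT", "NV", "NVD", "NVT"),
                           kmer_normalize = FALSE) {
  variant <- match.arg(variant)
  out <- c(nucleotide_counts(seq), mean_positions(seq),
           second_central_moments(seq))
  scale_kmers <- function(cnt, k) {
    if (!kmer_normalize) return(cnt)
    nw <- max(nchar(seq) - k + 1L, 0L)
    if (nw == 0L) cnt else cnt / nw
  }
  if (variant %in% c("NVD", "NVDT"))
    out <- c(out, scale_kmers(kmer_counts(seq, 2L), 2L))
  if (variant %in% c("NVT", "NVDT"))
    out <- c(out, scale_kmers(kmer_counts(seq, 3L), 3L))
  out
}

#' Natural-vector matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams natural_vector
#' @return Numeric matrix, one row per sequence (rownames = ids), columns in
#'   [nv_feature_names()] order.
#' @export
natural_vector_matrix <- function(seqs, variant = c("NVDT", "NV", "NVD", "NVT"),
                                  kmer_normalize = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  fn <- nv_feature_names(variant)
  mat <- t(vapply(seqs, natural_vector, numeric(length(fn)),
                  variant = variant, kmer_normalize = kmer_normalize))
  dimnames(mat) <- list(names(seqs), fn)
  mat
}

#' Write a feature matrix as CSV
#'
#' First column `id` (sequence or pair identifier), then one column per
#' feature, with a header of feature names.
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
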