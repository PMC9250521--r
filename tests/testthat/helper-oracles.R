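# Independent brute-force oracles and fixture builders. These deliberately
# use the most naive formulation possible (explicit position loops, pairwise
# comparisons) so they share no code with the package implementation.

BASES4 <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES4, len, replace = TRUE),
                                  collapse = "")

# --- naive natural-vector oracles: explicit loops over positions ----------

naive_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(4)
  for (i in seq_along(ch))
    for (b in 1:4) if (ch[i] == BASES4[b]) out[b] <- out[b] + 1
  out
}

naive_means <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(4)
  for (b in 1:4) {
    s <- 0; n <- 0
    for (i in seq_along(ch)) if (ch[i] == BASES4[b]) { s <- s + i; n <- n + 1 }
    out[b] <- if (n == 0) 0 else s / n
  }
  out
}

naive_moments <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  N <- length(ch)
  mu <- naive_means(seq)
  out <- numeric(4)
  for (b in 1:4) {
    s <- 0; n <- 0
    for (i in seq_along(ch))
      if (ch[i] == BASES4[b]) { s <- s + (i - mu[b])^2; n <- n + 1 }
    out[b] <- if (n == 0) 0 else s / (n * N)
  }
  out
}

naive_kmers <- function(seq, k) {
  kmers <- apply(expand.grid(rep(list(BASES4), k))[, k:1, drop = FALSE],
                 1, paste, collapse = "")
  kmers <- sort(kmers)  # lexicographic, C locale for ACGT == any locale
  out <- setNames(numeric(length(kmers)), kmers)
  if (nchar(seq) < k) return(out)
  for (i in 1:(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (w %in% kmers) out[w] <- out[w] + 1
  }
  out
}

# --- brute-force metric oracle (direct transcription of the defining
#     ratios, no shared helpers) ------------------------------------------

brute_metrics <- function(tp, fp, tn, fn) {
  den_or_0 <- function(num, den) if (den == 0) 0 else num / den
  pre <- den_or_0(tp, tp + fp)
  sen <- den_or_0(tp, tp + fn)
  list(
    acc = den_or_0(tp + tn, tp + tn + fp + fn),
    pre = pre,
    sen = sen,
    spe = den_or_0(tn, tn + fp),
    mcc = den_or_0(tp * tn - fp * fn,
                   sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)),
    f1 = den_or_0(2 * pre * sen, pre + sen))
}

# Mann-Whitney AUC: fraction of (positive, negative) score pairs ordered
# correctly, ties counted 0.5.
mw_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# --- tiny fixture builders ------------------------------------------------

write_tmp_fasta <- function(records, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    body <- if (is.null(wrap)) s
            else substring(s, seq(1, nchar(s), wrap),
                           pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Two well-separated Gaussian blobs: a linearly separable toy problem.
make_blobs <- function(n_per_class = 20, d = 5, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  colnames(x) <- paste0("f", 1:d)
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}
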