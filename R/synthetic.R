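STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Draw latent codon-usage profiles
#'
#' Samples `n_profiles` probability vectors over the 64 codons from a
#' symmetric Dirichlet distribution (via normalized Gamma draws). Each
#' profile sums to 1. Larger `concentration` gives profiles closer to
#' uniform (weaker codon-usage bias and therefore a harder classification
#' problem).
#'
#' @param n_profiles Number of profiles (>= 2).
#' @param concentration Dirichlet concentration parameter (> 0; default 1).
#' @param seed Integer seed.
#' @return Numeric matrix `n_profiles x 64`, columns named by codon in
#'   lexicographic order; rows sum to 1.
#' @export
make_codon_profiles <- function(n_profiles, concentration = 1, seed) {
  stopifnot(n_profiles >= 2L, concentration > 0)
  g <- with_seed(seed,
                 matrix(rgamma(n_profiles * 64L, shape = concentration),
                        nrow = n_profiles))
  p <- g / rowSums(g)
  colnames(p) <- TRINUC
  rownames(p) <- paste0("profile", seq_len(n_profiles))
  p
}

# Sample one CDS: ATG start, remaining codons drawn from `probs` with
# in-frame stop codons excluded (renormalized over the 61 sense codons,
# equivalent to rejection-resampling stops).
sample_cds <- function(n_codons, probs) {
  probs[TRINUC %in% STOP_CODONS] <- 0
  probs <- probs / sum(probs)
  codons <- sample(TRINUC, n_codons - 1L, replace = TRUE, prob = probs)
  paste0("ATG", paste(codons, collapse = ""))
}

#' Simulate a PPI/PPNI benchmark with a planted codon-usage signal
#'
#' Generates CDS-like sequences in pairs. The two sequences of an
#' interacting pair (label 1) are both drawn codon-by-codon from the *same*
#' latent codon-usage profile; the two sequences of a non-interacting pair
#' (label 0) are drawn from two *distinct* profiles. Each sampling
#' distribution is the profile mixed with the uniform codon distribution by
#' weight `effect`, so `effect = 0` removes the signal entirely (both
#' classes exchangeable) and `effect = 1` plants the full profile contrast.
#' Every sequence starts with ATG and contains no in-frame stop codon.
#' Classes are balanced and all output is reproducible from the seed.
#'
#' This is a validation construct for the feature/classifier pipeline (the
#' trinucleotide features are exactly codon-composition-sensitive), not a
#' biological interactome simulator.
#'
#' @param n_pairs Pairs per class (default 300).
#' @param seq_len_nt Sequence length in nucleotides (multiple of 3,
#'   >= 150; default 900).
#' @param effect Signal strength in `[0, 1]` (default 1).
#' @param n_profiles Number of latent profiles (>= 2; default 2).
#' @param concentration Dirichlet concentration of the profiles (default 1).
#' @param seed Integer seed.
#' @return List of class `nvdt_synthetic`: `sequences` (named character
#'   vector, 4 * n_pairs entries), `pairs` (data.frame `id_a`, `id_b`,
#'   `label`, balanced), `profile_of` (named integer vector: the latent
#'   profile each sequence was drawn from, for building ground-truth
#'   networks and diagnostics), `profiles`, `config`.
#' @export
simulate_ppi_dataset <- function(n_pairs = 300L, seq_len_nt = 900L,
                                 effect = 1, n_profiles = 2L,
                                 concentration = 1, seed = 1L) {
  stopifnot(seq_len_nt %% 3L == 0L, seq_len_nt >= 150L,
            effect >= 0, effect <= 1, n_profiles >= 2L, n_pairs >= 1L)
  n_codons <- seq_len_nt %/% 3L
  profiles <- make_codon_profiles(n_profiles, concentration, seed = seed)
  uniform <- rep(1 / 64, 64L)
  mix <- function(p) effect * p + (1 - effect) * uniform
  out <- with_seed(seed + 1L, {
    seqs <- character(4L * n_pairs)
    ids <- sprintf("syn%04d", seq_len(4L * n_pairs))
    prof_of <- integer(4L * n_pairs)
    rows <- vector("list", 2L * n_pairs)
    for (i in seq_len(n_pairs)) {            # interacting: shared profile
      p <- sample.int(n_profiles, 1L)
      a <- 2L * i - 1L
      b <- 2L * i
      seqs[a] <- sample_cds(n_codons, mix(profiles[p, ]))
      seqs[b] <- sample_cds(n_codons, mix(profiles[p, ]))
      prof_of[c(a, b)] <- p
      rows[[i]] <- data.frame(id_a = ids[a], id_b = ids[b], label = 1L)
    }
    for (i in seq_len(n_pairs)) {            # non-interacting: distinct profiles
      pq <- sample.int(n_profiles, 2L)       # without replacement
      a <- 2L * n_pairs + 2L * i - 1L
      b <- 2L * n_pairs + 2L * i
      seqs[a] <- sample_cds(n_codons, mix(profiles[pq[1L], ]))
      seqs[b] <- sample_cds(n_codons, mix(profiles[pq[2L], ]))
      prof_of[c(a, b)] <- pq
      rows[[n_pairs + i]] <- data.frame(id_a = ids[a], id_b = ids[b], label = 0L)
    }
    names(seqs) <- ids
    names(prof_of) <- ids
    list(sequences = seqs, pairs = do.call(rbind, rows),
         profile_of = prof_of)
  })
  structure(list(sequences = out$sequences, pairs = out$pairs,
                 profile_of = out$profile_of, profiles = profiles,
                 config = list(n_pairs = n_pairs, seq_len_nt = seq_len_nt,
                               effect = effect, n_profiles = n_profiles,
                               concentration = concentration, seed = seed)),
            class = "nvdt_synthetic")
}

#' Write a synthetic dataset to disk
#'
#' Emits `sequences.fasta`, `pairs.tsv` and a `config.json` snapshot into
#' `dir`. Byte-identical for identical configs.
#'
#' @param dataset An `nvdt_synthetic` from [simulate_ppi_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nvdt_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_pair_table(dataset$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(dataset$config, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
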