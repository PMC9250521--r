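#' Read CDS sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file of nucleotide
#' sequences. Sequences are uppercased and `U` is mapped to `T`. The record
#' identifier is the first whitespace-delimited token of the header line.
#'
#' Characters outside `{A,C,G,T}` (ambiguity codes such as `N`, `R`, `Y`)
#' are handled according to `policy`:
#' \describe{
#'   \item{`"strict"`}{(default) error, reporting the sequence id and the
#'     1-based position of the first offending character.}
#'   \item{`"drop"`}{discard the whole sequence with a warning.}
#'   \item{`"mask"`}{keep the sequence; downstream feature extraction ignores
#'     the ambiguous positions and any k-mer window touching them. This
#'     changes count totals; published-style runs should use `"strict"` or
#'     `"drop"`.}
#' }
#'
#' A warning summarises sequences whose length is not a multiple of 3 (no
#' reading-frame check is enforced beyond this).
#'
#' @param path Path to a FASTA file.
#' @param policy One of `"strict"`, `"drop"`, `"mask"`.
#' @return Named character vector of validated sequences (names = ids).
#' @export
read_fasta <- function(path, policy = c("strict", "drop", "mask")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs <- validate_sequences(seqs, policy = policy)
  frame_off <- names(seqs)[nchar(seqs) %% 3L != 0L]
  if (length(frame_off) > 0L)
    warning("sequence length not a multiple of 3 for: ",
            paste(frame_off, collapse = ", "))
  seqs
}

# Apply the ambiguity policy to a named character vector of sequences.
validate_sequences <- function(seqs, policy = c("strict", "drop", "mask")) {
  policy <- match.arg(policy)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  bad_pos <- regexpr("[^ACGT]", seqs)
  bad <- bad_pos != -1L
  if (!any(bad)) return(seqs)
  switch(policy,
    strict = stop("non-ACGT character in sequence '", names(seqs)[bad][1L],
                  "' at position ", bad_pos[bad][1L],
                  " (policy \"strict\")"),
    drop = {
      warning("dropping ", sum(bad), " sequence(s) with non-ACGT characters: ",
              paste(names(seqs)[bad], collapse = ", "))
      seqs[!bad]
    },
    mask = seqs
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (nucleotides per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a protein-pair table
#'
#' Reads a tab-separated table of protein pairs with 2 columns (`id_a`,
#' `id_b`; unlabeled) or 3 columns (plus `label` in `{0,1}`; 1 =
#' interacting, 0 = non-interacting). A header row is recognised when the
#' first two fields are `id_a`/`id_b` (case-insensitive) or the third is
#' `label`. Input order is preserved.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `id_a`, `id_b`, `label` (`NA` for
#'   unlabeled pairs).
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("pair table is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1L]]))
  has_header <- (length(first) >= 2L && first[1L] == "id_a" && first[2L] == "id_b") ||
    (length(first) >= 3L && first[3L] == "label")
  if (has_header) {
    fields <- fields[-1L]
    lines <- lines[-1L]
    if (length(fields) == 0L) stop("pair table has a header but no rows: ", path)
  }
  ncol <- lengths(fields)
  offset <- if (has_header) 1L else 0L
  bad <- which(!(ncol %in% c(2L, 3L)))
  if (length(bad) > 0L)
    stop("pair table line ", bad[1L] + offset, " has ", ncol[bad[1L]],
         " columns (expected 2 or 3)")
  if (length(unique(ncol)) > 1L)
    stop("pair table mixes 2- and 3-column rows (first mismatch at line ",
         which(ncol != ncol[1L])[1L] + offset, ")")
  id_a <- vapply(fields, `[[`, character(1), 1L)
  id_b <- vapply(fields, `[[`, character(1), 2L)
  if (ncol[1L] == 3L) {
    raw <- vapply(fields, `[[`, character(1), 3L)
    if (!all(raw %in% c("0", "1")))
      stop("pair label outside {0,1} at line ",
           which(!(raw %in% c("0", "1")))[1L] + offset, ": '",
           raw[!(raw %in% c("0", "1"))][1L], "'")
    label <- as.integer(raw)
  } else {
    label <- rep(NA_integer_, length(fields))
  }
  data.frame(id_a = id_a, id_b = id_b, label = label,
             stringsAsFactors = FALSE)
}

#' Write a protein-pair table
#'
#' @param pairs Data.frame with columns `id_a`, `id_b` and optionally `label`.
#' @param path Output path (TSV, with header).
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  cols <- intersect(c("id_a", "id_b", "label"), names(pairs))
  df <- pairs[, cols, drop = FALSE]
  if ("label" %in% names(df)) df <- df[!is.na(df$label) | TRUE, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Canonical unordered key for protein pairs
#'
#' The pair (a, b) denotes the same biological pair as (b, a); this returns a
#' key string that is identical for both orders (C-locale lexicographic).
#'
#' @param id_a,id_b Character vectors of ids (recycled to common length).
#' @return Character vector of keys.
#' @export
pair_key <- function(id_a, id_b) {
  n <- max(length(id_a), length(id_b))
  id_a <- rep_len(as.character(id_a), n)
  id_b <- rep_len(as.character(id_b), n)
  vapply(seq_len(n), function(i) {
    ab <- c(id_a[i], id_b[i])[order(c(id_a[i], id_b[i]), method = "radix")]
    paste(ab, collapse = "\t")
  }, character(1))
}
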