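#' Construct a PPNI/PPI network
#'
#' A network holds protein nodes with a role (`"core"` hub or
#' `"satellite"`) and unordered edges (candidate pairs) carrying an optional
#' true label and, after [predict_network()], a predicted label and score.
#' The supported topologies include the one-core network (one hub that does
#' not interact with its satellites), the multiple-core network (several
#' hubs along a pathway) and the general crossing network.
#'
#' @param edges Data.frame with columns `id_a`, `id_b` and optionally
#'   `true_label` (0/1), `predicted_label`, `score`. Duplicate unordered
#'   edges are an error.
#' @param nodes Optional data.frame with columns `id`, `role` (`"core"` or
#'   `"satellite"`). Nodes referenced by edges but absent here are added as
#'   satellites; by default all nodes are satellites (roles come from
#'   curation, they are never inferred).
#' @return Object of class `ppni_network`: list with `nodes`, `edges`.
#' @export
ppni_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("id_a", "id_b") %in% names(edges)))
  keys <- pair_key(edges$id_a, edges$id_b)
  if (anyDuplicated(keys))
    stop("duplicate unordered edge(s): ",
         paste(unique(gsub("\t", "-", keys[duplicated(keys)])), collapse = ", "))
  for (col in c("true_label", "predicted_label", "score"))
    if (!col %in% names(edges)) edges[[col]] <- rep(NA_real_, nrow(edges))
  edge_ids <- unique(c(edges$id_a, edges$id_b))
  if (is.null(nodes)) {
    nodes <- data.frame(id = edge_ids,
                        role = rep("satellite", length(edge_ids)),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "role") %in% names(nodes)),
              all(nodes$role %in% c("core", "satellite")))
    extra <- setdiff(edge_ids, nodes$id)
    if (length(extra) > 0L)
      nodes <- rbind(nodes[, c("id", "role")],
                     data.frame(id = extra, role = "satellite"))
    orphan <- setdiff(edge_ids, nodes$id)
    if (length(orphan) > 0L)
      stop("edges reference unknown node(s): ", paste(orphan, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "ppni_network")
}

#' @export
print.ppni_network <- function(x, ...) {
  cat("PPNI network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "core"), "core ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a network from edge-list and node-role TSV files
#'
#' The edge list has columns `id_a`, `id_b` and optionally `true_label`;
#' the optional side file has columns `id`, `role`.
#'
#' @param edge_path Edge-list TSV path.
#' @param node_path Optional node-role TSV path.
#' @return A `ppni_network`.
#' @export
read_network <- function(edge_path, node_path = NULL) {
  pairs <- read_pair_table(edge_path)
  names(pairs)[names(pairs) == "label"] <- "true_label"
  nodes <- if (!is.null(node_path))
    utils::read.delim(node_path, stringsAsFactors = FALSE)
  else NULL
  ppni_network(pairs, nodes)
}

#' Predict every edge of a network
#'
#' Annotates each edge with the model's score and predicted label, by
#' pointwise application of the trained classifier to the edge's pair
#' feature. Nodes are untouched; edge order does not affect the result.
#'
#' @param model An `nvdt_model` from [train_ppi()].
#' @param network A `ppni_network`.
#' @param sequences Named character vector covering every node id (an error
#'   lists missing ids).
#' @return The network with `edges$score` and `edges$predicted_label`
#'   filled in.
#' @export
predict_network <- function(model, network, sequences) {
  stopifnot(inherits(network, "ppni_network"), inherits(model, "nvdt_model"))
  if (nrow(network$edges) == 0L) return(network)
  missing <- setdiff(network$nodes$id, names(sequences))
  if (length(missing) > 0L)
    stop("no sequence for node id(s): ", paste(missing, collapse = ", "))
  feats <- featurize_pairs(network$edges[, c("id_a", "id_b")], sequences,
                           variant = model$variant, scheme = model$scheme,
                           kmer_normalize = isTRUE(model$kmer_normalize))
  pred <- predict_classifier(model, feats$x)
  network$edges$score <- pred$score
  network$edges$predicted_label <- pred$label
  network
}

#' Per-network prediction accuracy
#'
#' @param network A `ppni_network` whose edges carry both `true_label` and
#'   `predicted_label` (an error otherwise).
#' @return List: `accuracy` (correct / total), `n_correct`, `n_edges`, and
#'   `table` -- the per-edge correctness table partitioning edges into the
#'   correctly and falsely predicted classes.
#' @export
network_accuracy <- function(network) {
  stopifnot(inherits(network, "ppni_network"))
  e <- network$edges
  if (nrow(e) == 0L) stop("network has no edges")
  if (anyNA(e$true_label) || anyNA(e$predicted_label))
    stop("network edges must carry true and predicted labels")
  correct <- as.integer(e$true_label) == as.integer(e$predicted_label)
  list(accuracy = mean(correct), n_correct = sum(correct),
       n_edges = nrow(e),
       table = data.frame(id_a = e$id_a, id_b = e$id_b,
                          true_label = e$true_label,
                          predicted_label = e$predicted_label,
                          correct = correct))
}

#' Retrain with incremental core-protein non-interaction information
#'
#' Emulates adding experimentally known non-interactions: for each core
#' protein, a seeded uniform random `fraction` of its incident network
#' edges is moved (with its true label) from the evaluation set into the
#' training pairs; the model is retrained and the remaining edges are
#' re-evaluated. Moved edges never appear in the evaluated set.
#'
#' @param base_pairs Labeled training pairs (data.frame).
#' @param network A `ppni_network` with true labels on all edges.
#' @param sequences Named character vector of CDS sequences.
#' @param spec A [model_spec()].
#' @param fraction Fraction of each core protein's edges to move, in
#'   `[0, 1)` (e.g. 0.10, 0.30, 0.40; 0 is a no-op retrain).
#' @param seed Integer seed for the edge sampling.
#' @param variant,scheme Featurization options.
#' @return List: `model` (retrained), `accuracy` (on remaining edges),
#'   `moved` (data.frame of moved edges), `evaluated` (the re-predicted
#'   remainder network).
#' @export
augment_and_retrain <- function(base_pairs, network, sequences,
                                spec = model_spec("svm"), fraction, seed,
                                variant = "NVDT", scheme = "Cod5") {
  stopifnot(inherits(network, "ppni_network"),
            fraction >= 0, fraction < 1)
  e <- network$edges
  if (anyNA(e$true_label)) stop("network edges must carry true labels")
  core <- network$nodes$id[network$nodes$role == "core"]
  moved_idx <- integer(0)
  if (fraction > 0 && length(core) > 0L) {
    moved_idx <- with_seed(seed, {
      picked <- integer(0)
      for (cp in core) {
        inc <- setdiff(which(e$id_a == cp | e$id_b == cp), picked)
        n_move <- round(fraction * length(inc))
        if (n_move > 0L) picked <- c(picked, sample(inc, n_move))
      }
      sort(picked)
    })
  }
  if (length(moved_idx) == nrow(e))
    stop("fraction ", fraction, " moves every edge; nothing left to evaluate")
  moved <- e[moved_idx, c("id_a", "id_b", "true_label")]
  names(moved)[3L] <- "label"
  train <- rbind(base_pairs[, c("id_a", "id_b", "label")], moved)
  model <- train_ppi(train, sequences, spec, variant = variant, scheme = scheme)
  remainder <- ppni_network(e[setdiff(seq_len(nrow(e)), moved_idx),
                              c("id_a", "id_b", "true_label")],
                            network$nodes)
  remainder <- predict_network(model, remainder, sequences)
  list(model = model, accuracy = network_accuracy(remainder)$accuracy,
       moved = moved, evaluated = remainder)
}

#' Export a network to Pajek .net format
#'
#' Writes a `*Vertices` block (1-based contiguous vertex numbers with
#' quoted id labels) followed by a `*Edges` block. The edge value column
#' encodes prediction correctness as in the usual figure colour classes:
#' 1 = predicted correctly, 2 = predicted falsely, 0 = correctness unknown
#' (missing labels).
#'
#' @param network A `ppni_network`.
#' @param path Output path (conventionally `.net`).
#' @return `path`, invisibly.
#' @export
export_pajek <- function(network, path) {
  stopifnot(inherits(network, "ppni_network"))
  ids <- network$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  lines <- c(paste0("*Vertices ", length(ids)),
             sprintf("%d \"%s\"", seq_along(ids), ids),
             "*Edges")
  e <- network$edges
  if (nrow(e) > 0L) {
    value <- ifelse(is.na(e$true_label) | is.na(e$predicted_label), 0L,
                    ifelse(as.integer(e$true_label) ==
                             as.integer(e$predicted_label), 1L, 2L))
    lines <- c(lines, sprintf("%d %d %d", idx[e$id_a], idx[e$id_b], value))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Minimal reader for the files written by [export_pajek()]: returns the
#' vertex labels and the edge table (1-based vertex numbers and the edge
#' value column).
#'
#' @param path Path to a `.net` file.
#' @return List: `vertices` (character vector of labels), `edges`
#'   (data.frame `from`, `to`, `value`).
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[1L],
                       ignore.case = TRUE))
  vert <- sub("^\\d+\\s+\"(.*)\"\\s*$", "\\1", lines[1L + seq_len(nv)])
  edge_start <- which(grepl("^\\*Edges", lines, ignore.case = TRUE))[1L]
  edge_lines <- lines[seq_len(length(lines) - edge_start) + edge_start]
  edge_lines <- edge_lines[nzchar(trimws(edge_lines))]
  if (length(edge_lines) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0), value = integer(0))
  } else {
    parts <- do.call(rbind, lapply(strsplit(trimws(edge_lines), "\\s+"),
                                   function(p) as.integer(p[1:3])))
    edges <- data.frame(from = parts[, 1L], to = parts[, 2L],
                        value = parts[, 3L])
  }
  list(vertices = vert, edges = edges)
}

#' Write an annotated edge table
#'
#' TSV with `id_a`, `id_b`, `true_label`, `predicted_label`, `score`.
#'
#' @param network A `ppni_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "ppni_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
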