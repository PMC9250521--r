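# A small one-core network over synthetic sequences: the hub fails to
# interact with its satellites (label 0 edges), satellites interact among
# themselves where stated.
make_test_network <- function(n_sat = 6, true_label = 0L) {
  ids <- c("hub", paste0("sat", seq_len(n_sat)))
  edges <- data.frame(id_a = "hub", id_b = ids[-1],
                      true_label = true_label)
  nodes <- data.frame(id = ids, role = c("core", rep("satellite", n_sat)))
  ppni_network(edges, nodes)
}

test_that("network construction validates edges, roles and duplicates", {
  net <- make_test_network()
  expect_s3_class(net, "ppni_network")
  expect_equal(sum(net$nodes$role == "core"), 1L)
  expect_error(ppni_network(data.frame(id_a = c("a", "b"), id_b = c("b", "a"))),
               "duplicate")
  expect_error(ppni_network(data.frame(id_a = "a", id_b = "b"),
                            data.frame(id = "a", role = "boss")))
  # nodes referenced by edges but missing from the role table become satellites
  net2 <- ppni_network(data.frame(id_a = "a", id_b = "b"),
                       data.frame(id = "a", role = "core"))
  expect_setequal(net2$nodes$id, c("a", "b"))
})

test_that("network accuracy is correct/total with a per-edge correctness table", {
  edges <- data.frame(id_a = paste0("x", 1:26), id_b = paste0("y", 1:26),
                      true_label = 0L,
                      predicted_label = c(rep(0L, 23), rep(1L, 3)))
  acc <- network_accuracy(ppni_network(edges))
  expect_equal(acc$accuracy, 23 / 26)
  expect_equal(acc$n_correct, 23L)
  expect_equal(sum(acc$table$correct), 23L)
  expect_equal(nrow(acc$table), 26L)
  all_right <- ppni_network(data.frame(id_a = "a", id_b = "b",
                                       true_label = 1L, predicted_label = 1L))
  expect_equal(network_accuracy(all_right)$accuracy, 1.0)
  expect_error(network_accuracy(make_test_network()), "labels")
})

test_that("predict_network annotates every edge by pointwise classification", {
  ds <- simulate_ppi_dataset(n_pairs = 40, seq_len_nt = 300, effect = 1,
                             seed = 21)
  spec <- model_spec("svm", cost = 1, gamma = 1 / 184, seed = 21)
  model <- train_ppi(ds$pairs, ds$sequences, spec)
  # build a candidate network from held-out-style edges among known proteins
  ids <- names(ds$sequences)
  edges <- data.frame(id_a = ids[seq(1, 20, 2)], id_b = ids[seq(2, 20, 2)],
                      true_label = 1L)
  net <- predict_network(model, ppni_network(edges), ds$sequences)
  expect_equal(nrow(net$edges), 10L)
  expect_false(anyNA(net$edges$score))
  expect_false(anyNA(net$edges$predicted_label))
  # composition contract: equals pointwise predict on the Cod5 features
  feats <- featurize_pairs(edges[, c("id_a", "id_b")], ds$sequences)
  pred <- predict_classifier(model, feats$x)
  expect_identical(net$edges$score, pred$score)
  expect_identical(net$edges$predicted_label, pred$label)
  # edge-order independence
  perm <- sample(nrow(edges))
  net_p <- predict_network(model, ppni_network(edges[perm, ]), ds$sequences)
  expect_identical(net_p$edges$score, pred$score[perm])
  # empty edge set is a no-op; missing sequences are reported by id
  empty <- ppni_network(data.frame(id_a = character(0), id_b = character(0)))
  expect_identical(predict_network(model, empty, ds$sequences)$edges,
                   empty$edges)
  bad <- ppni_network(data.frame(id_a = "ghost", id_b = ids[1]))
  expect_error(predict_network(model, bad, ds$sequences), "ghost")
})

test_that("network accuracy equals confusion-based accuracy on the same edges", {
  ds <- simulate_ppi_dataset(n_pairs = 30, seq_len_nt = 300, effect = 0.8,
                             seed = 22)
  spec <- model_spec("svm", cost = 1, gamma = 1 / 184, seed = 22)
  sp <- split_pairs(ds$pairs, seed = 22)
  model <- train_ppi(sp$train, ds$sequences, spec)
  net <- predict_network(model,
                         ppni_network(stats::setNames(sp$test,
                                        c("id_a", "id_b", "true_label"))),
                         ds$sequences)
  acc_net <- network_accuracy(net)$accuracy
  m <- evaluate_ppi(model, sp$test, ds$sequences)
  expect_equal(acc_net, m$acc, tolerance = 1e-12)
})

test_that("augment_and_retrain moves seeded core edges out of evaluation", {
  ds <- simulate_ppi_dataset(n_pairs = 40, seq_len_nt = 300, effect = 1,
                             seed = 23)
  spec <- model_spec("svm", cost = 1, gamma = 1 / 184, seed = 23)
  ids <- names(ds$sequences)
  # core protein = first synthetic id; its candidate partners are negatives
  neg <- ds$pairs[ds$pairs$label == 0L, ][1:10, ]
  edges <- data.frame(id_a = neg$id_a[1], id_b = neg$id_b,
                      true_label = 0L)
  nodes <- data.frame(id = unique(c(edges$id_a, edges$id_b)),
                      role = c("core", rep("satellite", nrow(edges))))
  net <- ppni_network(edges, nodes)
  base <- ds$pairs[!(pair_key(ds$pairs$id_a, ds$pairs$id_b) %in%
                       pair_key(edges$id_a, edges$id_b)), ]
  res <- augment_and_retrain(base, net, ds$sequences, spec,
                             fraction = 0.4, seed = 23)
  expect_equal(nrow(res$moved), 4L)   # round(0.4 * 10)
  expect_equal(nrow(res$evaluated$edges), 6L)
  moved_keys <- pair_key(res$moved$id_a, res$moved$id_b)
  eval_keys <- pair_key(res$evaluated$edges$id_a, res$evaluated$edges$id_b)
  expect_length(intersect(moved_keys, eval_keys), 0L)
  # determinism of the move
  res2 <- augment_and_retrain(base, net, ds$sequences, spec,
                              fraction = 0.4, seed = 23)
  expect_identical(res$moved, res2$moved)
  # fraction 0 is a no-op: all edges evaluated, accuracy matches direct path
  res0 <- augment_and_retrain(base, net, ds$sequences, spec,
                              fraction = 0, seed = 23)
  expect_equal(nrow(res0$evaluated$edges), 10L)
  direct <- predict_network(train_ppi(base, ds$sequences, spec), net,
                            ds$sequences)
  expect_equal(res0$accuracy, network_accuracy(direct)$accuracy)
})

test_that("Pajek export has 1-based contiguous vertices and round-trips counts", {
  edges <- data.frame(id_a = "a", id_b = "b", true_label = 0L,
                      predicted_label = 0L)
  net <- ppni_network(edges)
  path <- withr::local_tempfile(fileext = ".net")
  export_pajek(net, path)
  lines <- readLines(path)
  expect_identical(lines[1], "*Vertices 2")
  expect_identical(lines[4], "*Edges")
  expect_identical(lines[5], "1 2 1")  # correct prediction => edge value 1
  back <- read_pajek(path)
  expect_identical(back$vertices, c("a", "b"))
  expect_equal(nrow(back$edges), 1L)

  # larger network: contiguous numbering, false predictions flagged as 2
  net6 <- make_test_network()
  net6$edges$predicted_label <- c(0L, 0L, 1L, 0L, 1L, 0L)
  path6 <- withr::local_tempfile(fileext = ".net")
  export_pajek(net6, path6)
  back6 <- read_pajek(path6)
  expect_identical(back6$vertices, net6$nodes$id)
  expect_identical(sort(unique(c(back6$edges$from, back6$edges$to))),
                   seq_along(back6$vertices)[1:7])
  expect_equal(sum(back6$edges$value == 2), 2L)
})

test_that("network edge and role files round-trip through read_network", {
  edge_path <- write_tmp_tsv(c("id_a\tid_b\tlabel", "hub\ts1\t0", "hub\ts2\t0"))
  node_path <- write_tmp_tsv(c("id\trole", "hub\tcore", "s1\tsatellite",
                               "s2\tsatellite"))
  net <- read_network(edge_path, node_path)
  expect_equal(nrow(net$edges), 2L)
  expect_identical(net$edges$true_label, c(0L, 0L))
  expect_identical(net$nodes$role[net$nodes$id == "hub"], "core")
})
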