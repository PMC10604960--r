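# Negative sampling, splits, metrics and the training loop contracts.

test_that("sample_negatives draws distinct zero cells reproducibly", {
  assoc <- rand_assoc(10, 8, seed = 71)
  n <- sum(assoc$entries)
  neg <- sample_negatives(assoc, n, seed = 72)
  expect_equal(nrow(neg), n)
  expect_equal(nrow(unique(neg)), n)
  idx <- cbind(match(neg$mirna, assoc$mirna_ids),
               match(neg$disease, assoc$disease_ids))
  expect_true(all(assoc$entries[idx] == 0))
  expect_identical(neg, sample_negatives(assoc, n, seed = 72))
  expect_false(identical(neg, sample_negatives(assoc, n, seed = 73)))
  expect_error(sample_negatives(assoc, 10000L, seed = 1), "zero cells")
})

test_that("five_fold_split partitions with stratified, balanced folds", {
  assoc <- rand_assoc(12, 10, seed = 74)
  pos <- association_edges(assoc)
  neg <- sample_negatives(assoc, nrow(pos), seed = 75)
  edges <- labeled_edge_set(pos, neg, seed = 75)
  folds <- five_fold_split(edges, seed = 76)
  expect_length(folds, 5L)
  total <- 2L * nrow(pos)
  sizes <- vapply(folds, nrow, integer(1))
  expect_equal(sum(sizes), total)
  expect_lte(max(sizes) - min(sizes), 2L)  # one per label class
  key <- function(df) paste(df$mirna, df$disease, df$label)
  allkeys <- unlist(lapply(folds, key))
  expect_equal(anyDuplicated(allkeys), 0L)
  for (f in folds) expect_lte(abs(sum(f$label == 1) - sum(f$label == 0)), 1L)
})

test_that("independent_split is stratified and sized by rounding", {
  assoc <- rand_assoc(10, 8, seed = 77)
  pos <- association_edges(assoc)
  neg <- sample_negatives(assoc, nrow(pos), seed = 78)
  edges <- labeled_edge_set(pos, neg, seed = 78)
  sp <- independent_split(edges, 0.5, seed = 79)
  expect_equal(nrow(sp$test), nrow(pos))        # half of 2n, stratified
  expect_equal(sum(sp$test$label), nrow(pos) / 2, tolerance = 0.51)
  expect_equal(nrow(sp$train) + nrow(sp$test), 2L * nrow(pos))
  key <- function(df) paste(df$mirna, df$disease)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_error(independent_split(edges, 1.2, seed = 1), "test_fraction")
})

test_that("labeled_edge_set rejects overlap and imbalance", {
  pos <- data.frame(mirna = c("m1", "m2"), disease = c("d1", "d2"))
  neg1 <- data.frame(mirna = "m1", disease = "d2")
  expect_error(labeled_edge_set(pos, neg1), "balanced")
  expect_error(labeled_edge_set(pos, pos), "overlap")
})

test_that("evaluate_scores matches the pairwise AUC oracle and edge cases", {
  set.seed(81)
  for (s in 1:6) {
    n <- sample(20:120, 1L)
    p <- round(runif(n), 2)          # rounding forces ties
    y <- rbinom(n, 1L, 0.5)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    sc <- pair_scores(data.frame(m = paste0("m", 1:n), d = paste0("d", 1:n)),
                      pmin(pmax(p, 0.001), 0.999), labels = y)
    ev <- evaluate_scores(sc)
    expect_equal(ev$auc, oracle_auc(sc$probabilities, y), tolerance = 1e-12)
    expect_equal(sum(ev$confusion), n)
    expect_equal(ev$acc, (ev$confusion[["TP"]] + ev$confusion[["TN"]]) / n)
  }
  # perfect separation
  sc <- pair_scores(data.frame(m = paste0("m", 1:4), d = paste0("d", 1:4)),
                    c(0.9, 0.8, 0.2, 0.1), labels = c(1, 1, 0, 0))
  ev <- evaluate_scores(sc)
  expect_equal(ev$auc, 1)
  expect_equal(ev$aupr, 1)
  expect_equal(ev$f1, 1)
  # single-class labels are undefined for AUC
  one <- pair_scores(data.frame(m = "m1", d = "d1"), 0.7, labels = 1)
  expect_error(evaluate_scores(one), "single class")
})

test_that("cross-validation folds leak no validation positives into inputs", {
  assoc <- rand_assoc(10, 8, seed = 82, p = 0.35)
  pos <- association_edges(assoc)
  neg <- sample_negatives(assoc, nrow(pos), seed = 83)
  folds <- five_fold_split(labeled_edge_set(pos, neg, 83), seed = 84)
  dag <- rand_dag(8, seed = 85)
  dag$terms <- assoc$disease_ids
  if (nrow(dag$edges)) {
    dag$edges$child <- assoc$disease_ids[match(dag$edges$child, paste0("t", 1:8))]
    dag$edges$parent <- assoc$disease_ids[match(dag$edges$parent, paste0("t", 1:8))]
  }
  cfg <- tiny_config()
  for (f in 1:5) {
    val_pos <- folds[[f]][folds[[f]]$label == 1, ]
    if (!nrow(val_pos)) next
    assoc_tr <- dualmda:::.drop_positives(assoc, val_pos)
    feats <- build_model_inputs(assoc_tr, dag = dag, cfg = cfg)
    mi <- match(val_pos$mirna, assoc$mirna_ids)
    dj <- match(val_pos$disease, assoc$disease_ids)
    # absent from the training adjacency (heterogeneous graph)...
    expect_true(all(feats$graph$adjacency[cbind(mi, feats$M + dj)] == 0))
    # ...and from the GIP profiles (rows/cols of the training matrix)
    expect_true(all(assoc_tr$entries[cbind(mi, dj)] == 0))
  }
})

test_that("training reduces the loss on separable data and validates inputs", {
  scfg <- synth_config(n_mirna = 24L, n_disease = 16L, n_blocks = 2L,
                       p_within = 0.6, p_background = 0.02, seed = 5L)
  dag <- simulate_dag(scfg)
  assoc <- simulate_associations(scfg)
  pos <- association_edges(assoc)
  neg <- sample_negatives(assoc, nrow(pos), seed = 86)
  df <- rbind(cbind(pos, label = 1), cbind(neg, label = 0))
  cfg <- tiny_config(epochs = 40L, lr = 3e-3, sim_threshold = 0.5)
  feats <- build_model_inputs(assoc, dag = dag, cfg = cfg)
  model <- mda_train(feats, df, cfg = cfg, seed = 87)
  losses <- model$history$loss
  expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
  expect_error(mda_train(feats, df[0, ], cfg = cfg, seed = 1), "no training")
})
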