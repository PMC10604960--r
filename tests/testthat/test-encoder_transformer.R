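# Channel 2: degree-encoded input features and SPD-biased self-attention.

test_that("input features decompose into projections plus degree embedding", {
  set.seed(41)
  M <- 5L; N <- 4L
  cfg <- tiny_config()
  params <- init_model_params(cfg, M, N)
  mf <- diag(M); df <- diag(N)
  degrees <- c(0L, 1L, 2L, 3L, 9L, 0L, 1L, 2L, 3L)
  fmd <- build_input_features(mf, df, degrees, params, cfg)
  expect_equal(dim(fmd), c(M + N, cfg$embed_dim))
  # zeroing the degree table leaves the stacked linear projections
  p0 <- params; p0$trf_Edeg[] <- 0
  fmd0 <- build_input_features(mf, df, degrees, p0, cfg)
  manual <- rbind(sweep(mf %*% params$trf_Wpm, 2, as.numeric(params$trf_bpm), "+"),
                  sweep(df %*% params$trf_Wpd, 2, as.numeric(params$trf_bpd), "+"))
  expect_equal(fmd0, manual, tolerance = 1e-12)
  # equal feature rows with different degrees still get distinct inputs
  mf2 <- matrix(1, M, M)
  fmd2 <- build_input_features(mf2, df, degrees, params, cfg)
  expect_gt(max(abs(fmd2[1, ] - fmd2[2, ])), 1e-8)
  expect_error(build_input_features(mf, df, degrees[-1], params, cfg),
               "aligned")
})

test_that("zero SPD bias reduces structural attention to plain attention", {
  set.seed(42)
  n <- 6L
  Fmd <- matrix(rnorm(n * 8), n, 8)
  Wq <- matrix(rnorm(8 * 4), 8, 4); Wk <- matrix(rnorm(8 * 4), 8, 4)
  Wv <- matrix(rnorm(8 * 4), 8, 4)
  adj <- rand_adjacency(n, seed = 43, p = 0.4)
  spd <- shortest_path_matrix(adj, clip = 4L)
  plain <- structural_attention(Fmd, spd, Wq, Wk, Wv, spd_bias = NULL)
  zeroed <- structural_attention(Fmd, spd, Wq, Wk, Wv,
                                 spd_bias = rep(0, 6), spd_clip = 4L)
  expect_equal(plain$output, zeroed$output, tolerance = 1e-12)
  expect_equal(rowSums(plain$attention), rep(1, n), tolerance = 1e-6)
})

test_that("a large negative far-bucket bias confines attention to neighbours", {
  set.seed(44)
  n <- 6L
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1   # path graph
  spd <- shortest_path_matrix(adj, clip = 4L)
  Fmd <- matrix(rnorm(n * 8), n, 8)
  Wq <- matrix(rnorm(8 * 4), 8, 4); Wk <- matrix(rnorm(8 * 4), 8, 4)
  Wv <- matrix(rnorm(8 * 4), 8, 4)
  # buckets: dist 0 and 1 free, everything farther -1e9
  bias <- c(0, 0, rep(-1e9, 4))
  out <- structural_attention(Fmd, spd, Wq, Wk, Wv, spd_bias = bias,
                              spd_clip = 4L)
  # oracle: masked softmax restricted to self + graph neighbours
  Q <- Fmd %*% Wq; K <- Fmd %*% Wk; V <- Fmd %*% Wv
  logits <- tcrossprod(Q, K) / sqrt(4)
  logits[spd > 1] <- -Inf
  P <- t(apply(logits, 1L, function(z) { e <- exp(z - max(z)); e / sum(e) }))
  expect_equal(out$attention, P, tolerance = 1e-9)
  expect_equal(out$output, P %*% V, tolerance = 1e-9)
  expect_true(all(out$attention[spd > 1] < 1e-12))
})

test_that("multi_head with one head equals structural attention plus W_O", {
  set.seed(45)
  cfg <- tiny_config(trf_heads = 1L, trf_graph_attrs = FALSE)
  params <- init_model_params(cfg, 3L, 3L)
  Fmd <- matrix(rnorm(6 * 8), 6, 8)
  adj <- rand_adjacency(6, seed = 46, p = 0.4)
  spd <- shortest_path_matrix(adj, clip = cfg$spd_clip)
  mh <- multi_head(Fmd, spd, params, cfg)
  sa <- structural_attention(Fmd, spd, params$trf_Wq_1_1, params$trf_Wk_1_1,
                             params$trf_Wv_1_1)
  manual <- sweep(sa$output %*% params$trf_WO_1, 2,
                  as.numeric(params$trf_bO_1), "+")
  expect_equal(mh, manual, tolerance = 1e-9)
  # output shape is (M+N) x d regardless of head count
  cfg4 <- tiny_config(trf_heads = 4L, trf_graph_attrs = FALSE)
  set.seed(45)
  params4 <- init_model_params(cfg4, 3L, 3L)
  expect_equal(dim(multi_head(Fmd, spd, params4, cfg4)), c(6L, 8L))
})

test_that("transformer encoder with zeroed graph attributes matches the plain oracle", {
  set.seed(47)
  cfg <- tiny_config(trf_graph_attrs = FALSE)
  params <- init_model_params(cfg, 6L, 6L)
  Fmd <- matrix(rnorm(12 * 8), 12, 8)
  adj <- rand_adjacency(12, seed = 48, p = 0.25)
  spd <- shortest_path_matrix(adj, clip = cfg$spd_clip)
  H <- transformer_encode(Fmd, spd, params, cfg)
  H_oracle <- oracle_plain_transformer(Fmd, params, cfg)
  expect_equal(H, H_oracle, tolerance = 1e-5)
})

test_that("zero encoder layers is the identity", {
  set.seed(49)
  cfg <- tiny_config(trf_graph_attrs = FALSE)
  cfg$trf_layers <- 0L
  params <- init_model_params(tiny_config(trf_graph_attrs = FALSE), 3L, 3L)
  Fmd <- matrix(rnorm(6 * 8), 6, 8)
  spd <- matrix(1L, 6, 6); diag(spd) <- 0L
  expect_equal(transformer_encode(Fmd, spd, params, cfg), Fmd)
})

test_that("multi_head is node-permutation equivariant given permuted SPD", {
  set.seed(50)
  cfg <- tiny_config()
  params <- init_model_params(cfg, 10L, 10L)
  Fmd <- matrix(rnorm(20 * 8), 20, 8)
  adj <- rand_adjacency(20, seed = 51, p = 0.2)
  spd <- shortest_path_matrix(adj, clip = cfg$spd_clip)
  out <- multi_head(Fmd, spd, params, cfg)
  perm <- sample(20)
  out_p <- multi_head(Fmd[perm, ], spd[perm, perm], params, cfg)
  expect_equal(out_p, out[perm, ], tolerance = 1e-9)
})

test_that("evaluation-mode embeddings are bitwise deterministic", {
  assoc <- rand_assoc(8, 6, seed = 52)
  dag <- rand_dag(6, seed = 53)
  dag$terms <- assoc$disease_ids
  if (nrow(dag$edges)) {
    dag$edges$child <- assoc$disease_ids[match(dag$edges$child, paste0("t", 1:6))]
    dag$edges$parent <- assoc$disease_ids[match(dag$edges$parent, paste0("t", 1:6))]
  }
  cfg <- tiny_config()
  feats <- build_model_inputs(assoc, dag = dag, cfg = cfg)
  set.seed(54)
  params <- init_model_params(cfg, feats$M, feats$N)
  f1 <- dualmda:::model_forward(params, feats, cfg, 1:3, 1:3)
  f2 <- dualmda:::model_forward(params, feats, cfg, 1:3, 1:3)
  expect_identical(f1$fused$value, f2$fused$value)
  expect_identical(f1$logits$value, f2$logits$value)
})
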