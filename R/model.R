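# The dual-channel encoder forward pass. Internal .fw_* functions operate on
# autodiff nodes so the same code serves training (with gradients) and the
# exported evaluation wrappers (constants in, values out).

# symmetric-normalised convolution operator D^-1/2 (A + I) D^-1/2
sym_norm_adjacency <- function(Adj) {
  At <- Adj + diag(nrow(Adj))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

# additive softmax mask: 0 on edges, -1e9 elsewhere; isolated nodes get a
# self-loop so their softmax neighbourhood is never empty
attention_mask <- function(Adj, big = 1e9) {
  Mk <- ifelse(Adj > 0, 0, -big)
  iso <- which(rowSums(Adj) == 0)
  if (length(iso)) Mk[cbind(iso, iso)] <- 0
  Mk
}

.drop_node <- function(nd, rate, training) {
  if (!training || rate <= 0) return(nd)
  keep <- matrix(stats::rbinom(length(nd$value), 1L, 1 - rate),
                 nrow(nd$value), ncol(nd$value))
  ad_mul_const(nd, keep / (1 - rate))
}

#' Assemble all model inputs from a training association matrix
#'
#' Computes, from the training-fold associations only (to avoid label
#' leakage), the full similarity stack (DSS, MFS, DGS, MGS and the aggregated
#' MF / DF feature matrices), the similarity adjacencies `GM` / `GD`, the
#' heterogeneous graph with its degree vector and clipped shortest-path
#' matrix, and the precomputed constants consumed by the two encoder
#' channels.
#'
#' @param assoc Training [association_matrix()].
#' @param dag Optional [disease_dag()]; required unless `dss` is given.
#' @param cfg An [mda_config()].
#' @param dss Optional precomputed `mda_sim` of kind `"DSS"`.
#' @param mfs Optional precomputed `mda_sim` of kind `"MFS"` (e.g. from an
#'   external functional-similarity resource); computed from `dss` otherwise.
#' @return List of model inputs (class `mda_inputs`).
#' @export
build_model_inputs <- function(assoc, dag = NULL, cfg = mda_config(),
                               dss = NULL, mfs = NULL) {
  if (is.null(dss)) {
    if (is.null(dag)) stop("either dag or dss must be supplied")
    dss_full <- disease_semantic_similarity(dag)
    miss <- setdiff(assoc$disease_ids, dss_full$ids)
    if (length(miss)) stop("diseases missing from DAG: ",
                           paste(miss, collapse = ", "))
    dss <- similarity_matrix(assoc$disease_ids,
                             dss_full$values[assoc$disease_ids,
                                             assoc$disease_ids],
                             kind = "DSS")
  }
  if (is.null(mfs)) {
    mfs <- mirna_functional_similarity(dss, assoc)
  } else if (!identical(mfs$ids, assoc$mirna_ids)) {
    mfs <- similarity_matrix(assoc$mirna_ids,
                             mfs$values[assoc$mirna_ids, assoc$mirna_ids],
                             kind = "MFS")
  }
  mgs <- gip_similarity(assoc, "mirna")
  dgs <- gip_similarity(assoc, "disease")
  MF <- aggregate_similarity(mfs, mgs)
  DF <- aggregate_similarity(dss, dgs)
  gm <- similarity_adjacency(mfs, cfg$sim_threshold)
  gd <- similarity_adjacency(dss, cfg$sim_threshold)
  graph <- hetero_graph(assoc, cfg$spd_clip)
  Ahat_m <- sym_norm_adjacency(gm)
  Ahat_d <- sym_norm_adjacency(gd)
  AXm <- MF$values
  AXd <- DF$values
  for (i in seq_len(cfg$gcn_layers)) {
    AXm <- Ahat_m %*% AXm
    AXd <- Ahat_d %*% AXd
  }
  structure(list(
    assoc = assoc, sims = list(dss = dss, mfs = mfs, mgs = mgs, dgs = dgs),
    MF = MF$values, DF = DF$values, gm = gm, gd = gd, graph = graph,
    AXm = AXm, AXd = AXd,
    att_mask = attention_mask(graph$adjacency),
    spd_idx = graph$spd + 1L,
    deg_idx = degree_bucket(graph$degrees, cfg$degree_max_bucket) + 1L,
    M = graph$M, N = graph$N,
    mirna_ids = assoc$mirna_ids, disease_ids = assoc$disease_ids
  ), class = "mda_inputs")
}

# ---- GAT channel ----------------------------------------------------------

.fw_gcn <- function(tape, pn, feats, cfg, training) {
  if (cfg$gat_gcn) {
    Xm <- ad_const(tape, feats$AXm)
    Xd <- ad_const(tape, feats$AXd)
  } else {
    Xm <- ad_const(tape, feats$MF)
    Xd <- ad_const(tape, feats$DF)
  }
  Hm <- ad_elu(ad_add_bias(ad_matmul(Xm, pn$gcn_Wm), pn$gcn_bm))
  Hd <- ad_elu(ad_add_bias(ad_matmul(Xd, pn$gcn_Wd), pn$gcn_bd))
  ad_rbind(list(Hm, Hd))
}

.fw_gat_layer <- function(tape, pn, H, mask, cfg, i) {
  n <- nrow(H$value)
  ones_row <- ad_const(tape, matrix(1, 1L, n))
  ones_col <- ad_const(tape, matrix(1, n, 1L))
  heads <- vector("list", cfg$gat_heads)
  atts <- vector("list", cfg$gat_heads)
  for (k in seq_len(cfg$gat_heads)) {
    S <- ad_matmul(H, pn[[sprintf("gat_W_%d_%d", i, k)]])
    f1 <- ad_matmul(S, pn[[sprintf("gat_a1_%d_%d", i, k)]])
    f2 <- ad_matmul(S, pn[[sprintf("gat_a2_%d_%d", i, k)]])
    E <- ad_leakyrelu(ad_add(ad_matmul(f1, ones_row),
                             ad_matmul(ones_col, ad_t(f2))),
                      cfg$negative_slope)
    P <- ad_rowsoftmax(E, mask = mask)
    heads[[k]] <- ad_elu(ad_matmul(P, S))
    atts[[k]] <- P
  }
  list(out = ad_cbind(heads), attention = atts)
}

.fw_gat <- function(tape, pn, feats, cfg, training) {
  H <- .drop_node(.fw_gcn(tape, pn, feats, cfg, training), cfg$dropout, training)
  outs <- vector("list", cfg$gat_layers)
  for (i in seq_len(cfg$gat_layers)) {
    res <- .fw_gat_layer(tape, pn, H, feats$att_mask, cfg, i)
    outs[[i]] <- res$out
    H <- .drop_node(res$out, cfg$dropout, training)
  }
  if (cfg$gat_jk) {
    ad_add_bias(ad_matmul(ad_cbind(outs), pn$jk_W), pn$jk_b)
  } else {
    outs[[cfg$gat_layers]]
  }
}

# ---- transformer channel --------------------------------------------------

.fw_trf_input <- function(tape, pn, feats, cfg) {
  Fm <- ad_add_bias(ad_matmul(ad_const(tape, feats$MF), pn$trf_Wpm), pn$trf_bpm)
  Fd <- ad_add_bias(ad_matmul(ad_const(tape, feats$DF), pn$trf_Wpd), pn$trf_bpd)
  F0 <- ad_rbind(list(Fm, Fd))
  if (cfg$trf_graph_attrs)
    F0 <- ad_add(F0, ad_gather_rows(pn$trf_Edeg, feats$deg_idx))
  F0
}

.fw_trf_mh <- function(tape, pn, Fn, feats, cfg, i) {
  hd <- cfg$embed_dim %/% cfg$trf_heads
  heads <- vector("list", cfg$trf_heads)
  atts <- vector("list", cfg$trf_heads)
  for (u in seq_len(cfg$trf_heads)) {
    Q <- ad_matmul(Fn, pn[[sprintf("trf_Wq_%d_%d", i, u)]])
    K <- ad_matmul(Fn, pn[[sprintf("trf_Wk_%d_%d", i, u)]])
    V <- ad_matmul(Fn, pn[[sprintf("trf_Wv_%d_%d", i, u)]])
    logits <- ad_scale(ad_matmul(Q, ad_t(K)), 1 / sqrt(hd))
    if (cfg$trf_graph_attrs) {
      bnm <- if (cfg$spd_bias_per_head) sprintf("trf_Bspd_%d_%d", i, u)
             else sprintf("trf_Bspd_%d", i)
      logits <- ad_add(logits, ad_bucket_bias(pn[[bnm]], feats$spd_idx))
    }
    if (!all(is.finite(logits$value)))
      stop("non-finite attention logits in transformer layer ", i)
    P <- ad_rowsoftmax(logits)
    heads[[u]] <- ad_matmul(P, V)
    atts[[u]] <- P
  }
  out <- ad_add_bias(ad_matmul(ad_cbind(heads), pn[[sprintf("trf_WO_%d", i)]]),
                     pn[[sprintf("trf_bO_%d", i)]])
  list(out = out, attention = atts)
}

.fw_trf_ffn <- function(tape, pn, H, cfg, i, training) {
  Hh <- ad_relu(ad_add_bias(ad_matmul(H, pn[[sprintf("trf_Wf1_%d", i)]]),
                            pn[[sprintf("trf_bf1_%d", i)]]))
  ad_add_bias(ad_matmul(Hh, pn[[sprintf("trf_Wf2_%d", i)]]),
              pn[[sprintf("trf_bf2_%d", i)]])
}

.fw_trf_layer <- function(tape, pn, Fn, feats, cfg, i, training) {
  mh <- .fw_trf_mh(tape, pn, Fn, feats, cfg, i)
  MH <- .drop_node(mh$out, cfg$dropout, training)
  ln1g <- pn[[sprintf("trf_ln1g_%d", i)]]
  ln1b <- pn[[sprintf("trf_ln1b_%d", i)]]
  if (cfg$strict_post_ln) {
    # literal reading: H = FNN(LN(MultiHead(F))), no residual paths
    H1 <- ad_layernorm(MH, ln1g, ln1b)
    return(.fw_trf_ffn(tape, pn, H1, cfg, i, training))
  }
  H1 <- ad_layernorm(ad_add(Fn, MH), ln1g, ln1b)
  F2 <- .drop_node(.fw_trf_ffn(tape, pn, H1, cfg, i, training),
                   cfg$dropout, training)
  ad_layernorm(ad_add(H1, F2),
               pn[[sprintf("trf_ln2g_%d", i)]],
               pn[[sprintf("trf_ln2b_%d", i)]])
}

.fw_trf <- function(tape, pn, feats, cfg, training) {
  Fn <- .fw_trf_input(tape, pn, feats, cfg)
  for (i in seq_len(cfg$trf_layers))
    Fn <- .fw_trf_layer(tape, pn, Fn, feats, cfg, i, training)
  Fn
}

# ---- fusion and scoring ---------------------------------------------------

.fw_fuse <- function(tape, pn, HG, HT, cfg) {
  if (is.null(HG)) return(HT)
  if (is.null(HT)) return(HG)
  switch(cfg$fusion,
         max = ad_pmax(HG, HT),
         mean = ad_scale(ad_add(HG, HT), 0.5),
         add = ad_add(HG, HT),
         dot = ad_hadamard(HG, HT),
         lin = ad_add_bias(ad_matmul(ad_cbind(list(HG, HT)), pn$fuse_W),
                           pn$fuse_b))
}

.fw_score <- function(tape, pn, fused, mi, dj, M, cfg, training) {
  rm_ <- ad_gather_rows(fused, mi)
  rd_ <- ad_gather_rows(fused, M + dj)
  if (cfg$scorer == "mlp") {
    X <- ad_cbind(list(rm_, rd_))
    Hh <- ad_relu(ad_add_bias(ad_matmul(X, pn$mlp_W1), pn$mlp_b1))
    Hh <- .drop_node(Hh, cfg$dropout, training)
    ad_add_bias(ad_matmul(Hh, pn$mlp_w2), pn$mlp_b2)
  } else {
    ad_matmul(ad_hadamard(rm_, rd_),
              ad_const(tape, matrix(1, ncol(fused$value), 1L)))
  }
}

# Full forward pass. mi/dj are 1-based indices into the miRNA / disease
# registries; labels (0/1) turn on the loss node.
model_forward <- function(params, feats, cfg, mi, dj, labels = NULL,
                          training = FALSE) {
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  HG <- if ("gat" %in% cfg$channels) .fw_gat(tape, pn, feats, cfg, training)
        else NULL
  HT <- if ("trf" %in% cfg$channels) .fw_trf(tape, pn, feats, cfg, training)
        else NULL
  fused <- .fw_fuse(tape, pn, HG, HT, cfg)
  logits <- .fw_score(tape, pn, fused, mi, dj, feats$M, cfg, training)
  loss <- if (!is.null(labels)) ad_bce_logits(logits, labels) else NULL
  list(tape = tape, pn = pn, HG = HG, HT = HT, fused = fused,
       logits = logits, loss = loss)
}

model_gradients <- function(fwd) {
  ad_backward(fwd$loss)
  lapply(fwd$pn, function(nd) nd$grad)
}

# ---- exported operation wrappers (evaluation mode) ------------------------

.as_rows <- function(x) if (inherits(x, "mda_embeddings")) x$rows else as.matrix(x)
.as_values <- function(x) if (inherits(x, "mda_sim")) x$values else as.matrix(x)
.as_adj <- function(g) if (inherits(g, "mda_graph")) g$adjacency else as.matrix(g)

#' GCN pre-encoding of the similarity networks
#'
#' Propagates each node family's aggregated similarity features over its own
#' similarity adjacency with the symmetric-normalised convolution (self-loops
#' added), projects both families to the common embedding width and stacks
#' them miRNAs-then-diseases.
#'
#' @param mf,df Aggregated feature matrices (`mda_sim` of kind `MF` / `DF`,
#'   or plain matrices).
#' @param gm,gd Binary similarity adjacencies from [similarity_adjacency()].
#' @param params Model parameters from [init_model_params()].
#' @param cfg An [mda_config()].
#' @return An [node_embeddings()] of channel `"GAT"` (the pre-encoding).
#' @export
gcn_preencode <- function(mf, df, gm, gd, params, cfg = mda_config()) {
  MFv <- .as_values(mf); DFv <- .as_values(df)
  AXm <- MFv; AXd <- DFv
  Am <- sym_norm_adjacency(as.matrix(gm)); Ad <- sym_norm_adjacency(as.matrix(gd))
  for (i in seq_len(cfg$gcn_layers)) { AXm <- Am %*% AXm; AXd <- Ad %*% AXd }
  feats <- list(AXm = AXm, AXd = AXd, MF = MFv, DF = DFv)
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  out <- .fw_gcn(tape, pn, feats, cfg, training = FALSE)
  mids <- if (inherits(mf, "mda_sim")) mf$ids else paste0("m", seq_len(nrow(MFv)))
  dids <- if (inherits(df, "mda_sim")) df$ids else paste0("d", seq_len(nrow(DFv)))
  node_embeddings(mids, dids, out$value, channel = "GAT")
}

#' Graph-attention coefficients
#'
#' Per-head attention matrices over the heterogeneous graph: logits
#' `LeakyReLU(a^T [W h_i || W h_j])` on edges, softmax-normalised over each
#' node's neighbourhood (row-stochastic on the neighbourhood; zero
#' elsewhere). Isolated nodes attend to themselves.
#'
#' @param features Node feature matrix or [node_embeddings()].
#' @param g An `mda_graph` or binary adjacency matrix.
#' @param params Model parameters.
#' @param cfg An [mda_config()].
#' @param layer GAT layer index whose parameters are used.
#' @return List of `cfg$gat_heads` attention matrices.
#' @export
gat_attention <- function(features, g, params, cfg = mda_config(), layer = 1L) {
  X <- .as_rows(features)
  mask <- attention_mask(.as_adj(g))
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  H <- ad_const(tape, X)
  res <- .fw_gat_layer(tape, pn, H, mask, cfg, layer)
  lapply(res$attention, function(p) p$value)
}

#' One multi-head graph-attention layer
#'
#' Per head, neighbours' transformed features are combined with the
#' [gat_attention()] coefficients; heads are activated (ELU) and
#' concatenated to the configured embedding width.
#'
#' @inheritParams gat_attention
#' @return Numeric matrix of shape `nodes x embed_dim`.
#' @export
gat_layer <- function(features, g, params, cfg = mda_config(), layer = 1L) {
  X <- .as_rows(features)
  mask <- attention_mask(.as_adj(g))
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  res <- .fw_gat_layer(tape, pn, ad_const(tape, X), mask, cfg, layer)
  res$out$value
}

#' Jumping-knowledge merge of GAT layer outputs
#'
#' Concatenates the per-layer embeddings along the feature axis and applies
#' the learned linear map back to the embedding width.
#'
#' @param layer_outputs List of matrices with equal row counts.
#' @param params Model parameters (uses `jk_W`, `jk_b`).
#' @return Numeric matrix `nodes x embed_dim`.
#' @export
jumping_knowledge_merge <- function(layer_outputs, params) {
  mats <- lapply(layer_outputs, .as_rows)
  rc <- vapply(mats, nrow, integer(1))
  if (length(unique(rc)) != 1L) stop("layer outputs disagree on row count")
  X <- do.call(cbind, mats)
  if (ncol(X) != nrow(params$jk_W)) stop("concatenated width does not match jk_W")
  sweep(X %*% params$jk_W, 2L, as.numeric(params$jk_b), "+")
}

#' Transformer input features with degree encoding
#'
#' Separate learned projections of the miRNA and disease feature matrices,
#' stacked along the node axis, plus the degree-bucket embedding row of each
#' node.
#'
#' @param mf,df Aggregated feature matrices (`MF`, `DF`).
#' @param degrees Integer degree vector over miRNAs-then-diseases.
#' @param params Model parameters.
#' @param cfg An [mda_config()].
#' @return Numeric matrix `(M+N) x embed_dim`.
#' @export
build_input_features <- function(mf, df, degrees, params, cfg = mda_config()) {
  feats <- list(MF = .as_values(mf), DF = .as_values(df),
                deg_idx = degree_bucket(degrees, cfg$degree_max_bucket) + 1L)
  if (nrow(feats$MF) + nrow(feats$DF) != length(degrees))
    stop("degrees not aligned to miRNAs-then-diseases stacking")
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  .fw_trf_input(tape, pn, feats, cfg)$value
}

#' Scaled dot-product attention with a shortest-path bias
#'
#' Single-head attention `softmax(Q K^T / sqrt(d) + B) V` where `B[i, j]` is
#' a scalar looked up by the SPD bucket of the pair: distance 0..`spd_clip`
#' maps to its own bucket and the unreachable sentinel `spd_clip + 1` to the
#' last one. `spd_bias = NULL` (or all zeros) reduces exactly to plain scaled
#' dot-product attention.
#'
#' @param fmd Input feature matrix (`nodes x d`).
#' @param spd Clipped SPD matrix from [shortest_path_matrix()].
#' @param Wq,Wk,Wv Projection matrices (`d x d_head`).
#' @param spd_bias Optional numeric vector of length `spd_clip + 2`.
#' @param spd_clip Clip used to build `spd`.
#' @return List with `output` (`nodes x d_head`) and `attention`
#'   (row-stochastic matrix).
#' @export
structural_attention <- function(fmd, spd, Wq, Wk, Wv, spd_bias = NULL,
                                 spd_clip = max(spd)) {
  Fv <- .as_rows(fmd)
  Q <- Fv %*% Wq; K <- Fv %*% Wk; V <- Fv %*% Wv
  logits <- tcrossprod(Q, K) / sqrt(ncol(Q))
  if (!is.null(spd_bias)) {
    idx <- pmin(spd, spd_clip + 1L) + 1L
    if (max(idx) > length(spd_bias)) stop("spd_bias too short for SPD buckets")
    logits <- logits + matrix(spd_bias[idx], nrow(spd), ncol(spd))
  }
  if (!all(is.finite(logits))) stop("non-finite attention logits")
  z <- logits - apply(logits, 1L, max)
  P <- exp(z); P <- P / rowSums(P)
  list(output = P %*% V, attention = P)
}

#' Multi-head structurally biased self-attention
#'
#' Runs the configured number of heads with their distinct projections in
#' parallel, concatenates them and applies the output projection.
#'
#' @param fmd Input feature matrix (`nodes x embed_dim`).
#' @param spd Clipped SPD matrix.
#' @param params Model parameters.
#' @param cfg An [mda_config()].
#' @param layer Transformer layer index.
#' @return Numeric matrix `nodes x embed_dim`.
#' @export
multi_head <- function(fmd, spd, params, cfg = mda_config(), layer = 1L) {
  feats <- list(spd_idx = pmin(spd, cfg$spd_clip + 1L) + 1L)
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  Fn <- ad_const(tape, .as_rows(fmd))
  .fw_trf_mh(tape, pn, Fn, feats, cfg, layer)$out$value
}

#' Transformer encoder stack
#'
#' Applies `cfg$trf_layers` encoder layers to prepared input features: each
#' layer is multi-head structurally biased attention and a two-linear-layer
#' ReLU feed-forward block, with post-sub-layer layer normalisation
#' (residual connections unless `cfg$strict_post_ln`). With zero layers this
#' is the identity.
#'
#' @inheritParams multi_head
#' @return Numeric matrix `nodes x embed_dim` (the `TRF` channel embedding).
#' @export
transformer_encode <- function(fmd, spd, params, cfg = mda_config()) {
  feats <- list(spd_idx = pmin(spd, cfg$spd_clip + 1L) + 1L)
  tape <- ad_tape()
  pn <- lapply(params, function(x) ad_param(tape, x))
  Fn <- ad_const(tape, .as_rows(fmd))
  for (i in seq_len(cfg$trf_layers))
    Fn <- .fw_trf_layer(tape, pn, Fn, feats, cfg, i, training = FALSE)
  Fn$value
}

#' Fuse the two channel embeddings
#'
#' Default elementwise maximum pooling keeps, per position, the stronger of
#' the two channel activations; `lin`, `dot`, `mean` and `add` implement the
#' linear-map, elementwise-product, mean-pooling and summation variants.
#'
#' @param h_gat,h_trf [node_embeddings()] (or matrices) of equal shape.
#' @param mode Fusion mode.
#' @param params Model parameters (needed for `mode = "lin"`).
#' @return Fused embeddings, same type as the inputs.
#' @export
fuse_embeddings <- function(h_gat, h_trf,
                            mode = c("max", "lin", "dot", "mean", "add"),
                            params = NULL) {
  mode <- match.arg(mode)
  A <- .as_rows(h_gat); B <- .as_rows(h_trf)
  if (!identical(dim(A), dim(B))) stop("channel embeddings differ in shape")
  V <- switch(mode,
              max = pmax(A, B),
              mean = (A + B) / 2,
              add = A + B,
              dot = A * B,
              lin = {
                if (is.null(params$fuse_W)) stop("mode 'lin' needs fuse_W/fuse_b")
                sweep(cbind(A, B) %*% params$fuse_W, 2L,
                      as.numeric(params$fuse_b), "+")
              })
  if (inherits(h_gat, "mda_embeddings"))
    node_embeddings(h_gat$mirna_ids, h_gat$disease_ids, V, channel = "FUSED")
  else V
}

#' Score miRNA-disease pairs from fused embeddings
#'
#' Concatenates the miRNA and disease embedding rows of each pair and runs
#' them through the one-hidden-layer ReLU MLP with a sigmoid output (or an
#' inner product under `cfg$scorer = "dot"`).
#'
#' @param fused A `"FUSED"` [node_embeddings()].
#' @param pairs data.frame of (mirna id, disease id).
#' @param params Model parameters.
#' @param cfg An [mda_config()].
#' @param labels Optional 0/1 vector attached to the result.
#' @return A [pair_scores()] object.
#' @export
pair_score <- function(fused, pairs, params, cfg = mda_config(),
                       labels = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  mi <- match(as.character(pairs[[1L]]), fused$mirna_ids)
  dj <- match(as.character(pairs[[2L]]), fused$disease_ids)
  if (anyNA(mi)) stop("unknown miRNA id in pairs")
  if (anyNA(dj)) stop("unknown disease id in pairs")
  M <- length(fused$mirna_ids)
  if (cfg$scorer == "mlp") {
    X <- cbind(fused$rows[mi, , drop = FALSE],
               fused$rows[M + dj, , drop = FALSE])
    Hh <- pmax(sweep(X %*% params$mlp_W1, 2L, as.numeric(params$mlp_b1), "+"), 0)
    z <- as.numeric(Hh %*% params$mlp_w2) + params$mlp_b2[1L, 1L]
  } else {
    z <- rowSums(fused$rows[mi, , drop = FALSE] *
                 fused$rows[M + dj, , drop = FALSE])
  }
  p <- 1 / (1 + exp(-z))
  eps <- 1e-7
  pair_scores(pairs, pmin(pmax(p, eps), 1 - eps), labels = labels)
}

#' Balanced binary cross-entropy loss
#'
#' Mean cross-entropy between labels and predicted probabilities, with
#' probabilities clamped to `[eps, 1 - eps]` to keep the logs finite.
#'
#' @param scores A labelled [pair_scores()] object.
#' @param eps Probability clamp (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(scores, eps = 1e-7) {
  if (is.null(scores$labels)) stop("bce_loss requires labels")
  p <- pmin(pmax(scores$probabilities, eps), 1 - eps)
  y <- scores$labels
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
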