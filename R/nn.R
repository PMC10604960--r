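# Parameter initialisation and the Adam optimiser. Parameters live in a flat
# named list of numeric matrices; every forward pass lifts them onto a fresh
# autodiff tape.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros <- function(nin, nout = 1L) matrix(0, nin, nout)

#' Initialise model parameters
#'
#' Creates every learnable tensor required by the configured channels:
#' GCN pre-encoder projections, per-layer per-head GAT attention parameters,
#' the jumping-knowledge merge, transformer input projections with the
#' degree-bucket embedding table, per-layer attention/FFN/layer-norm weights
#' with the SPD bias table, the fusion map (linear mode only) and the MLP
#' pair scorer. Weight matrices use Glorot-uniform initialisation; biases,
#' layer-norm offsets and structural-bias tables start at zero (layer-norm
#' gains at one). Draws from the current RNG state.
#'
#' @param cfg An [mda_config()].
#' @param M,N miRNA and disease counts.
#' @return Named list of numeric matrices (class `mda_params`).
#' @export
init_model_params <- function(cfg, M, N) {
  l <- cfg$embed_dim
  p <- list()
  if ("gat" %in% cfg$channels) {
    p$gcn_Wm <- glorot(M, l); p$gcn_bm <- zeros(1L, l)
    p$gcn_Wd <- glorot(N, l); p$gcn_bd <- zeros(1L, l)
    hd <- l %/% cfg$gat_heads
    for (i in seq_len(cfg$gat_layers)) {
      for (k in seq_len(cfg$gat_heads)) {
        p[[sprintf("gat_W_%d_%d", i, k)]] <- glorot(l, hd)
        p[[sprintf("gat_a1_%d_%d", i, k)]] <- glorot(hd, 1L)
        p[[sprintf("gat_a2_%d_%d", i, k)]] <- glorot(hd, 1L)
      }
    }
    if (cfg$gat_jk) {
      p$jk_W <- glorot(cfg$gat_layers * l, l); p$jk_b <- zeros(1L, l)
    }
  }
  if ("trf" %in% cfg$channels) {
    p$trf_Wpm <- glorot(M, l); p$trf_bpm <- zeros(1L, l)
    p$trf_Wpd <- glorot(N, l); p$trf_bpd <- zeros(1L, l)
    if (cfg$trf_graph_attrs) {
      p$trf_Edeg <- matrix(stats::rnorm((cfg$degree_max_bucket + 1L) * l,
                                        sd = 0.02),
                           cfg$degree_max_bucket + 1L, l)
    }
    hd <- l %/% cfg$trf_heads
    nb <- cfg$spd_clip + 2L  # buckets 0..clip plus unreachable sentinel
    for (i in seq_len(cfg$trf_layers)) {
      for (u in seq_len(cfg$trf_heads)) {
        p[[sprintf("trf_Wq_%d_%d", i, u)]] <- glorot(l, hd)
        p[[sprintf("trf_Wk_%d_%d", i, u)]] <- glorot(l, hd)
        p[[sprintf("trf_Wv_%d_%d", i, u)]] <- glorot(l, hd)
        if (cfg$trf_graph_attrs && cfg$spd_bias_per_head)
          p[[sprintf("trf_Bspd_%d_%d", i, u)]] <- zeros(1L, nb)
      }
      if (cfg$trf_graph_attrs && !cfg$spd_bias_per_head)
        p[[sprintf("trf_Bspd_%d", i)]] <- zeros(1L, nb)
      p[[sprintf("trf_WO_%d", i)]] <- glorot(l, l)
      p[[sprintf("trf_bO_%d", i)]] <- zeros(1L, l)
      p[[sprintf("trf_ln1g_%d", i)]] <- matrix(1, 1L, l)
      p[[sprintf("trf_ln1b_%d", i)]] <- zeros(1L, l)
      p[[sprintf("trf_Wf1_%d", i)]] <- glorot(l, cfg$ffn_hidden)
      p[[sprintf("trf_bf1_%d", i)]] <- zeros(1L, cfg$ffn_hidden)
      p[[sprintf("trf_Wf2_%d", i)]] <- glorot(cfg$ffn_hidden, l)
      p[[sprintf("trf_bf2_%d", i)]] <- zeros(1L, l)
      if (!cfg$strict_post_ln) {
        p[[sprintf("trf_ln2g_%d", i)]] <- matrix(1, 1L, l)
        p[[sprintf("trf_ln2b_%d", i)]] <- zeros(1L, l)
      }
    }
  }
  if (cfg$fusion == "lin" && length(cfg$channels) == 2L) {
    p$fuse_W <- glorot(2L * l, l); p$fuse_b <- zeros(1L, l)
  }
  if (cfg$scorer == "mlp") {
    p$mlp_W1 <- glorot(2L * l, l); p$mlp_b1 <- zeros(1L, l)
    p$mlp_w2 <- glorot(l, 1L); p$mlp_b2 <- zeros(1L, 1L)
  }
  structure(p, class = "mda_params")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Per-node embedding container
#'
#' Dense embedding rows for all `M + N` nodes of the heterogeneous graph,
#' miRNAs first, as emitted by either encoder channel or their fusion.
#'
#' @param mirna_ids,disease_ids Node registries.
#' @param rows `(M+N) x width` numeric matrix.
#' @param channel One of `"GAT"`, `"TRF"`, `"FUSED"`.
#' @return Object of class `mda_embeddings`.
#' @export
node_embeddings <- function(mirna_ids, disease_ids, rows,
                            channel = c("FUSED", "GAT", "TRF")) {
  channel <- match.arg(channel)
  rows <- as.matrix(rows)
  if (nrow(rows) != length(mirna_ids) + length(disease_ids))
    stop("row count must equal M + N")
  if (!all(is.finite(rows))) stop("non-finite embedding rows")
  structure(list(mirna_ids = as.character(mirna_ids),
                 disease_ids = as.character(disease_ids),
                 rows = rows, width = ncol(rows), channel = channel),
            class = "mda_embeddings")
}

#' @export
print.mda_embeddings <- function(x, ...) {
  cat(sprintf("<mda_embeddings %s> %d nodes x %d dims\n", x$channel,
              nrow(x$rows), x$width))
  invisible(x)
}

#' Scored miRNA-disease pairs
#'
#' @param pairs data.frame with columns `mirna`, `disease`.
#' @param probabilities Numeric vector strictly inside `(0, 1)`.
#' @param labels Optional 0/1 ground-truth vector.
#' @return Object of class `mda_scores`.
#' @export
pair_scores <- function(pairs, probabilities, labels = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("mirna", "disease")
  if (length(probabilities) != nrow(pairs))
    stop("probabilities and pairs lengths differ")
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("probabilities must lie strictly within (0, 1)")
  if (!is.null(labels)) {
    if (length(labels) != nrow(pairs)) stop("labels and pairs lengths differ")
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  }
  structure(list(pairs = pairs, probabilities = as.numeric(probabilities),
                 labels = labels), class = "mda_scores")
}

#' @export
print.mda_scores <- function(x, ...) {
  cat(sprintf("<mda_scores> %d pairs%s, mean p = %.3f\n", nrow(x$pairs),
              if (is.null(x$labels)) "" else " (labelled)",
              mean(x$probabilities)))
  invisible(x)
}
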