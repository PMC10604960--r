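#' Model and training configuration
#'
#' Collects every tunable of the dual-channel model with defaults matching
#' the reference hyperparameter setting: 4 attention heads in both channels,
#' 512-dimensional embeddings, feed-forward hidden width 2048, shortest-path
#' clip 8, dropout 0.5 and Adam learning rate 1e-4.
#'
#' @param embed_dim Embedding width `l` shared by both channels (default 512).
#' @param gat_heads,trf_heads Attention heads per layer (default 4 each).
#' @param gat_layers,trf_layers Encoder depth per channel (default 2).
#' @param gcn_layers GCN pre-encoder depth for the GAT channel (default 1).
#' @param ffn_hidden Transformer feed-forward hidden width (default 2048).
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @param negative_slope LeakyReLU slope for GAT attention logits (default 0.2).
#' @param spd_clip Shortest-path clip `L` (default 8); unreachable pairs use
#'   bucket `L + 1`.
#' @param degree_max_bucket Degree-embedding clip (default 64).
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs Maximum training epochs (default 300).
#' @param patience Early-stopping patience in validation checks (default 30).
#' @param eval_every Validation-AUC check interval in epochs (default 1).
#' @param channels Character subset of `c("gat", "trf")`; both by default.
#' @param fusion One of `"max"`, `"lin"`, `"dot"`, `"mean"`, `"add"`.
#' @param sim_threshold Similarity-adjacency cutoff for `GM`/`GD` (default 0).
#' @param decay Semantic decay factor for the disease DAG (default 0.5).
#' @param gat_gcn Use the GCN pre-encoder (default TRUE; FALSE gives the
#'   vanilla-GAT ablation).
#' @param gat_jk Use jumping-knowledge layer merging (default TRUE).
#' @param trf_graph_attrs Use degree and SPD structural encodings (default
#'   TRUE; FALSE gives the plain-transformer ablation).
#' @param strict_post_ln Drop the residual connections around the transformer
#'   sub-layers (default FALSE keeps them).
#' @param spd_bias_per_head Learn a separate SPD bias table per attention head
#'   (default FALSE: shared).
#' @param scorer `"mlp"` (concatenated pair rows through a one-hidden-layer
#'   MLP) or `"dot"` (inner product).
#' @return A validated list of class `mda_config`.
#' @export
mda_config <- function(embed_dim = 512L, gat_heads = 4L, trf_heads = 4L,
                       gat_layers = 2L, trf_layers = 2L, gcn_layers = 1L,
                       ffn_hidden = 2048L, dropout = 0.5,
                       negative_slope = 0.2, spd_clip = 8L,
                       degree_max_bucket = 64L, lr = 1e-4,
                       epochs = 300L, patience = 30L, eval_every = 1L,
                       channels = c("gat", "trf"),
                       fusion = c("max", "lin", "dot", "mean", "add"),
                       sim_threshold = 0, decay = 0.5,
                       gat_gcn = TRUE, gat_jk = TRUE,
                       trf_graph_attrs = TRUE, strict_post_ln = FALSE,
                       spd_bias_per_head = FALSE,
                       scorer = c("mlp", "dot")) {
  fusion <- match.arg(fusion)
  scorer <- match.arg(scorer)
  cfg <- list(embed_dim = as.integer(embed_dim),
              gat_heads = as.integer(gat_heads),
              trf_heads = as.integer(trf_heads),
              gat_layers = as.integer(gat_layers),
              trf_layers = as.integer(trf_layers),
              gcn_layers = as.integer(gcn_layers),
              ffn_hidden = as.integer(ffn_hidden),
              dropout = dropout, negative_slope = negative_slope,
              spd_clip = as.integer(spd_clip),
              degree_max_bucket = as.integer(degree_max_bucket),
              lr = lr, epochs = as.integer(epochs),
              patience = as.integer(patience),
              eval_every = as.integer(eval_every),
              channels = channels, fusion = fusion,
              sim_threshold = sim_threshold, decay = decay,
              gat_gcn = isTRUE(gat_gcn), gat_jk = isTRUE(gat_jk),
              trf_graph_attrs = isTRUE(trf_graph_attrs),
              strict_post_ln = isTRUE(strict_post_ln),
              spd_bias_per_head = isTRUE(spd_bias_per_head),
              scorer = scorer)
  validate_config(cfg)
  structure(cfg, class = "mda_config")
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (cfg$gat_heads < 1L || cfg$embed_dim %% cfg$gat_heads != 0L)
    bad <- c(bad, "embed_dim must be divisible by gat_heads (>= 1)")
  if (cfg$trf_heads < 1L || cfg$embed_dim %% cfg$trf_heads != 0L)
    bad <- c(bad, "embed_dim must be divisible by trf_heads (>= 1)")
  if (cfg$dropout < 0 || cfg$dropout >= 1) bad <- c(bad, "dropout must be in [0, 1)")
  if (cfg$ffn_hidden < cfg$embed_dim) bad <- c(bad, "ffn_hidden must be >= embed_dim")
  if (cfg$spd_clip < 1L) bad <- c(bad, "spd_clip must be >= 1")
  if (cfg$lr <= 0) bad <- c(bad, "lr must be positive")
  if (!length(cfg$channels) || !all(cfg$channels %in% c("gat", "trf")))
    bad <- c(bad, "channels must be a nonempty subset of {gat, trf}")
  if (cfg$sim_threshold < 0 || cfg$sim_threshold >= 1)
    bad <- c(bad, "sim_threshold must be in [0, 1)")
  if (cfg$decay <= 0 || cfg$decay > 1) bad <- c(bad, "decay must be in (0, 1]")
  if (length(bad)) stop("invalid configuration:\n  - ",
                        paste(bad, collapse = "\n  - "))
  invisible(cfg)
}

#' Desk-scale configuration profile
#'
#' A reduced profile for laptop/CI-scale experiments on the synthetic
#' block-model data: 32-dimensional embeddings, feed-forward width 64, two
#' heads and one layer per channel, dropout 0.1, Adam at 2e-3 for at most 120
#' epochs with early stopping. Chosen once from convergence traces at desk
#' scale; the full-scale defaults of [mda_config()] are impractical without
#' GPU-backed tensor libraries.
#'
#' @param ... Overrides forwarded to [mda_config()].
#' @return An `mda_config`.
#' @export
mda_desk_config <- function(...) {
  defaults <- list(embed_dim = 32L, ffn_hidden = 64L, gat_heads = 2L,
                   trf_heads = 2L, gat_layers = 1L, trf_layers = 1L,
                   dropout = 0.1, lr = 2e-3, epochs = 120L, patience = 5L,
                   eval_every = 10L, sim_threshold = 0.5)
  do.call(mda_config, utils::modifyList(defaults, list(...)))
}

#' Ablation variants of the model
#'
#' Named configuration overrides for the standard degenerate models:
#' `dae_a` (plain transformer channel, graph attributes zeroed), `dae_b`
#' (vanilla GAT channel: no GCN pre-encoding, no jumping knowledge), `dae_c`
#' (graph-attention channel only) and `dae_d` (self-attention channel only).
#'
#' @param cfg A base [mda_config()].
#' @param variant One of `"dae_a"`, `"dae_b"`, `"dae_c"`, `"dae_d"`, `"full"`.
#' @return A modified `mda_config`.
#' @export
config_variant <- function(cfg, variant = c("full", "dae_a", "dae_b",
                                            "dae_c", "dae_d")) {
  variant <- match.arg(variant)
  out <- unclass(cfg)
  switch(variant,
    full = NULL,
    dae_a = { out$channels <- "trf"; out$trf_graph_attrs <- FALSE },
    dae_b = { out$channels <- "gat"; out$gat_gcn <- FALSE; out$gat_jk <- FALSE },
    dae_c = { out$channels <- "gat" },
    dae_d = { out$channels <- "trf" })
  validate_config(out)
  structure(out, class = "mda_config")
}
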