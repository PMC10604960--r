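#' Sample negative miRNA-disease pairs
#'
#' Uniformly samples `n` distinct zero cells of the association matrix
#' without replacement; reproducible for a given seed.
#'
#' @param assoc An [association_matrix()].
#' @param n Number of negatives (typically the number of positives, giving a
#'   balanced set).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `mirna`, `disease`.
#' @export
sample_negatives <- function(assoc, n, seed) {
  zero_cells <- which(assoc$entries == 0)
  if (n > length(zero_cells))
    stop("requested ", n, " negatives but only ", length(zero_cells),
         " zero cells exist")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- sample(zero_cells, n)
  M <- nrow(assoc$entries)
  ri <- ((pick - 1L) %% M) + 1L
  ci <- ((pick - 1L) %/% M) + 1L
  data.frame(mirna = assoc$mirna_ids[ri], disease = assoc$disease_ids[ci],
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Balanced labelled edge set
#'
#' @param positives,negatives data.frames of (mirna, disease) pairs;
#'   must be disjoint and of equal size.
#' @param seed Seed recorded for provenance.
#' @return Object of class `mda_edges`.
#' @export
labeled_edge_set <- function(positives, negatives, seed = NA_integer_) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)[, 1:2]
  negatives <- as.data.frame(negatives, stringsAsFactors = FALSE)[, 1:2]
  names(positives) <- names(negatives) <- c("mirna", "disease")
  key <- function(df) paste(df$mirna, df$disease, sep = "\r")
  if (length(intersect(key(positives), key(negatives))))
    stop("positives and negatives overlap")
  if (nrow(positives) != nrow(negatives))
    stop("positive and negative sets must be balanced")
  structure(list(positives = positives, negatives = negatives, seed = seed),
            class = "mda_edges")
}

.edges_df <- function(edges) {
  rbind(cbind(edges$positives, label = 1),
        cbind(edges$negatives, label = 0))
}

#' Stratified five-fold split
#'
#' Partitions the balanced edge set into five folds, stratified by label so
#' every fold is (up to one sample) half positive.
#'
#' @param edges An [labeled_edge_set()].
#' @param seed Integer RNG seed.
#' @param k Number of folds (default 5).
#' @return List of `k` data.frames (columns `mirna`, `disease`, `label`).
#' @export
five_fold_split <- function(edges, seed, k = 5L) {
  df <- .edges_df(edges)
  if (nrow(df) < k) stop("need at least ", k, " labelled pairs")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(nrow(df))
  for (lab in c(1, 0)) {
    idx <- which(df$label == lab)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) df[fold == f, , drop = FALSE])
}

#' Stratified independent train/test split
#'
#' @param edges An [labeled_edge_set()].
#' @param test_fraction Fraction held out, in (0, 1); per-label rounding.
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` data.frames.
#' @export
independent_split <- function(edges, test_fraction, seed) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  df <- .edges_df(edges)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- integer(0)
  for (lab in c(1, 0)) {
    idx <- which(df$label == lab)
    n_test <- round(length(idx) * test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = df[-test_idx, , drop = FALSE],
       test = df[test_idx, , drop = FALSE])
}

#' Classification and ranking metrics
#'
#' Confusion counts at the decision threshold, accuracy, F1, precision
#' (`TP / (TP + FP)`), recall (`TP / (TP + FN)`), rank-statistic AUC (tied
#' scores count 1/2) and step-integrated AUPR.
#'
#' @param scores A labelled [pair_scores()] object, or a list with elements
#'   `probabilities` and `labels`.
#' @param threshold Decision cutoff in (0, 1), default 0.5.
#' @return List of class `mda_eval` with `auc`, `aupr`, `acc`, `f1`,
#'   `precision`, `recall`, `confusion` (TP/FP/TN/FN) and `threshold`.
#' @export
evaluate_scores <- function(scores, threshold = 0.5) {
  p <- scores$probabilities
  y <- scores$labels
  if (is.null(y)) stop("evaluate_scores requires labels")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: labels contain a single class")
  pred <- as.integer(p >= threshold)
  TP <- sum(pred == 1 & y == 1); FP <- sum(pred == 1 & y == 0)
  TN <- sum(pred == 0 & y == 0); FN <- sum(pred == 0 & y == 1)
  r <- rank(p)
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(p, decreasing = TRUE)
  ys <- y[o]; ps <- p[o]
  tp <- cumsum(ys)
  prec <- tp / seq_along(ys)
  rec <- tp / npos
  last <- c(ps[-1L] != ps[-length(ps)], TRUE)  # keep end of each tie group
  prec <- prec[last]; rec <- rec[last]
  aupr <- sum(diff(c(0, rec)) * prec)
  metrics_from_confusion(TP, FP, TN, FN, auc = auc, aupr = aupr,
                         threshold = threshold)
}

#' Metrics from explicit confusion counts
#'
#' @param TP,FP,TN,FN Confusion counts.
#' @param auc,aupr Optional ranking metrics to carry through.
#' @param threshold Decision cutoff recorded in the report.
#' @return List of class `mda_eval`.
#' @export
metrics_from_confusion <- function(TP, FP, TN, FN, auc = NA_real_,
                                   aupr = NA_real_, threshold = 0.5) {
  total <- TP + FP + TN + FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(auc = auc, aupr = aupr, acc = (TP + TN) / total, f1 = f1,
                 precision = precision, recall = recall,
                 confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 threshold = threshold),
            class = "mda_eval")
}

#' @export
print.mda_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f  AUPR %.4f  ACC %.4f  F1 %.4f  Prec %.4f  Rec %.4f\n",
              x$auc, x$aupr, x$acc, x$f1, x$precision, x$recall))
  invisible(x)
}

# ---- training -------------------------------------------------------------

.pair_indices <- function(df, mirna_ids, disease_ids) {
  mi <- match(df$mirna, mirna_ids)
  dj <- match(df$disease, disease_ids)
  if (anyNA(mi) || anyNA(dj)) stop("pair identifiers missing from registries")
  list(mi = mi, dj = dj, y = df$label)
}

#' Train the dual-channel model
#'
#' Full-batch Adam optimisation of the balanced cross-entropy over the
#' training pairs, on model inputs built strictly from the training-fold
#' association matrix. When validation pairs are supplied, training stops
#' early once validation AUC fails to improve for `cfg$patience` consecutive
#' checks, and the best-AUC parameters are restored.
#'
#' @param feats Model inputs from [build_model_inputs()] (built from the
#'   training associations only).
#' @param train_df data.frame with columns `mirna`, `disease`, `label`.
#' @param cfg An [mda_config()].
#' @param seed Integer seed controlling initialisation and dropout.
#' @param val_df Optional validation data.frame (same columns).
#' @param verbose Print per-epoch progress.
#' @return An `mda_model`: list with `params`, `cfg`, `feats`, `history`.
#' @export
mda_train <- function(feats, train_df, cfg = mda_config(), seed = 0L,
                      val_df = NULL, verbose = FALSE) {
  if (nrow(train_df) == 0L) stop("no training pairs supplied")
  if (sum(feats$graph$adjacency) == 0) stop("training graph has no edges")
  tr <- .pair_indices(train_df, feats$mirna_ids, feats$disease_ids)
  va <- if (!is.null(val_df) && nrow(val_df))
    .pair_indices(val_df, feats$mirna_ids, feats$disease_ids) else NULL
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- init_model_params(cfg, feats$M, feats$N)
  state <- adam_init(params)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  stale <- 0L
  losses <- numeric(0)
  val_auc <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    fwd <- model_forward(params, feats, cfg, tr$mi, tr$dj, labels = tr$y,
                         training = TRUE)
    loss <- fwd$loss$value[1L, 1L]
    if (!is.finite(loss)) stop("training diverged: non-finite loss at epoch ",
                               epoch)
    grads <- model_gradients(fwd)
    upd <- adam_step(params, grads, state, cfg$lr)
    params <- upd$params; state <- upd$state
    losses[epoch] <- loss
    if (!is.null(va) && (epoch %% cfg$eval_every == 0L)) {
      ev <- model_forward(params, feats, cfg, va$mi, va$dj, training = FALSE)
      pva <- 1 / (1 + exp(-as.numeric(ev$logits$value)))
      r <- rank(pva); npos <- sum(va$y == 1); nneg <- sum(va$y == 0)
      auc <- (sum(r[va$y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
      val_auc <- c(val_auc, auc)
      if (auc > best$auc + 1e-5) {
        best <- list(auc = auc, params = params, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
      if (verbose) message(sprintf("epoch %d loss %.4f val AUC %.4f",
                                   epoch, loss, auc))
    } else if (verbose) {
      message(sprintf("epoch %d loss %.4f", epoch, loss))
    }
  }
  if (!is.null(va) && is.finite(best$auc)) params <- best$params
  structure(list(params = params, cfg = cfg, feats = feats,
                 history = list(loss = losses, val_auc = val_auc,
                                best_epoch = best$epoch, seed = seed)),
            class = "mda_model")
}

#' @export
print.mda_model <- function(x, ...) {
  cat(sprintf("<mda_model> channels {%s}, fusion %s, %d epochs trained\n",
              paste(x$cfg$channels, collapse = ","), x$cfg$fusion,
              length(x$history$loss)))
  invisible(x)
}

#' Node embeddings of a trained model
#' @param model An `mda_model`.
#' @return List with `fused`, and per-channel `gat` / `trf`
#'   [node_embeddings()] where the channel is enabled.
#' @export
model_embeddings <- function(model) {
  fwd <- model_forward(model$params, model$feats, model$cfg,
                       mi = 1L, dj = 1L, training = FALSE)
  mk <- function(nd, ch) if (is.null(nd)) NULL else
    node_embeddings(model$feats$mirna_ids, model$feats$disease_ids,
                    nd$value, channel = ch)
  list(fused = mk(fwd$fused, "FUSED"), gat = mk(fwd$HG, "GAT"),
       trf = mk(fwd$HT, "TRF"))
}

#' Score miRNA-disease pairs with a trained model
#'
#' @param object An `mda_model`.
#' @param pairs data.frame of (mirna id, disease id).
#' @param labels Optional 0/1 labels carried into the result.
#' @param ... Unused.
#' @return A [pair_scores()] object.
#' @export
predict.mda_model <- function(object, pairs, labels = NULL, ...) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  mi <- match(as.character(pairs[[1L]]), object$feats$mirna_ids)
  dj <- match(as.character(pairs[[2L]]), object$feats$disease_ids)
  if (anyNA(mi)) stop("unknown miRNA id in pairs")
  if (anyNA(dj)) stop("unknown disease id in pairs")
  fwd <- model_forward(object$params, object$feats, object$cfg, mi, dj,
                       training = FALSE)
  p <- 1 / (1 + exp(-as.numeric(fwd$logits$value)))
  eps <- 1e-7
  pair_scores(pairs[, 1:2], pmin(pmax(p, eps), 1 - eps), labels = labels)
}

#' Leakage-free cross-validation
#'
#' Samples balanced negatives, builds a stratified k-fold partition and, for
#' each fold, rebuilds every model input (similarity kernels, GIP profiles,
#' adjacencies, SPD) from the training positives only before training and
#' scoring the held-out fold. Multiple configuration variants can share the
#' per-fold inputs, which is how channel ablations are compared on identical
#' folds.
#'
#' @param assoc Full [association_matrix()].
#' @param dag An [disease_dag()] covering the disease registry.
#' @param cfg Base [mda_config()].
#' @param seed Integer seed driving negative sampling, fold assignment,
#'   initialisation and dropout.
#' @param folds Number of folds (default 5).
#' @param variants Optional named list of `mda_config` objects trained on the
#'   same folds; default is just the base configuration (`full`).
#' @param mfs Optional precomputed functional similarity (`mda_sim` `MFS`).
#' @param verbose Print fold progress.
#' @return List of class `mda_cv`: per-variant data.frame of fold metrics
#'   plus a `summary` data.frame of means and standard deviations.
#' @export
mda_cv <- function(assoc, dag, cfg = mda_config(), seed = 0L, folds = 5L,
                   variants = NULL, mfs = NULL, verbose = FALSE) {
  pos <- association_edges(assoc)
  neg <- sample_negatives(assoc, nrow(pos), seed)
  edges <- labeled_edge_set(pos, neg, seed = seed)
  fold_dfs <- five_fold_split(edges, seed, k = folds)
  if (is.null(variants)) variants <- list(full = cfg)
  res <- lapply(variants, function(v) NULL)
  for (f in seq_len(folds)) {
    val_df <- fold_dfs[[f]]
    train_df <- do.call(rbind, fold_dfs[-f])
    assoc_train <- .drop_positives(assoc, val_df[val_df$label == 1, ])
    feats <- build_model_inputs(assoc_train, dag = dag, cfg = cfg, mfs = mfs)
    for (vn in names(variants)) {
      vcfg <- variants[[vn]]
      model <- mda_train(feats, train_df, cfg = vcfg,
                         seed = seed + 97L * f, val_df = val_df)
      sc <- predict(model, val_df[, 1:2], labels = val_df$label)
      ev <- evaluate_scores(sc)
      row <- data.frame(fold = f, auc = ev$auc, aupr = ev$aupr, acc = ev$acc,
                        f1 = ev$f1, precision = ev$precision,
                        recall = ev$recall)
      res[[vn]] <- rbind(res[[vn]], row)
      if (verbose)
        message(sprintf("fold %d [%s]: AUC %.4f AUPR %.4f", f, vn,
                        ev$auc, ev$aupr))
    }
  }
  summaries <- do.call(rbind, lapply(names(res), function(vn) {
    m <- res[[vn]]
    data.frame(variant = vn,
               auc = mean(m$auc), auc_sd = stats::sd(m$auc),
               aupr = mean(m$aupr), aupr_sd = stats::sd(m$aupr),
               acc = mean(m$acc), f1 = mean(m$f1))
  }))
  structure(list(folds = res, summary = summaries, seed = seed),
            class = "mda_cv")
}

#' @export
print.mda_cv <- function(x, ...) {
  cat("cross-validation summary (mean over folds):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# remove validation positives from the association matrix (training fold view)
.drop_positives <- function(assoc, pos_df) {
  A <- assoc$entries
  if (nrow(pos_df)) {
    mi <- match(pos_df$mirna, assoc$mirna_ids)
    dj <- match(pos_df$disease, assoc$disease_ids)
    A[cbind(mi, dj)] <- 0
  }
  association_matrix(assoc$mirna_ids, assoc$disease_ids, A,
                     provenance = "training-fold")
}
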