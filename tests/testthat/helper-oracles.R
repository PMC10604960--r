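# Independent oracles and small random-input builders shared across tests.
# These deliberately use brute force / textbook algorithms, not the package's
# code paths.

# random DAG: each term may attach to 0-2 uniformly chosen earlier terms,
# so edges always point backwards and the graph is acyclic by construction
rand_dag <- function(n, seed, decay = 0.5) {
  set.seed(seed)
  terms <- paste0("t", seq_len(n))
  if (n == 1L) return(disease_dag(terms, NULL, decay = decay))
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    np <- min(sample(0:2, 1L, prob = c(0.25, 0.5, 0.25)), i - 1L)
    if (np > 0L) {
      ps <- sample.int(i - 1L, np)
      child <- c(child, rep(terms[i], np))
      parent <- c(parent, terms[ps])
    }
  }
  edges <- if (length(child)) data.frame(child = child, parent = parent) else NULL
  disease_dag(terms, edges, decay = decay)
}

# exhaustive-path semantic oracle: enumerate every upward path from the root,
# score each reached term decay^length, keep the maximum per term
oracle_semantic <- function(dag, root) {
  best <- new.env(parent = emptyenv())
  assign(root, 1, envir = best)
  rec <- function(node, depth) {
    ps <- dag$edges$parent[dag$edges$child == node]
    for (p in ps) {
      v <- dag$decay^(depth + 1L)
      cur <- if (exists(p, envir = best)) get(p, envir = best) else -Inf
      if (v > cur) assign(p, v, envir = best)
      rec(p, depth + 1L)
    }
  }
  rec(root, 0L)
  unlist(as.list(best))
}

# textbook Floyd-Warshall on a binary adjacency matrix; Inf = unreachable
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      cand <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], cand)
    }
  }
  D
}

# exhaustive pairwise-concordance AUC (ties count 1/2)
oracle_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# scalar-loop binary cross-entropy
oracle_bce <- function(p, y, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pi_ <- min(max(p[i], eps), 1 - eps)
    s <- s + if (y[i] == 1) -log(pi_) else -log(1 - pi_)
  }
  s / length(p)
}

# independent plain (unbiased, no structural encodings) post-LN transformer
# encoder, written in loop/sweep style against the same parameter list
oracle_plain_transformer <- function(Fmd, params, cfg) {
  softmax_rows <- function(Z) {
    out <- Z
    for (r in seq_len(nrow(Z))) {
      z <- Z[r, ] - max(Z[r, ])
      e <- exp(z)
      out[r, ] <- e / sum(e)
    }
    out
  }
  ln_rows <- function(X, g, b, eps = 1e-5) {
    out <- X
    for (r in seq_len(nrow(X))) {
      x <- X[r, ]
      xh <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + eps)
      out[r, ] <- xh * as.numeric(g) + as.numeric(b)
    }
    out
  }
  H <- Fmd
  hd <- cfg$embed_dim %/% cfg$trf_heads
  for (i in seq_len(cfg$trf_layers)) {
    heads <- NULL
    for (u in seq_len(cfg$trf_heads)) {
      Q <- H %*% params[[sprintf("trf_Wq_%d_%d", i, u)]]
      K <- H %*% params[[sprintf("trf_Wk_%d_%d", i, u)]]
      V <- H %*% params[[sprintf("trf_Wv_%d_%d", i, u)]]
      P <- softmax_rows(Q %*% t(K) / sqrt(hd))
      heads <- cbind(heads, P %*% V)
    }
    MH <- sweep(heads %*% params[[sprintf("trf_WO_%d", i)]], 2L,
                as.numeric(params[[sprintf("trf_bO_%d", i)]]), "+")
    H1 <- ln_rows(H + MH, params[[sprintf("trf_ln1g_%d", i)]],
                  params[[sprintf("trf_ln1b_%d", i)]])
    FF <- sweep(pmax(sweep(H1 %*% params[[sprintf("trf_Wf1_%d", i)]], 2L,
                           as.numeric(params[[sprintf("trf_bf1_%d", i)]]),
                           "+"), 0) %*% params[[sprintf("trf_Wf2_%d", i)]],
                2L, as.numeric(params[[sprintf("trf_bf2_%d", i)]]), "+")
    H <- ln_rows(H1 + FF, params[[sprintf("trf_ln2g_%d", i)]],
                 params[[sprintf("trf_ln2b_%d", i)]])
  }
  H
}

# small random association matrix with every node linked at least once
rand_assoc <- function(M, N, seed, p = 0.3) {
  set.seed(seed)
  A <- matrix(stats::rbinom(M * N, 1L, p), M, N)
  for (i in which(rowSums(A) == 0)) A[i, sample.int(N, 1L)] <- 1
  for (j in which(colSums(A) == 0)) A[sample.int(M, 1L), j] <- 1
  association_matrix(paste0("m", seq_len(M)), paste0("d", seq_len(N)), A)
}

# random undirected graph adjacency
rand_adjacency <- function(n, seed, p = 0.15) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- stats::rbinom(length(up), 1L, p)
  A + t(A)
}

# tiny two-channel config for fast neural tests
tiny_config <- function(...) {
  defaults <- list(embed_dim = 8L, ffn_hidden = 8L, gat_heads = 2L,
                   trf_heads = 2L, gat_layers = 2L, trf_layers = 2L,
                   dropout = 0, spd_clip = 4L, degree_max_bucket = 8L)
  do.call(mda_config, utils::modifyList(defaults, list(...)))
}
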