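# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every op appends a node (an environment holding value, parents and
# a backward closure) to a tape; ad_backward() replays the tape in reverse.
# Graphs here are small (hundreds of nodes), so interpreter overhead is
# negligible next to the BLAS matmuls.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) ad_node(tape, as.matrix(value))
ad_param <- ad_const  # leaves; distinction is bookkeeping by the caller

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ad_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

ad_matmul <- function(a, b) {
  ad_node(a$tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$value))
    ad_accum(nd$parents[[2L]], t(nd$parents[[1L]]$value) %*% nd$grad)
  })
}

ad_t <- function(a) {
  ad_node(a$tape, t(a$value), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], t(nd$grad))
  })
}

ad_add <- function(a, b) {
  ad_node(a$tape, a$value + b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], nd$grad)
  })
}

# matrix + row-vector bias (1 x k), broadcast over rows
ad_add_bias <- function(a, b) {
  ad_node(a$tape, sweep(a$value, 2L, as.numeric(b$value), "+"), list(a, b),
          function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad)
    ad_accum(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
  })
}

ad_scale <- function(a, s) {
  ad_node(a$tape, a$value * s, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * s)
  })
}

ad_hadamard <- function(a, b) {
  ad_node(a$tape, a$value * b$value, list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    ad_accum(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

# elementwise multiply by a constant matrix (dropout masks, attribute gates)
ad_mul_const <- function(a, m) {
  ad_node(a$tape, a$value * m, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * m)
  })
}

ad_relu <- function(a) {
  ad_node(a$tape, pmax(a$value, 0), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$value > 0))
  })
}

ad_leakyrelu <- function(a, slope = 0.2) {
  v <- a$value
  pos <- v > 0
  ad_node(a$tape, pmax(v, 0) + slope * pmin(v, 0), list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * (pos + slope * (!pos)))
  })
}

ad_elu <- function(a, alpha = 1) {
  v <- a$value
  pos <- v > 0
  eneg <- exp(pmin(v, 0))
  ad_node(a$tape, pmax(v, 0) + alpha * (eneg - 1) * (!pos), list(a),
          function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * (pos + alpha * eneg * (!pos)))
  })
}

ad_sigmoid <- function(a) {
  p <- 1 / (1 + exp(-a$value))
  ad_node(a$tape, p, list(a), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * nd$value * (1 - nd$value))
  })
}

# row-wise softmax with an optional constant additive mask (e.g. -1e9 on
# non-edges); the mask is part of the logits but carries no gradient
ad_rowsoftmax <- function(a, mask = NULL) {
  z <- a$value
  if (!is.null(mask)) z <- z + mask
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  p <- exp(z)
  p <- p / rowSums(p)
  ad_node(a$tape, p, list(a), function(nd) {
    g <- nd$grad
    pv <- nd$value
    dot <- rowSums(g * pv)
    ad_accum(nd$parents[[1L]], pv * (g - dot))
  })
}

# row-wise layer normalisation with learned affine (gamma, beta are 1 x k)
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  k <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  s <- sqrt(va + eps)
  xhat <- xc / s
  out <- sweep(sweep(xhat, 2L, as.numeric(gamma$value), "*"),
               2L, as.numeric(beta$value), "+")
  nd <- ad_node(a$tape, out, list(a, gamma, beta), function(nd) {
    g <- nd$grad
    ad_accum(nd$parents[[2L]], matrix(colSums(g * nd$extra$xhat), 1L))
    ad_accum(nd$parents[[3L]], matrix(colSums(g), 1L))
    dxh <- sweep(g, 2L, as.numeric(nd$parents[[2L]]$value), "*")
    m1 <- rowMeans(dxh)
    m2 <- rowMeans(dxh * nd$extra$xhat)
    dx <- (dxh - m1 - nd$extra$xhat * m2) / nd$extra$s
    ad_accum(nd$parents[[1L]], dx)
  })
  nd$extra <- list(xhat = xhat, s = s)
  nd
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(nodes[[1L]]$tape, do.call(cbind, vals), nodes, function(nd) {
    for (i in seq_along(nd$parents)) {
      ad_accum(nd$parents[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_rbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ad_node(nodes[[1L]]$tape, do.call(rbind, vals), nodes, function(nd) {
    for (i in seq_along(nd$parents)) {
      ad_accum(nd$parents[[i]], nd$grad[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

# out[r, ] = a[idx[r], ]; backward scatter-adds rows (embedding lookups,
# pair-row extraction)
ad_gather_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ad_node(a$tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    ga <- matrix(0, nrow(nd$parents[[1L]]$value), ncol(nd$parents[[1L]]$value))
    acc <- rowsum(nd$grad, group = idx)
    ga[as.integer(rownames(acc)), ] <- acc
    ad_accum(nd$parents[[1L]], ga)
  })
}

# B[i, j] = v[idx[i, j]] for a parameter vector v (1 x nbucket) and an integer
# index matrix; backward sums gradient entries per bucket
ad_bucket_bias <- function(v, idx) {
  vv <- as.numeric(v$value)
  B <- matrix(vv[idx], nrow(idx), ncol(idx))
  ad_node(v$tape, B, list(v), function(nd) {
    acc <- rowsum(as.numeric(nd$grad), group = as.integer(idx))
    gs <- numeric(length(vv))
    gs[as.integer(rownames(acc))] <- acc[, 1L]
    ad_accum(nd$parents[[1L]], matrix(gs, 1L))
  })
}

# elementwise maximum of two same-shape nodes; ties route gradient to `a`
ad_pmax <- function(a, b) {
  take_a <- a$value >= b$value
  ad_node(a$tape, pmax(a$value, b$value), list(a, b), function(nd) {
    ad_accum(nd$parents[[1L]], nd$grad * take_a)
    ad_accum(nd$parents[[2L]], nd$grad * (!take_a))
  })
}

# mean binary cross-entropy on logits (fused with the sigmoid for a stable
# (p - y) / n gradient); y is a constant 0/1 vector, eps clamps probabilities
ad_bce_logits <- function(z, y, eps = 1e-7) {
  y <- as.numeric(y)
  p <- 1 / (1 + exp(-as.numeric(z$value)))
  p <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  ad_node(z$tape, matrix(loss, 1L, 1L), list(z), function(nd) {
    g <- nd$grad[1L, 1L]
    ad_accum(nd$parents[[1L]], matrix((p - y) / length(y) * g, ncol = 1L))
  })
}
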