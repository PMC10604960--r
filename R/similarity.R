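#' Square symmetric similarity matrix for one node family
#'
#' Container for the similarity kernels used as node features: disease
#' semantic similarity (`DSS`), miRNA functional similarity (`MFS`), GIP
#' kernel similarities (`DGS`, `MGS`) and their aggregations (`MF`, `DF`).
#' Values are validated to be symmetric and within `[0, 1]`.
#'
#' @param ids Ordered identifier registry.
#' @param values Square numeric matrix, `length(ids)` on a side.
#' @param kind One of `"DSS"`, `"MFS"`, `"DGS"`, `"MGS"`, `"MF"`, `"DF"`.
#' @return An object of class `mda_sim`.
#' @export
similarity_matrix <- function(ids, values,
                              kind = c("DSS", "MFS", "DGS", "MGS", "MF", "DF")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in similarity registry")
  values <- as.matrix(values)
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("values must be square on the id registry")
  if (max(abs(values - t(values))) > 1e-9) stop("similarity values not symmetric")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    stop("similarity values outside [0, 1]")
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  if (kind %in% c("DSS", "DGS", "MGS", "MF", "DF") &&
      any(abs(diag(values) - 1) > 1e-9))
    stop("diagonal must equal 1 for kind ", kind)
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind), class = "mda_sim")
}

#' @export
print.mda_sim <- function(x, ...) {
  cat(sprintf("<mda_sim %s> %d x %d, mean off-diagonal %.4f\n", x$kind,
              length(x$ids), length(x$ids),
              mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' miRNA functional similarity
#'
#' Best-match average of disease semantic similarity between the disease sets
#' of two miRNAs: each disease of one miRNA is matched to its most
#' semantically similar disease of the other, and the matched similarities
#' (both directions) are averaged over the total number of diseases.
#'
#' With `mi`/`mj` omitted, computes the full `MFS` matrix; rows for miRNAs
#' with no associated disease are left at 0 (excluding the diagonal handled by
#' aggregation with the GIP kernel), mirroring the fallback rule of
#' [aggregate_similarity()].
#'
#' @param dss A [similarity_matrix()] of kind `"DSS"` on the disease registry.
#' @param assoc An [association_matrix()] aligned to the same diseases.
#' @param mi,mj Optional miRNA identifiers for a scalar query.
#' @return Scalar in `[0, 1]`, or an `mda_sim` of kind `"MFS"`.
#' @export
mirna_functional_similarity <- function(dss, assoc, mi = NULL, mj = NULL) {
  if (dss$kind != "DSS") stop("dss must have kind DSS")
  if (!identical(dss$ids, assoc$disease_ids))
    stop("DSS registry must match association disease registry")
  A <- assoc$entries
  S <- dss$values
  dsets <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] == 1))
  if (!is.null(mi) || !is.null(mj)) {
    ii <- match(mi, assoc$mirna_ids); jj <- match(mj, assoc$mirna_ids)
    if (is.na(ii)) stop("unknown miRNA id: ", mi)
    if (is.na(jj)) stop("unknown miRNA id: ", mj)
    if (!length(dsets[[ii]]) || !length(dsets[[jj]]))
      stop("miRNA with no associated disease; fall back to the GIP kernel")
    return(.mfs_pair(S, dsets[[ii]], dsets[[jj]]))
  }
  M <- nrow(A)
  V <- matrix(0, M, M)
  nonempty <- which(vapply(dsets, length, integer(1)) > 0L)
  for (a in seq_along(nonempty)) {
    i <- nonempty[[a]]
    V[i, i] <- 1
    if (a < length(nonempty)) {
      for (b in (a + 1L):length(nonempty)) {
        j <- nonempty[[b]]
        V[i, j] <- V[j, i] <- .mfs_pair(S, dsets[[i]], dsets[[j]])
      }
    }
  }
  # empty rows keep 0 everywhere incl. diagonal; MFS kind does not force diag 1
  similarity_matrix(assoc$mirna_ids, V, kind = "MFS")
}

.mfs_pair <- function(S, di, dj) {
  sub <- S[di, dj, drop = FALSE]
  (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
    (length(di) + length(dj))
}

#' GIP kernel bandwidth
#'
#' Normalising bandwidth for the Gaussian interaction profile kernel: the
#' reciprocal of the mean squared Euclidean norm of the interaction profiles.
#'
#' @param profiles A list of equal-length binary vectors, or a matrix whose
#'   rows are profiles.
#' @return Strictly positive bandwidth.
#' @export
gip_bandwidth <- function(profiles) {
  P <- if (is.matrix(profiles)) profiles else do.call(rbind, profiles)
  if (nrow(P) < 1L) stop("need at least one profile")
  msq <- mean(rowSums(P^2))
  if (msq == 0) stop("all interaction profiles are zero; bandwidth undefined")
  1 / msq
}

#' GIP kernel similarity
#'
#' Gaussian interaction profile kernel over one side of the bipartite
#' association matrix: `exp(-theta * ||IP(i) - IP(j)||^2)` with `theta` the
#' [gip_bandwidth()] of the profiles. Disease profiles are the columns of the
#' association matrix, miRNA profiles the rows.
#'
#' @param assoc An [association_matrix()].
#' @param axis `"disease"` (kind `DGS`) or `"mirna"` (kind `MGS`).
#' @return An `mda_sim` of the corresponding kind.
#' @export
gip_similarity <- function(assoc, axis = c("disease", "mirna")) {
  axis <- match.arg(axis)
  P <- if (axis == "disease") t(assoc$entries) else assoc$entries
  ids <- if (axis == "disease") assoc$disease_ids else assoc$mirna_ids
  theta <- gip_bandwidth(P)
  r <- rowSums(P^2)
  D2 <- outer(r, r, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  V <- exp(-theta * D2)
  diag(V) <- 1
  similarity_matrix(ids, (V + t(V)) / 2,
                    kind = if (axis == "disease") "DGS" else "MGS")
}

#' Aggregate a primary similarity with a GIP fallback
#'
#' Entrywise: where the primary similarity (semantic or functional) is
#' nonzero it is kept, otherwise the GIP kernel value fills in. The result is
#' the initial node feature matrix (`MF` for miRNAs, `DF` for diseases).
#'
#' @param primary `mda_sim` of kind `"MFS"` or `"DSS"`.
#' @param fallback `mda_sim` of kind `"MGS"` or `"DGS"` on the same registry.
#' @return `mda_sim` of kind `"MF"` (miRNA) or `"DF"` (disease).
#' @export
aggregate_similarity <- function(primary, fallback) {
  if (!identical(primary$ids, fallback$ids))
    stop("registry mismatch between primary and fallback similarity")
  ok <- (primary$kind == "MFS" && fallback$kind == "MGS") ||
        (primary$kind == "DSS" && fallback$kind == "DGS")
  if (!ok) stop("expected MFS+MGS or DSS+DGS input kinds")
  V <- ifelse(primary$values != 0, primary$values, fallback$values)
  similarity_matrix(primary$ids, V,
                    kind = if (primary$kind == "MFS") "MF" else "DF")
}

#' Binary adjacency from a similarity matrix
#'
#' Marks node pairs with similarity strictly above `threshold` as connected;
#' self-loops are excluded. With the default threshold 0 this connects every
#' pair with any nonzero similarity (the homogeneity networks `GM` and `GD`).
#'
#' @param sim An `mda_sim`.
#' @param threshold Similarity cutoff in `[0, 1)`; strict comparison.
#' @return Binary symmetric matrix with zero diagonal.
#' @export
similarity_adjacency <- function(sim, threshold = 0) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  Adj <- (sim$values > threshold) * 1
  diag(Adj) <- 0
  dimnames(Adj) <- list(sim$ids, sim$ids)
  Adj
}

#' Heterogeneous network adjacency
#'
#' The `(M+N) x (M+N)` block matrix `[[0, A], [A^T, 0]]` representing the
#' bipartite miRNA-disease network, rows ordered miRNAs then diseases.
#'
#' @param assoc An [association_matrix()].
#' @return Binary symmetric matrix of size `M + N`.
#' @export
hetero_adjacency <- function(assoc) {
  A <- assoc$entries
  M <- nrow(A); N <- ncol(A)
  G <- rbind(cbind(matrix(0, M, M), A),
             cbind(t(A), matrix(0, N, N)))
  ids <- c(assoc$mirna_ids, assoc$disease_ids)
  dimnames(G) <- list(ids, ids)
  G
}

#' Write a similarity matrix as dense delimited text
#' @param sim An `mda_sim`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_similarity <- function(sim, path, sep = "\t") {
  df <- as.data.frame(sim$values)
  utils::write.table(cbind(id = sim$ids, df), path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = c("id", sim$ids))
  invisible(path)
}

#' Read a dense similarity matrix written by [write_similarity()]
#' @param path File path.
#' @param kind Similarity kind, see [similarity_matrix()].
#' @param sep Field separator.
#' @return An `mda_sim`.
#' @export
read_similarity <- function(path, kind, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  V <- as.matrix(df[, -1L, drop = FALSE])
  similarity_matrix(ids, V, kind = kind)
}
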