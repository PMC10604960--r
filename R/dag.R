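#' Disease ontology DAG
#'
#' A directed acyclic graph over disease terms in which an edge
#' `(child, parent)` states that `child` *is-a* `parent`, as in the MeSH
#' descriptor hierarchy. The DAG is the substrate for Wang-style disease
#' semantic similarity: each ancestor of a disease contributes a semantic
#' score that decays by `decay` per hierarchy level.
#'
#' @param terms Character vector of unique disease identifiers. Order is kept
#'   and defines the registry used by all downstream matrices.
#' @param parent_edges Two-column `data.frame` (or matrix) of `(child, parent)`
#'   identifier pairs. May have zero rows (a forest of isolated terms).
#' @param decay Semantic contribution factor in `(0, 1]`; each step up the
#'   hierarchy multiplies a term's contribution by this factor. Default 0.5.
#' @return An object of class `mda_dag` with elements `terms`, `edges`
#'   (a data.frame with columns `child`, `parent`), and `decay`.
#' @examples
#' dag <- disease_dag(c("root", "p", "a"),
#'                    data.frame(child = c("p", "a"), parent = c("root", "p")))
#' semantic_profile(dag, "a")
#' @export
disease_dag <- function(terms, parent_edges, decay = 0.5) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate disease terms in registry")
  if (length(terms) < 1L) stop("at least one disease term required")
  if (!is.numeric(decay) || length(decay) != 1L || decay <= 0 || decay > 1)
    stop("decay must be a single number in (0, 1]")
  if (is.null(parent_edges) || NROW(parent_edges) == 0L) {
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
  } else {
    parent_edges <- as.data.frame(parent_edges, stringsAsFactors = FALSE)
    if (ncol(parent_edges) < 2L) stop("parent_edges needs (child, parent) columns")
    edges <- data.frame(child = as.character(parent_edges[[1L]]),
                        parent = as.character(parent_edges[[2L]]),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(unknown))
      stop("edge endpoints not in term registry: ", paste(unknown, collapse = ", "))
    if (any(edges$child == edges$parent)) stop("self-loop edge in DAG")
    edges <- unique(edges)
  }
  dag <- structure(list(terms = terms, edges = edges, decay = decay),
                   class = "mda_dag")
  if (.dag_has_cycle(dag)) stop("parent edges contain a cycle; not a DAG")
  dag
}

# Kahn's algorithm on the child -> parent digraph.
.dag_has_cycle <- function(dag) {
  n <- length(dag$terms)
  if (nrow(dag$edges) == 0L) return(FALSE)
  ci <- match(dag$edges$child, dag$terms)
  pi <- match(dag$edges$parent, dag$terms)
  indeg <- tabulate(pi, nbins = n)   # incoming edges (from children)
  out <- split(pi, ci)               # child index -> parent indices
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ps <- out[[as.character(v)]]
    if (!is.null(ps)) {
      for (p in ps) {
        indeg[p] <- indeg[p] - 1L
        if (indeg[p] == 0L) queue <- c(queue, p)
      }
    }
  }
  seen < n
}

#' @export
print.mda_dag <- function(x, ...) {
  cat(sprintf("<mda_dag> %d terms, %d is-a edges, decay = %g\n",
              length(x$terms), nrow(x$edges), x$decay))
  invisible(x)
}

.dag_check_term <- function(dag, id) {
  if (!id %in% dag$terms) stop("unknown disease term: ", id)
}

# All ancestors of `root` (excluding root) reachable via child -> parent edges.
.dag_ancestors <- function(dag, root) {
  anc <- character(0)
  frontier <- root
  repeat {
    parents <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    parents <- setdiff(parents, c(anc, root))
    if (!length(parents)) break
    anc <- c(anc, parents)
    frontier <- parents
  }
  anc
}

#' Semantic profile of a disease
#'
#' Computes the decayed semantic contribution of every term in the sub-DAG
#' rooted at `root` (the term itself plus all of its ancestors), following the
#' Wang recursion: the root contributes 1, and any ancestor `t` contributes
#' `decay * max` over the contributions of its children *within the sub-DAG*.
#' The semantic value is the sum of all contributions.
#'
#' @param dag An [disease_dag()] object.
#' @param root A registered disease identifier.
#' @return An object of class `mda_semantic_profile`: a list with `root`,
#'   `contributions` (named numeric vector over the sub-DAG terms, root first),
#'   and `semantic_value`.
#' @export
semantic_profile <- function(dag, root) {
  .dag_check_term(dag, root)
  anc <- .dag_ancestors(dag, root)
  set <- c(root, anc)
  contrib <- stats::setNames(rep(NA_real_, length(set)), set)
  contrib[[root]] <- 1
  # children of t restricted to the sub-DAG
  kids_of <- function(t) intersect(dag$edges$child[dag$edges$parent == t], set)
  score <- function(t) {
    v <- contrib[[t]]
    if (!is.na(v)) return(v)
    ks <- kids_of(t)
    v <- dag$decay * max(vapply(ks, score, numeric(1)))
    contrib[[t]] <<- v
    v
  }
  for (t in set) score(t)
  structure(list(root = root,
                 contributions = contrib,
                 semantic_value = sum(contrib)),
            class = "mda_semantic_profile")
}

#' @export
print.mda_semantic_profile <- function(x, ...) {
  cat(sprintf("<semantic profile> root %s: %d contributing terms, SD = %g\n",
              x$root, length(x$contributions), x$semantic_value))
  invisible(x)
}

#' Disease semantic similarity
#'
#' Wang-style similarity between two diseases: the summed contributions of
#' their shared sub-DAG terms, normalised by the sum of the two semantic
#' values. With no arguments beyond the DAG, computes the full symmetric
#' similarity matrix over the registry (kind `"DSS"`).
#'
#' @param dag An [disease_dag()] object.
#' @param di,dj Optional disease identifiers; when both given, returns the
#'   scalar similarity.
#' @return Scalar in `[0, 1]`, or a [similarity_matrix()] of kind `"DSS"`.
#' @export
disease_semantic_similarity <- function(dag, di = NULL, dj = NULL) {
  if (!is.null(di) || !is.null(dj)) {
    .dag_check_term(dag, di); .dag_check_term(dag, dj)
    pi_ <- semantic_profile(dag, di)
    pj_ <- semantic_profile(dag, dj)
    return(.dss_pair(pi_, pj_))
  }
  profs <- lapply(dag$terms, semantic_profile, dag = dag)
  n <- length(dag$terms)
  v <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v[i, j] <- v[j, i] <- .dss_pair(profs[[i]], profs[[j]])
      }
    }
  }
  dimnames(v) <- list(dag$terms, dag$terms)
  similarity_matrix(dag$terms, v, kind = "DSS")
}

.dss_pair <- function(pi_, pj_) {
  shared <- intersect(names(pi_$contributions), names(pj_$contributions))
  if (!length(shared)) return(0)
  num <- sum(pi_$contributions[shared]) + sum(pj_$contributions[shared])
  num / (pi_$semantic_value + pj_$semantic_value)
}
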