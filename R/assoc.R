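#' Binary miRNA x disease association matrix
#'
#' The bipartite incidence structure at the core of the method: `entries[i, j]
#' = 1` states an experimentally supported association between miRNA `i` and
#' disease `j`. Columns are the disease interaction profiles `IP(d)` and rows
#' the miRNA interaction profiles `IP(m)` used by the GIP kernel.
#'
#' @param mirna_ids Character vector, ordered miRNA registry (size M).
#' @param disease_ids Character vector, ordered disease registry (size N).
#' @param entries M x N matrix of 0/1 values.
#' @param provenance One of `"observed"`, `"training-fold"`, `"synthetic"`.
#' @return An object of class `mda_assoc`.
#' @export
association_matrix <- function(mirna_ids, disease_ids, entries,
                               provenance = c("observed", "training-fold",
                                              "synthetic")) {
  provenance <- match.arg(provenance)
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (length(mirna_ids) < 1L || length(disease_ids) < 1L)
    stop("need at least one miRNA and one disease")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA ids")
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids")
  entries <- as.matrix(entries)
  if (nrow(entries) != length(mirna_ids) || ncol(entries) != length(disease_ids))
    stop("entries must be |mirna_ids| x |disease_ids|")
  if (!all(entries %in% c(0, 1))) stop("entries must be exactly 0 or 1")
  storage.mode(entries) <- "double"
  dimnames(entries) <- list(mirna_ids, disease_ids)
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids,
                 entries = entries, provenance = provenance),
            class = "mda_assoc")
}

#' @export
print.mda_assoc <- function(x, ...) {
  cat(sprintf("<mda_assoc> %d miRNAs x %d diseases, %d associations (%s)\n",
              length(x$mirna_ids), length(x$disease_ids),
              sum(x$entries), x$provenance))
  invisible(x)
}

#' Build an association matrix from an edge list
#'
#' @param edges Two-column data.frame of (miRNA id, disease id) pairs.
#' @param mirna_ids,disease_ids Optional explicit registries; defaults to
#'   order of first appearance in `edges`.
#' @inheritParams association_matrix
#' @return An `mda_assoc` object.
#' @export
association_from_edges <- function(edges, mirna_ids = NULL, disease_ids = NULL,
                                   provenance = "observed") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  m <- as.character(edges[[1L]]); d <- as.character(edges[[2L]])
  if (is.null(mirna_ids)) mirna_ids <- unique(m)
  if (is.null(disease_ids)) disease_ids <- unique(d)
  mi <- match(m, mirna_ids); di <- match(d, disease_ids)
  if (anyNA(mi) || anyNA(di)) stop("edge endpoint missing from registry")
  A <- matrix(0, length(mirna_ids), length(disease_ids))
  A[cbind(mi, di)] <- 1
  association_matrix(mirna_ids, disease_ids, A, provenance = provenance)
}

#' Association matrix as an edge list
#' @param assoc An `mda_assoc` object.
#' @return data.frame with columns `mirna`, `disease`.
#' @export
association_edges <- function(assoc) {
  idx <- which(assoc$entries == 1, arr.ind = TRUE)
  data.frame(mirna = assoc$mirna_ids[idx[, 1L]],
             disease = assoc$disease_ids[idx[, 2L]],
             stringsAsFactors = FALSE)[order(idx[, 1L], idx[, 2L]), ,
                                       drop = FALSE]
}

#' Read associations from delimited text
#'
#' Expects two columns (miRNA id, disease id); a header line is detected and
#' skipped when its fields repeat nowhere else as ids do.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param header Logical; whether the first line is a header.
#' @inheritParams association_from_edges
#' @return An `mda_assoc` object.
#' @export
read_associations <- function(path, sep = "\t", header = FALSE,
                              mirna_ids = NULL, disease_ids = NULL,
                              provenance = "observed") {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  association_from_edges(df[, 1:2], mirna_ids = mirna_ids,
                         disease_ids = disease_ids, provenance = provenance)
}

#' Write associations as delimited text
#' @param assoc An `mda_assoc` object.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_associations <- function(assoc, path, sep = "\t") {
  utils::write.table(association_edges(assoc), path, sep = sep,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a disease ontology from a parent-child edge list
#'
#' Either a plain `(child, parent)` edge list, or MeSH-style tree numbers
#' `(term, dot-separated tree code)` with `tree_numbers = TRUE`, in which case
#' parent edges are derived by truncating the last code segment.
#'
#' @param path File path.
#' @param sep Field separator.
#' @param header Logical.
#' @param tree_numbers Interpret column 2 as tree codes rather than parents.
#' @param decay Semantic decay factor, see [disease_dag()].
#' @return An `mda_dag` object.
#' @export
read_disease_dag <- function(path, sep = "\t", header = FALSE,
                             tree_numbers = FALSE, decay = 0.5) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  if (!tree_numbers) {
    terms <- unique(c(df[[1L]], df[[2L]]))
    return(disease_dag(terms, df[, 1:2], decay = decay))
  }
  term <- df[[1L]]; code <- df[[2L]]
  code2term <- stats::setNames(term, code)
  parent_code <- sub("\\.[^.]*$", "", code)
  has_parent <- parent_code != code & parent_code %in% names(code2term)
  edges <- data.frame(child = term[has_parent],
                      parent = unname(code2term[parent_code[has_parent]]),
                      stringsAsFactors = FALSE)
  edges <- unique(edges[edges$child != edges$parent, , drop = FALSE])
  disease_dag(unique(term), edges, decay = decay)
}
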