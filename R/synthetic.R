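#' Synthetic data configuration
#'
#' Desk-scale generator settings for a disease ontology DAG and a
#' block-structured bipartite association matrix. Defaults give 120 miRNAs x
#' 80 diseases in 4 latent blocks with within-block association probability
#' 0.3 against a 0.02 background, a learnable but non-trivial relational
#' signal of overall density about 0.09.
#'
#' @param n_mirna,n_disease Node counts.
#' @param n_blocks Number of latent blocks shared by both node families.
#' @param p_within,p_background Bernoulli association probabilities for
#'   same-block and cross-block pairs; `0 <= p_background < p_within <= 1`.
#' @param dag_branching Mean number of parents drawn per DAG term (1 to 2).
#' @param seed Integer seed.
#' @return List of class `mda_synth_config`.
#' @export
synth_config <- function(n_mirna = 120L, n_disease = 80L, n_blocks = 4L,
                         p_within = 0.3, p_background = 0.02,
                         dag_branching = 1.5, seed = 0L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
              n_blocks = as.integer(n_blocks), p_within = p_within,
              p_background = p_background, dag_branching = dag_branching,
              seed = as.integer(seed))
  if (cfg$p_background < 0 || cfg$p_background >= cfg$p_within || cfg$p_within > 1)
    stop("need 0 <= p_background < p_within <= 1")
  if (cfg$n_mirna < cfg$n_blocks || cfg$n_disease < cfg$n_blocks)
    stop("node counts must be >= n_blocks")
  if (cfg$dag_branching < 1 || cfg$dag_branching > 2)
    stop("dag_branching must be in [1, 2]")
  structure(cfg, class = "mda_synth_config")
}

.synth_block <- function(i, k) ((i - 1L) %% k) + 1L

#' Simulate a disease ontology DAG
#'
#' Builds a rooted random DAG over the disease terms: term 1 is the global
#' root, terms 2..K anchor the K latent blocks as children of the root, and
#' every later term attaches to one or two uniformly chosen earlier terms of
#' its own (round-robin) block, so same-block diseases share an ancestor
#' subtree. Acyclic by construction since edges always point to earlier
#' terms.
#'
#' @param cfg An [synth_config()].
#' @return An [disease_dag()].
#' @export
simulate_dag <- function(cfg) {
  n <- cfg$n_disease
  terms <- sprintf("DIS%03d", seq_len(n))
  if (n == 1L) return(disease_dag(terms, NULL))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  k <- cfg$n_blocks
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    if (i <= k) {
      child <- c(child, terms[i]); parent <- c(parent, terms[1L])
      next
    }
    b <- .synth_block(i, k)
    pool <- which(.synth_block(seq_len(i - 1L), k) == b)
    n_par <- if (stats::runif(1) < cfg$dag_branching - 1) 2L else 1L
    n_par <- min(n_par, length(pool))
    ps <- pool[sample.int(length(pool), n_par)]
    child <- c(child, rep(terms[i], n_par)); parent <- c(parent, terms[ps])
  }
  disease_dag(terms, data.frame(child = child, parent = parent),
              decay = 0.5)
}

#' Simulate a block-model association matrix
#'
#' Assigns miRNAs and diseases round-robin to the latent blocks and draws
#' each cell Bernoulli with `p_within` for same-block pairs and
#' `p_background` otherwise. Rows and columns that come out empty are
#' redrawn (rejection resampling) so every node retains at least one
#' association; if the expected node degree is below 0.2 the configuration
#' is rejected as infeasible.
#'
#' @param cfg An [synth_config()].
#' @return An [association_matrix()] with provenance `"synthetic"`.
#' @export
simulate_associations <- function(cfg) {
  M <- cfg$n_mirna; N <- cfg$n_disease; k <- cfg$n_blocks
  exp_deg <- N * (cfg$p_within / k + cfg$p_background * (k - 1) / k)
  if (exp_deg < 0.2)
    stop("infeasible density: expected miRNA degree ", signif(exp_deg, 3),
         " < 0.2; raise p_within/p_background or sizes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  bm <- .synth_block(seq_len(M), k)
  bd <- .synth_block(seq_len(N), k)
  P <- matrix(cfg$p_background, M, N)
  P[outer(bm, bd, "==")] <- cfg$p_within
  draw <- function(prob) (stats::runif(length(prob)) < prob) * 1
  A <- matrix(draw(P), M, N)
  for (pass in 1:100) {
    empty_rows <- which(rowSums(A) == 0)
    for (i in empty_rows) {
      for (tries in 1:1000) {
        A[i, ] <- draw(P[i, ])
        if (sum(A[i, ]) > 0) break
      }
      if (sum(A[i, ]) == 0) stop("could not populate miRNA row ", i)
    }
    empty_cols <- which(colSums(A) == 0)
    for (j in empty_cols) {
      for (tries in 1:1000) {
        A[, j] <- draw(P[, j])
        if (sum(A[, j]) > 0) break
      }
      if (sum(A[, j]) == 0) stop("could not populate disease column ", j)
    }
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  association_matrix(sprintf("MIR%03d", seq_len(M)),
                     sprintf("DIS%03d", seq_len(N)), A,
                     provenance = "synthetic")
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Writes the association edge list (`associations.tsv`), the ontology edge
#' list (`dag.tsv`) and a JSON manifest recording the seed, the generator
#' configuration and the full node registries, such that [read_fixture()]
#' reproduces the objects exactly.
#'
#' @param dag An [disease_dag()].
#' @param assoc An [association_matrix()].
#' @param directory Output directory (created if missing).
#' @param cfg Optional [synth_config()] recorded in the manifest.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(dag, assoc, directory, cfg = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_associations(assoc, file.path(directory, "associations.tsv"))
  utils::write.table(dag$edges, file.path(directory, "dag.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  manifest <- list(mirna_ids = assoc$mirna_ids,
                   disease_ids = assoc$disease_ids,
                   dag_terms = dag$terms, decay = dag$decay,
                   provenance = assoc$provenance,
                   seed = if (!is.null(cfg)) cfg$seed else NA,
                   config = if (!is.null(cfg)) unclass(cfg) else NULL)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return List with `dag`, `assoc` and the `manifest`.
#' @export
read_fixture <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  dag_path <- file.path(directory, "dag.tsv")
  edges <- if (file.exists(dag_path) && file.size(dag_path) > 0)
    utils::read.table(dag_path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character") else NULL
  dag <- disease_dag(manifest$dag_terms, edges, decay = manifest$decay)
  assoc <- read_associations(file.path(directory, "associations.tsv"),
                             mirna_ids = manifest$mirna_ids,
                             disease_ids = manifest$disease_ids,
                             provenance = if (is.null(manifest$provenance))
                               "observed" else manifest$provenance)
  list(dag = dag, assoc = assoc, manifest = manifest)
}
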