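# Similarity kernels: semantic profiles, DSS, MFS, GIP, aggregation and the
# adjacency builders.

test_that("semantic_profile reproduces hand-derived worked examples", {
  chain <- disease_dag(c("A", "P", "R"),
                       data.frame(child = c("A", "P"), parent = c("P", "R")))
  sp <- semantic_profile(chain, "A")
  expect_equal(sp$contributions[c("A", "P", "R")],
               c(A = 1, P = 0.5, R = 0.25))
  expect_equal(sp$semantic_value, 1.75)

  lone <- disease_dag("X", NULL)
  sp0 <- semantic_profile(lone, "X")
  expect_equal(sp0$contributions, c(X = 1))
  expect_equal(sp0$semantic_value, 1)

  diamond <- disease_dag(c("A", "P1", "P2", "R"),
                         data.frame(child = c("A", "A", "P1", "P2"),
                                    parent = c("P1", "P2", "R", "R")))
  spd <- semantic_profile(diamond, "A")
  expect_equal(unname(spd$contributions["R"]), 0.25)
  expect_equal(spd$semantic_value, 2.25)
})

test_that("semantic_profile matches the exhaustive-path oracle on random DAGs", {
  for (s in 1:50) {
    dag <- rand_dag(sample(2:12, 1L), seed = s)
    root <- sample(dag$terms, 1L)
    sp <- semantic_profile(dag, root)
    oracle <- oracle_semantic(dag, root)
    expect_setequal(names(sp$contributions), names(oracle))
    expect_equal(sp$contributions[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("disease_dag rejects malformed input", {
  expect_error(disease_dag(c("a", "a"), NULL), "duplicate")
  expect_error(disease_dag(c("a", "b"),
                           data.frame(child = "a", parent = "c")), "registry")
  expect_error(disease_dag(c("a", "b"),
                           data.frame(child = c("a", "b"),
                                      parent = c("b", "a"))), "cycle")
  expect_error(semantic_profile(disease_dag("a", NULL), "zzz"), "unknown")
})

test_that("disease semantic similarity follows the shared-ancestor formula", {
  dag <- disease_dag(c("A", "B", "P", "R"),
                     data.frame(child = c("A", "B", "P"),
                                parent = c("P", "P", "R")))
  expect_equal(disease_semantic_similarity(dag, "A", "A"), 1)
  expect_equal(disease_semantic_similarity(dag, "A", "B"), 3 / 7,
               tolerance = 1e-9)
  # disjoint components share no ancestors
  forest <- disease_dag(c("x", "y"), NULL)
  expect_equal(disease_semantic_similarity(forest, "x", "y"), 0)
  # full matrix: symmetric, unit diagonal, in range
  S <- disease_semantic_similarity(dag)
  expect_s3_class(S, "mda_sim")
  expect_equal(S$values, t(S$values))
  expect_true(all(diag(S$values) == 1))
  expect_true(all(S$values >= 0 & S$values <= 1))
})

test_that("miRNA functional similarity is a best-match average of DSS", {
  dag <- disease_dag(c("A", "B", "P", "R"),
                     data.frame(child = c("A", "B", "P"),
                                parent = c("P", "P", "R")))
  dss <- disease_semantic_similarity(dag)
  ord <- c("A", "B", "P", "R")
  assoc <- association_matrix(c("m1", "m2", "m3"), ord,
                              rbind(c(1, 0, 0, 0),
                                    c(0, 1, 0, 0),
                                    c(1, 1, 0, 0)))
  expect_equal(mirna_functional_similarity(dss, assoc, "m1", "m1"), 1)
  expect_equal(mirna_functional_similarity(dss, assoc, "m1", "m2"), 3 / 7,
               tolerance = 1e-9)
  expect_equal(mirna_functional_similarity(dss, assoc, "m1", "m3"), 17 / 21,
               tolerance = 1e-9)
  # a miRNA with no associations is a domain error for the pairwise op
  assoc0 <- association_matrix(c("m1", "m2"), ord,
                               rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)))
  expect_error(mirna_functional_similarity(dss, assoc0, "m1", "m2"), "GIP")
  # ...but the matrix builder leaves its rows at zero for aggregation
  Mf <- mirna_functional_similarity(dss, assoc0)
  expect_equal(unname(Mf$values[2, ]), c(0, 0))
})

test_that("GIP bandwidth and kernel match hand computation", {
  expect_equal(gip_bandwidth(list(c(1, 0), c(0, 1))), 1)
  expect_equal(gip_bandwidth(list(c(1, 1, 1, 1))), 0.25)
  expect_error(gip_bandwidth(list(c(0, 0))), "zero")

  assoc <- association_matrix(c("m1", "m2"), c("d1", "d2"), diag(2))
  dgs <- gip_similarity(assoc, "disease")
  expect_equal(dgs$kind, "DGS")
  expect_equal(dgs$values["d1", "d2"], exp(-2), tolerance = 1e-9)
  mgs <- gip_similarity(assoc, "mirna")
  expect_equal(mgs$values["m1", "m2"], exp(-2), tolerance = 1e-9)
})

test_that("similarity outputs are symmetric, bounded and self-similar", {
  for (s in 1:10) {
    assoc <- rand_assoc(8, 6, seed = 100 + s)
    dag <- rand_dag(6, seed = 200 + s)
    # rename DAG terms onto the disease registry
    dag$terms <- assoc$disease_ids
    if (nrow(dag$edges)) {
      dag$edges$child <- assoc$disease_ids[match(dag$edges$child,
                                                 paste0("t", 1:6))]
      dag$edges$parent <- assoc$disease_ids[match(dag$edges$parent,
                                                  paste0("t", 1:6))]
    }
    dss <- disease_semantic_similarity(dag)
    mfs <- mirna_functional_similarity(dss, assoc)
    dgs <- gip_similarity(assoc, "disease")
    mgs <- gip_similarity(assoc, "mirna")
    for (sim in list(dss, mfs, dgs, mgs)) {
      expect_lt(max(abs(sim$values - t(sim$values))), 1e-9)
      expect_true(all(sim$values >= 0 & sim$values <= 1))
    }
    expect_true(all(diag(dss$values) == 1))
    expect_true(all(diag(dgs$values) == 1))
    expect_true(all(diag(mgs$values) == 1))
    expect_true(all(diag(mfs$values) == 1))  # every miRNA has >= 1 disease
  }
})

test_that("gip_similarity is equivariant to simultaneous permutations", {
  for (s in 1:5) {
    assoc <- rand_assoc(7, 5, seed = 300 + s)
    pm <- sample(7); pd <- sample(5)
    perm <- association_matrix(assoc$mirna_ids[pm], assoc$disease_ids[pd],
                               assoc$entries[pm, pd])
    g1 <- gip_similarity(assoc, "mirna")$values[pm, pm]
    g2 <- gip_similarity(perm, "mirna")$values
    expect_equal(unname(g1), unname(g2), tolerance = 1e-12)
    d1 <- gip_similarity(assoc, "disease")$values[pd, pd]
    d2 <- gip_similarity(perm, "disease")$values
    expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
  }
})

test_that("aggregate_similarity keeps primary values and fills with fallback", {
  ids <- c("a", "b", "c")
  primary <- similarity_matrix(ids, rbind(c(1, 0.6, 0),
                                          c(0.6, 1, 0),
                                          c(0, 0, 1)) - diag(0, 3), "MFS")
  fallback <- similarity_matrix(ids, rbind(c(1, 0.2, 0.3),
                                           c(0.2, 1, 0.4),
                                           c(0.3, 0.4, 1)), "MGS")
  agg <- aggregate_similarity(primary, fallback)
  expect_equal(agg$kind, "MF")
  expect_equal(agg$values["a", "b"], 0.6)   # primary wins where nonzero
  expect_equal(agg$values["a", "c"], 0.3)   # fallback fills zeros
  # information never decreases: zero only where both inputs are zero
  expect_true(all((agg$values == 0) <= (primary$values == 0 & fallback$values == 0)))
  # all-zero primary degenerates to the fallback
  pz <- similarity_matrix(ids, diag(0, 3) * 0, "MFS")
  expect_equal(aggregate_similarity(pz, fallback)$values, fallback$values)
  # registry mismatch is an error
  other <- similarity_matrix(c("x", "y", "z"), diag(3), "MGS")
  expect_error(aggregate_similarity(primary, other), "mismatch")
})

test_that("similarity_adjacency applies a strict threshold and no self-loops", {
  ids <- c("a", "b", "c")
  sim <- similarity_matrix(ids, rbind(c(1, 0.4, 0),
                                      c(0.4, 1, 0),
                                      c(0, 0, 1)), "MGS")
  adj0 <- similarity_adjacency(sim, 0)
  expect_equal(unname(adj0[1, ]), c(0, 1, 0))
  expect_equal(sum(adj0), 2)
  expect_true(all(diag(adj0) == 0))
  expect_equal(sum(similarity_adjacency(sim, 0.5)), 0)
  ident <- similarity_matrix(ids, diag(3), "MGS")
  expect_equal(sum(similarity_adjacency(ident, 0)), 0)
  expect_error(similarity_adjacency(sim, 1), "threshold")
})

test_that("hetero_adjacency builds the bipartite block matrix", {
  assoc <- association_matrix(c("m1", "m2"), c("d1", "d2"), diag(2))
  G <- hetero_adjacency(assoc)
  expect_equal(dim(G), c(4L, 4L))
  expect_equal(sum(G), 4)                      # 2 x associations
  expect_equal(G[1:2, 1:2], matrix(0, 2, 2, dimnames = list(c("m1", "m2"), c("m1", "m2"))))
  expect_equal(unname(G[1:2, 3:4]), unname(assoc$entries))
  expect_equal(G, t(G))
  empty <- association_matrix("m1", "d1", matrix(0, 1, 1))
  expect_equal(sum(hetero_adjacency(empty)), 0)
})

test_that("similarity_matrix enforces its invariants", {
  expect_error(similarity_matrix(c("a", "b"), rbind(c(1, 0.5), c(0.2, 1)), "DSS"),
               "symmetric")
  expect_error(similarity_matrix(c("a", "b"), rbind(c(1, 2), c(2, 1)), "DSS"),
               "\\[0, 1\\]")
  expect_error(similarity_matrix(c("a", "b"), rbind(c(0.5, 0.1), c(0.1, 0.5)), "DGS"),
               "diagonal")
})
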