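# Similarity kernels: semantic models, GIP, set/functional similarity,
# integration and thresholding, against hand-derived and brute-force oracles.

test_that("build_dag returns the ancestor closure with induced edges", {
  single <- disease_ontology("T", data.frame(child = character(0),
                                             parent = character(0)),
                             list(X = "T"))
  dag <- build_dag(single, "X")
  expect_equal(dag$nodes, "T")
  expect_equal(nrow(dag$edges), 0)

  dag <- build_dag(chain_ontology(), "X")
  expect_setequal(dag$nodes, c("c", "p", "g"))
  expect_equal(nrow(dag$edges), 2)

  dag <- build_dag(diamond_ontology(), "X")
  expect_setequal(dag$nodes, c("c", "p1", "p2", "g"))
  expect_equal(nrow(dag$edges), 4)

  expect_error(build_dag(chain_ontology(), "nope"), "no term")
})

test_that("cyclic edge relations are rejected", {
  expect_error(
    disease_ontology(c("a", "b"),
                     data.frame(child = c("a", "b"), parent = c("b", "a")),
                     list(X = "a")),
    "cycle"
  )
})

test_that("model-1 contributions decay by hop distance with a max rule", {
  ct <- semantic_contribution_m1(build_dag(chain_ontology(), "X"), 0.5)
  expect_equal(ct$contributions[c("c", "p", "g")],
               c(c = 1, p = 0.5, g = 0.25))
  expect_equal(semantic_value(ct), 1.75)

  ct <- semantic_contribution_m1(build_dag(diamond_ontology(), "X"), 0.5)
  expect_equal(unname(ct$contributions["g"]), 0.25)
  expect_equal(semantic_value(ct), 2.25)

  # extra direct edge c->g raises g to 0.5 by the max rule
  ct <- semantic_contribution_m1(build_dag(diamond_ontology(TRUE), "X"), 0.5)
  expect_equal(unname(ct$contributions["g"]), 0.5)
})

test_that("model-1 contributions match the path-enumeration oracle", {
  for (seed in 1:12) {
    n <- sample(4:12, 1)
    dag <- random_tree_dag(n, seed)
    delta <- 0.5
    got <- semantic_contribution_m1(dag, delta)$contributions
    want <- contribution_by_paths(dag, delta)
    expect_equal(got[dag$nodes], want[dag$nodes], tolerance = 1e-12)
  }
})

test_that("semantic similarity reproduces the hand-derived values", {
  onto <- shared_parent_ontology()
  ca <- semantic_contribution_m1(build_dag(onto, "A"), 0.5)
  cb <- semantic_contribution_m1(build_dag(onto, "B"), 0.5)
  expect_equal(semantic_similarity(ca, cb), 1 / 3, tolerance = 1e-6)
  expect_equal(semantic_similarity(ca, ca), 1)

  # disjoint DAGs
  onto2 <- disease_ontology(c("A", "B"),
                            data.frame(child = character(0),
                                       parent = character(0)),
                            list(A = "A", B = "B"))
  c1 <- semantic_contribution_m1(build_dag(onto2, "A"), 0.5)
  c2 <- semantic_contribution_m1(build_dag(onto2, "B"), 0.5)
  expect_equal(semantic_similarity(c1, c2), 0)
})

test_that("model-2 rarity contributions use the DAG-count log ratio", {
  onto <- shared_parent_ontology()
  ca <- semantic_contribution_m2(onto, "A")
  # P in 2/2 DAGs -> 0; A in 1/2 -> -ln(0.5)
  expect_equal(unname(ca$contributions["P"]), 0)
  expect_equal(unname(ca$contributions["A"]), log(2), tolerance = 1e-6)
  cb <- semantic_contribution_m2(onto, "B")
  expect_equal(semantic_similarity(ca, cb), 0)

  # -ln(1/4) for a term in 1 of 4 DAGs
  onto4 <- disease_ontology(
    c("r", "a", "b", "c", "d"),
    data.frame(child = c("a", "b", "c", "d"), parent = rep("r", 4)),
    list(A = "a", B = "b", C = "c", D = "d")
  )
  ct <- semantic_contribution_m2(onto4, "A")
  expect_equal(unname(ct$contributions["a"]), 1.38629, tolerance = 1e-5)
  expect_equal(unname(ct$contributions["r"]), 0)

  # similarity is invariant to the log base
  c10a <- semantic_contribution_m2(onto, "A", log_base = 10)
  c10b <- semantic_contribution_m2(onto, "B", log_base = 10)
  cea <- semantic_contribution_m2(onto4, "A")
  ceb <- semantic_contribution_m2(onto4, "B")
  c10a4 <- semantic_contribution_m2(onto4, "A", log_base = 10)
  c10b4 <- semantic_contribution_m2(onto4, "B", log_base = 10)
  expect_equal(semantic_similarity(c10a4, c10b4),
               semantic_similarity(cea, ceb), tolerance = 1e-12)
})

test_that("GIP kernel matches hand values and is scaling invariant", {
  P <- rbind(a = c(1, 0), b = c(0, 1))
  S <- gip_similarity(P, 0.5)
  expect_equal(S["a", "b"], exp(-1), tolerance = 1e-6)
  expect_equal(diag(S), c(a = 1, b = 1))

  # identical profiles
  P2 <- rbind(a = c(1, 1), b = c(1, 1))
  expect_equal(gip_similarity(P2, 0.5)["a", "b"], 1)

  # uniform positive scaling leaves the kernel unchanged
  set.seed(5)
  P3 <- matrix(rbinom(40, 1, 0.4), 8, 5,
               dimnames = list(letters[1:8], NULL))
  expect_equal(gip_similarity(P3, 0.5), gip_similarity(3.7 * P3, 0.5),
               tolerance = 1e-12)

  expect_error(gip_similarity(matrix(0, 2, 2,
                                     dimnames = list(c("a", "b"), NULL))),
               "zero")
})

test_that("disease-set similarity is the max over the set", {
  S <- toy_disease_sim()
  expect_equal(disease_set_similarity("d1", "d1", S), 1)
  expect_equal(disease_set_similarity("d3", c("d1", "d2"), S), 0.8)
  expect_equal(disease_set_similarity("d1", "d2", S), 0)
  expect_error(disease_set_similarity("d1", character(0), S), "empty")
})

test_that("functional similarity averages best matches over both sets", {
  FS <- mirna_functional_similarity(toy_associations(), toy_disease_sim())
  # DT1 = {d1,d2}, DT2 = {d3}: (0.4 + 0.8 + 0.8) / 3
  expect_equal(FS["m1", "m2"], 2 / 3, tolerance = 1e-6)
  expect_equal(diag(FS), c(m1 = 1, m2 = 1))

  # zero cross-similarity, disjoint sets -> 0
  S0 <- diag(1, 3)
  dimnames(S0) <- dimnames(toy_disease_sim())
  expect_equal(mirna_functional_similarity(toy_associations(), S0)["m1", "m2"],
               0)

  # miRNA with no diseases: zero row and a warning
  A <- rbind(m1 = c(1, 0, 0), m2 = c(0, 0, 0))
  colnames(A) <- colnames(toy_disease_sim())
  expect_warning(FS2 <- mirna_functional_similarity(A, toy_disease_sim()),
                 "no associated disease")
  expect_equal(FS2["m1", "m2"], 0)
  expect_equal(FS2["m2", "m2"], 1)
})

test_that("integration mixes semantic and kernel parts entrywise", {
  labs <- c("x", "y")
  mk <- function(v) matrix(c(1, v, v, 1), 2, 2, dimnames = list(labs, labs))
  D1 <- mk(0.4); D2 <- mk(0.6); G <- mk(0.8)
  expect_equal(integrate_similarity(list(D1, D2), G, 0.5)["x", "y"], 0.65)
  expect_equal(integrate_similarity(list(D1, D2), G, 1), (D1 + D2) / 2)
  expect_equal(integrate_similarity(list(D1, D2), G, 0), G)
  bad <- mk(0.5); dimnames(bad) <- list(c("a", "b"), c("a", "b"))
  expect_error(integrate_similarity(list(D1), bad, 0.5), "mismatch")
})

test_that("threshold filter keeps the boundary, diagonal and symmetry", {
  labs <- c("x", "y", "z")
  S <- matrix(c(1, 0.2, 0.3, 0.2, 1, 0.7, 0.3, 0.7, 1), 3, 3,
              dimnames = list(labs, labs))
  Ft <- threshold_filter(S, 0.3)
  expect_equal(Ft["x", "y"], 0)      # below
  expect_equal(Ft["x", "z"], 0.3)    # boundary kept (>= h)
  expect_equal(Ft["y", "z"], 0.7)
  expect_equal(diag(Ft), stats::setNames(rep(1, 3), labs))
  expect_equal(threshold_filter(S, 0), S)
  # idempotent and never increasing
  expect_equal(threshold_filter(Ft, 0.3), Ft)
  expect_true(all(Ft <= S))
})

test_that("every produced similarity matrix is symmetric and bounded", {
  b <- make_fixture_bundle(15, 10, n_groups = 3, p_in = 0.5, p_out = 0.05,
                           seed = 4)
  sims <- suppressWarnings(compute_similarities(b$A, b$ontology))
  for (nm in c("DSS1", "DSS2", "DGS", "MGS", "FS", "DS_prime", "MS_prime",
               "DS", "MS")) {
    expect_valid_similarity(sims[[nm]])
  }
  # model-1 self-similarity on the DSS1 diagonal
  expect_equal(unname(diag(sims$DSS1)), rep(1, 10))
})
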