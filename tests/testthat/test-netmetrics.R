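mat_of <- function(...) {
  v <- c(...)
  n <- sqrt(length(v))
  m <- matrix(v, n, n, byrow = TRUE)
  dimnames(m) <- list(letters[1:n], letters[1:n])
  m
}

test_that("metrics reproduce closed forms on small graphs", {
  # strength: two-term sum
  A <- mat_of(0, 0.5, 0.25,
              0.5, 0, 0,
              0.25, 0, 0)
  expect_equal(unname(ai_strength(A)["a"]), 0.75)
  expect_equal(unname(ai_strength(A, "b")), 0.5)
  expect_error(ai_strength(A, "zz"), "unknown")

  # complete graph with equal weights: all centralities 1/sqrt(4)
  K4 <- matrix(0.3, 4, 4); diag(K4) <- 0
  dimnames(K4) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(ai_eigenvector(K4)), rep(0.5, 4), tolerance = 1e-10)
  # scale invariance of the eigenvector
  expect_equal(ai_eigenvector(K4 * 3), ai_eigenvector(K4), tolerance = 1e-10)

  # star with centre-leaf weights 0.5: centre reach = 3 * 0.5 * 0.5,
  # leaf reach = 0.5 * 1.5
  S <- matrix(0, 4, 4); S[1, 2:4] <- S[2:4, 1] <- 0.5
  dimnames(S) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(ai_reach(S)), c(0.75, 0.75, 0.75, 0.75))
  # star centre has no closed triples
  expect_equal(unname(ai_clustering(S)["a"]), 0)

  # equal-weight triangle is fully clustered
  Tr <- matrix(0.5, 3, 3); diag(Tr) <- 0
  dimnames(Tr) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(ai_clustering(Tr)), rep(1, 3))

  # affinity of a node with one neighbour equals that neighbour's strength
  expect_equal(unname(ai_affinity(A)["b"]), unname(ai_strength(A)["a"]))
  # complete graph n = 4, w = 0.2: all strengths 0.6, affinity 0.6
  K <- matrix(0.2, 4, 4); diag(K) <- 0
  dimnames(K) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(ai_affinity(K)), rep(0.6, 4))

  # zero matrix: zero strength, undefined centrality
  Z <- matrix(0, 3, 3); dimnames(Z) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(ai_strength(Z)), rep(0, 3))
  expect_error(ai_eigenvector(Z), "undefined")
  expect_equal(unname(ai_reach(Z)), rep(0, 3))  # isolated nodes reach 0
  expect_true(all(is.na(ai_affinity(Z))))
})

test_that("metrics agree with explicit-summation oracles on random matrices", {
  for (seed in c(1, 8, 21)) {
    M <- random_sym_matrix(8, seed)
    expect_equal(unname(ai_strength(M)), oracle_strength(M),
                 tolerance = 1e-12)
    expect_equal(unname(ai_reach(M)), oracle_reach(M), tolerance = 1e-12)
    expect_equal(unname(ai_clustering(M)), oracle_clustering(M),
                 tolerance = 1e-12)
    got <- ai_eigenvector(M)
    expect_equal(unname(got), oracle_power_iteration(M), tolerance = 1e-8)
    expect_equal(sqrt(sum(got^2)), 1, tolerance = 1e-10)
    # affinity * strength == reach wherever strength > 0
    s <- ai_strength(M)
    expect_equal(unname((ai_affinity(M) * s)[s > 0]),
                 unname(ai_reach(M)[s > 0]), tolerance = 1e-12)
  }
})

test_that("structural invariants hold on random matrices", {
  for (seed in 1:20) {
    n <- sample(3:12, 1)
    M <- random_sym_matrix(n, seed + 100)
    s <- ai_strength(M)
    # handshake identity
    expect_equal(sum(s), 2 * sum(M[upper.tri(M)]), tolerance = 1e-12)
    # reach equals the row sums of the squared matrix
    M0 <- M; M0[is.na(M0)] <- 0
    expect_equal(unname(ai_reach(M)), unname(rowSums(M0 %*% M0)),
                 tolerance = 1e-12)
    # clustering stays within [0, 1]
    cl <- ai_clustering(M)
    expect_true(all(cl >= -1e-12 & cl <= 1 + 1e-12))
    # node relabeling permutes but does not change metric values
    perm <- sample(n)
    MP <- M[perm, perm]
    expect_equal(unname(ai_strength(MP)), unname(s[perm]),
                 tolerance = 1e-12)
    expect_equal(unname(ai_clustering(MP)), unname(cl[perm]),
                 tolerance = 1e-12)
  }
})

test_that("node_metrics is consistent with the individual metric calls", {
  M <- random_sym_matrix(20, 77)
  tab <- node_metrics(M)
  expect_equal(tab$strength, unname(ai_strength(M)))
  expect_equal(tab$eigenvector, unname(ai_eigenvector(M)))
  expect_equal(tab$reach, unname(ai_reach(M)))
  expect_equal(tab$clustering, unname(ai_clustering(M)))
  expect_equal(tab$affinity, unname(ai_affinity(M)))

  # 2-node network: equal strengths, zero clustering
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  tab2 <- node_metrics(two)
  expect_equal(tab2$strength, c(0.4, 0.4))
  expect_equal(tab2$clustering, c(0, 0))
})

test_that("disconnected networks warn and edgeless networks degrade to NA", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.9
  M[3, 4] <- M[4, 3] <- 0.2
  dimnames(M) <- list(letters[1:4], letters[1:4])
  expect_warning(v <- ai_eigenvector(M), "disconnected")
  expect_equal(unname(v), c(1, 1, 0, 0) / sqrt(2), tolerance = 1e-10)

  Z <- matrix(0, 3, 3); dimnames(Z) <- list(letters[1:3], letters[1:3])
  expect_warning(tab <- node_metrics(Z), "no edges")
  expect_true(all(is.na(tab$eigenvector)))
})

test_that("origin-wise metric summaries have the expected layout", {
  M <- random_sym_matrix(6, 3)
  metrics <- node_metrics(M)
  demo <- tibble::tibble(id = metrics$id,
                         origin = rep(c("wild", "sanctuary"), 3))
  s <- summarise_metrics(metrics, demo)
  expect_setequal(unique(s$metric),
                  c("strength", "eigenvector", "reach", "clustering",
                    "affinity"))
  expect_equal(nrow(s), 10)
  sw <- s[s$metric == "strength" & s$origin == "wild", ]
  expect_equal(sw$mean,
               mean(metrics$strength[demo$origin == "wild"]))
})
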