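metrics_fixture <- function(n_wild = 6, n_sanct = 6, shift = 0, seed = 5) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("I%02d", seq_len(n_wild + n_sanct)),
    origin = rep(c("wild", "sanctuary"), c(n_wild, n_sanct)),
    group_id = rep(c("G1", "G2"), length.out = n_wild + n_sanct),
    strength = rnorm(n_wild + n_sanct) +
      shift * rep(c(1, 0), c(n_wild, n_sanct)))
}

test_that("permutation test handles degenerate and trivial inputs", {
  m <- metrics_fixture()
  m$strength <- 1   # no variation at all: observed diff 0, every null ties
  res <- node_permutation_test(m, "strength", n_perm = 99, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)

  one_label <- m; one_label$origin <- "wild"
  expect_error(node_permutation_test(one_label, "strength"), "2 observed")
  expect_error(node_permutation_test(m, "strength", n_perm = 0), "positive")
})

test_that("permutation test is reproducible and two-tailed", {
  m <- metrics_fixture(shift = 1)
  a <- node_permutation_test(m, "strength", n_perm = 200, seed = 42)
  b <- node_permutation_test(m, "strength", n_perm = 200, seed = 42)
  expect_identical(a$null, b$null)
  expect_identical(a$p_value, b$p_value)

  # swapping the label names flips the sign but not the p-value
  sw <- m
  sw$origin <- ifelse(m$origin == "wild", "aaa", "zzz")
  res <- node_permutation_test(m, "strength", n_perm = 500, seed = 9)
  res_sw <- node_permutation_test(sw, "strength", n_perm = 500, seed = 9)
  expect_equal(res_sw$p_value, res$p_value)
  expect_equal(abs(res_sw$observed), abs(res$observed))
})

test_that("exhaustive enumeration reproduces the brute-force exact p-value", {
  # the 3-vs-3 separation case: only the mirror assignment ties |observed|
  m <- tibble::tibble(id = letters[1:6],
                      origin = rep(c("wild", "sanctuary"), each = 3),
                      strength = c(1, 1, 1, 0, 0, 0))
  res <- node_permutation_test(m, "strength", exhaustive = TRUE)
  expect_equal(res$n_perm, choose(6, 3))
  expect_equal(res$p_value,
               oracle_exact_perm_p(m$strength, m$origin, "wild"))
  expect_equal(res$p_value, 2 / 20)

  # random values, several sizes
  for (seed in c(2, 4, 6)) {
    set.seed(seed)
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    mm <- tibble::tibble(id = seq_len(n1 + n2),
                         origin = rep(c("wild", "sanctuary"), c(n1, n2)),
                         strength = rnorm(n1 + n2))
    res <- node_permutation_test(mm, "strength", exhaustive = TRUE)
    expect_equal(res$p_value,
                 oracle_exact_perm_p(mm$strength, mm$origin, "wild"),
                 tolerance = 1e-12)
  }
})

test_that("stratified permutation preserves per-group label counts", {
  m <- metrics_fixture(8, 4)
  res <- node_permutation_test(m, "strength", n_perm = 50, seed = 3,
                               stratify_by = "group_id")
  expect_s3_class(res, "perm_test")
  expect_true(res$stratified)
  # directly check the stratified shuffler
  lab <- m$origin; strata <- m$group_id
  set.seed(1)
  for (r in 1:20) {
    perm <- focalnet:::permute_within(lab, strata)
    for (g in unique(strata)) {
      expect_equal(table(perm[strata == g]), table(lab[strata == g]))
    }
  }
})

test_that("missing metric values are dropped with a message", {
  m <- metrics_fixture()
  m$strength[c(1, 12)] <- NA
  expect_message(res <- node_permutation_test(m, "strength", n_perm = 50,
                                              seed = 2),
                 "dropping 2")
  expect_equal(res$n, 10)
})

test_that("Holm correction reproduces textbook step-down values", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_correct(c(0.01, 0.02, 0.5)), c(0.03, 0.04, 0.5))
  # monotonicity enforcement and order preservation
  p <- c(0.04, 0.001, 0.3, 0.02)
  adj <- holm_correct(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p))
  expect_error(holm_correct(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_named(holm_correct(c(a = 0.01, b = 0.2), labels = c("s", "t")),
               c("s", "t"))
})

test_that("likelihood-ratio test behaves across nesting situations", {
  set.seed(10)
  d <- data.frame(y = rpois(200, 5), x = rnorm(200), z = rnorm(200))
  full <- glm(y ~ x + z, family = poisson, data = d)
  red <- glm(y ~ x, family = poisson, data = d)
  res <- lr_test(full, red)
  expect_equal(res$df, 1)
  expect_equal(res$chi2, 2 * (as.numeric(logLik(full)) -
                                as.numeric(logLik(red))))
  expect_gte(res$chi2, 0)
  # identical models: zero statistic, p = 1
  same <- lr_test(full, glm(y ~ x + z, family = poisson, data = d))
  expect_equal(same$chi2, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1)
  # reversed nesting is an error
  expect_error(lr_test(red, full), "not nested")
  # different data sizes are an error
  red2 <- glm(y ~ x, family = poisson, data = d[1:100, ])
  expect_error(lr_test(full, red2), "different numbers")
})

test_that("LRT p-values are approximately uniform under the null", {
  set.seed(99)
  ps <- replicate(400, {
    d <- data.frame(y = rpois(120, 4), x = rnorm(120))
    lr_test(glm(y ~ x, family = poisson, data = d),
            glm(y ~ 1, family = poisson, data = d))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("leave-one-out stability flags planted outliers and only them", {
  fit_fun <- function(d) glm(y ~ x, data = d)
  extract_fun <- function(f) {
    s <- summary(f)$coefficients
    c(s["x", 1], s["x", 2])
  }
  set.seed(4)
  base <- tibble::tibble(
    focal_id = rep(sprintf("S%02d", 1:10), each = 5),
    x = rep(rnorm(10), each = 5))
  base$y <- 2 * base$x + rnorm(nrow(base), sd = 0.1)

  # exchangeable subjects: nothing flagged
  calm <- loo_stability(base, fit_fun, extract_fun)
  expect_equal(nrow(calm), 10)            # exactly one refit per subject
  expect_false(any(calm$flagged))

  # plant one high-leverage, discordant subject
  planted <- base
  planted$x[planted$focal_id == "S03"] <- 8
  planted$y[planted$focal_id == "S03"] <- 0
  res <- loo_stability(planted, fit_fun, extract_fun)
  expect_true(res$flagged[res$subject == "S03"])
  expect_equal(res$subject[which.max(abs(res$delta_se))], "S03")
  expect_error(loo_stability(base[1:10, ], fit_fun, extract_fun),
               "at least 3")
})
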