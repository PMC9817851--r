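# Direct Poisson data at the model's own level, for fitter checks.
sim_party_records <- function(n_focals = 60, follows_each = 25,
                              beta_origin = 0, seed = 1,
                              greg_sd = 0) {
  set.seed(seed)
  focals <- sprintf("F%03d", seq_len(n_focals))
  origin <- rep(c("sanctuary", "wild"), length.out = n_focals)
  u <- rnorm(n_focals, 0, greg_sd)
  d <- tidyr::expand_grid(focal_id = focals, rep = seq_len(follows_each))
  i <- match(d$focal_id, focals)
  d$origin <- factor(origin[i], levels = c("sanctuary", "wild"))
  d$sex <- factor(sample(c("F", "M"), n_focals, replace = TRUE)[i],
                  levels = c("F", "M"))
  d$rank_z <- rnorm(n_focals)[i]
  d$age_z <- rnorm(n_focals)[i]
  d$group_id <- "G1"
  d$log_duration_offset <- log(runif(nrow(d), 0.5, 1))
  d$log_popsize_offset <- 0
  d$log_family_units_offset <- 0
  lambda <- exp(log(5) + beta_origin * (d$origin == "wild") + u[i] +
                  d$log_duration_offset)
  d$associates <- rpois(nrow(d), lambda)
  d$party_size <- d$associates + 1L
  d$follow_id <- sprintf("f%05d", seq_len(nrow(d)))
  d$date <- as.Date("2020-01-01") + d$rep
  d$arrival_age_years <- ifelse(d$origin == "wild",
                                rep(runif(n_focals, 0.5, 8), length.out = n_focals)[i],
                                NA)
  d
}

test_that("party size is defined as party members plus the focal", {
  expect_equal(party_size(character(0)), 1L)
  expect_equal(party_size(c("a", "b", "c", "d", "e")), 6L)
  set.seed(2)
  k <- sample(0:10, 1)
  expect_equal(party_size(sprintf("x%d", seq_len(k))), k + 1L)
  # and build_party_table agrees on real structures
  pt <- build_party_table(toy_obs())
  expect_equal(pt$party_size, lengths(toy_follows()$party_member_ids) + 1L)
  expect_equal(pt$associates, pt$party_size - 1L)
})

test_that("party table carries offsets and standardised covariates", {
  pt <- build_party_table(toy_obs())
  expect_equal(pt$log_duration_offset, log(c(600, 450, 580) / 600))
  expect_equal(pt$log_popsize_offset, rep(log(4), 3))
  # matrilines: M1, M2 and one NA singleton -> 3 family units
  expect_equal(pt$log_family_units_offset, rep(log(3), 3))
  expect_equal(levels(pt$origin), c("sanctuary", "wild"))
})

test_that("Poisson fit with no informative covariates recovers the closed-form intercept", {
  d <- sim_party_records(n_focals = 40, follows_each = 10, seed = 3)
  # constant covariates collapse the model to intercept + offset
  d$rank_z <- 0; d$age_z <- 0; d$sex <- factor("F", levels = c("F", "M"))
  fit <- fit_party_size(d, include_origin = FALSE,
                        random_intercepts = "none",
                        demographic_offsets = "none")
  expect_equal(unname(coef(fit$model)["(Intercept)"]),
               log(sum(d$associates) / sum(exp(d$log_duration_offset))),
               tolerance = 1e-8)
})

test_that("offset algebra: doubling durations shifts the intercept by -log 2", {
  d <- sim_party_records(n_focals = 30, follows_each = 8, seed = 6)
  fit1 <- fit_party_size(d, random_intercepts = "none",
                         demographic_offsets = "none")
  d2 <- d
  d2$log_duration_offset <- d$log_duration_offset + log(2)
  fit2 <- fit_party_size(d2, random_intercepts = "none",
                         demographic_offsets = "none")
  c1 <- coef(fit1$model); c2 <- coef(fit2$model)
  expect_equal(unname(c2["(Intercept)"] - c1["(Intercept)"]), -log(2),
               tolerance = 1e-9)
  expect_equal(c1[-1], c2[-1], tolerance = 1e-9)
})

test_that("the origin coefficient is recovered from model-level simulations", {
  d <- sim_party_records(n_focals = 80, follows_each = 25,
                         beta_origin = -0.3, seed = 8)
  ot <- party_origin_test(d, random_intercepts = "none",
                          demographic_offsets = "none")
  expect_lt(abs(ot$estimate - (-0.3)), 3 * ot$se)
  expect_lt(ot$lrt$p_value, 0.05)
  expect_equal(ot$lrt$df, 1)

  # balanced null at large n: estimate near zero
  d0 <- sim_party_records(n_focals = 120, follows_each = 40,
                          beta_origin = 0, seed = 9)
  ot0 <- party_origin_test(d0, random_intercepts = "none",
                           demographic_offsets = "none")
  expect_lt(abs(ot0$estimate), 0.05)
})

test_that("focal random intercepts absorb between-individual heterogeneity", {
  d <- sim_party_records(n_focals = 60, follows_each = 15,
                         beta_origin = -0.3, greg_sd = 0.3, seed = 12)
  ot <- party_origin_test(d, random_intercepts = "focal",
                          demographic_offsets = "none")
  expect_s4_class(ot$full$model, "glmerMod")
  expect_lt(abs(ot$estimate - (-0.3)), 3 * ot$se)
  # the random-intercept SD estimate should be in the right region
  vc <- lme4::VarCorr(ot$full$model)
  expect_gt(sqrt(vc$focal_id[1]), 0.1)
})

test_that("model fits are deterministic given the data", {
  d <- sim_party_records(30, 6, seed = 21)
  f1 <- fit_party_size(d, random_intercepts = "none")
  f2 <- fit_party_size(d, random_intercepts = "none")
  expect_identical(coef(f1$model), coef(f2$model))
  expect_identical(as.numeric(logLik(f1)), as.numeric(logLik(f2)))
})

test_that("early/late contrast splits at the cutoff with >= going to later", {
  d <- sim_party_records(n_focals = 40, follows_each = 6, seed = 30)
  wild_focals <- unique(d$focal_id[d$origin == "wild"])
  per_focal_age <- rep(c(1, 2, 3, 5), length.out = length(wild_focals))
  d$arrival_age_years <- per_focal_age[match(d$focal_id, wild_focals)]
  res <- early_late_contrast(d, cutoff_years = 3,
                             random_intercepts = "none",
                             demographic_offsets = "none")
  strat <- res$data |>
    dplyr::distinct(.data$focal_id, .data$arrival_age_years,
                    .data$arrival_stratum)
  expect_true(all(strat$arrival_stratum[strat$arrival_age_years == 3] ==
                    "later"))
  expect_true(all(strat$arrival_stratum[strat$arrival_age_years < 3] ==
                    "early"))
  expect_equal(res$lrt$df, 1)

  # single-stratum data cannot be contrasted
  d_all_early <- d
  d_all_early$arrival_age_years[d_all_early$origin == "wild"] <- 1
  expect_error(early_late_contrast(d_all_early, random_intercepts = "none"),
               "both strata")
})

test_that("dyad tables enumerate covariate combinations correctly", {
  demo <- toy_demographics()   # ann(w), bob(s), cleo(w), dan(s)
  A <- matrix(c(NA, 0.2, 0, 0.1,
                0.2, NA, 0.3, 0,
                0, 0.3, NA, NA,
                0.1, 0, NA, NA), 4, 4,
              dimnames = list(demo$id, demo$id))
  dy <- build_dyad_table(A, demo, adult_cutoff_years = 12)
  expect_equal(nrow(dy), 6)
  expect_equal(sort(as.character(dy$dyad_origin)),
               sort(c("WS", "WW", "WS", "WS", "SS", "WS")))
  # ann & bob share matriline M1; dan's NA matriline never matches
  expect_true(dy$same_matriline[dy$id_a == "ann" & dy$id_b == "bob"])
  expect_false(any(dy$same_matriline[dy$id_a == "dan" | dy$id_b == "dan"]))
  # ages 15, 8, 22, 30 with cutoff 12: bob is the only subadult
  expect_equal(sum(dy$dyad_age == "subadult-adult"), 3)
  expect_equal(sum(dy$dyad_age == "adult-adult"), 3)
  # missing AI rows keep NA and are flagged as such
  expect_true(is.na(dy$ai[dy$id_a == "cleo" & dy$id_b == "dan"]))

  # category counts match exhaustive enumeration on a larger table
  set.seed(14)
  demo10 <- tibble::tibble(
    id = sprintf("x%02d", 1:10), group_id = "G1",
    origin = sample(c("wild", "sanctuary"), 10, TRUE),
    sex = sample(c("F", "M"), 10, TRUE),
    age_years = runif(10, 4, 30),
    arrival_age_years = NA_real_, rank = runif(10),
    matriline_id = sample(c("M1", "M2", "M3"), 10, TRUE))
  demo10$arrival_age_years[demo10$origin == "wild"] <- 3
  M <- random_sym_matrix(10, 15)
  dimnames(M) <- list(demo10$id, demo10$id)
  dy10 <- build_dyad_table(M, demo10)
  expect_equal(nrow(dy10), choose(10, 2))
  n_wild_pairs <- sum(outer(demo10$origin == "wild",
                            demo10$origin == "wild", `&`)[upper.tri(M)])
  expect_equal(sum(dy10$dyad_origin == "WW"), n_wild_pairs)
})

test_that("hurdle model factorises: parts are independent and logliks add", {
  truth <- synth_scenario("paper_like")$hurdle_truth
  dy <- simulate_hurdle_dyads(800, truth$beta_binomial, truth$beta_gamma,
                              shape = truth$shape, seed = 51)
  fit <- fit_hurdle(dy)
  expect_equal(fit$loglik_total, fit$loglik_binomial + fit$loglik_gamma)

  # perturbing zero rows never changes the gamma part
  dy2 <- dy
  zero_rows <- which(dy2$ai == 0)
  dy2$dyad_sex[zero_rows] <- sample(dy2$dyad_sex[zero_rows])
  fit2 <- fit_hurdle(dy2)
  expect_equal(coef(fit2$gamma), coef(fit$gamma), tolerance = 1e-12)

  # degenerate tables are errors
  all_zero <- dy; all_zero$ai <- 0; all_zero$nonzero <- FALSE
  expect_error(fit_hurdle(all_zero), "gamma part unfittable")
  all_pos <- dy[dy$ai > 0, ]
  expect_error(fit_hurdle(all_pos), "no zero")
})

test_that("hurdle coefficients are recovered from two-part simulations", {
  truth <- synth_scenario("strong_effect")$hurdle_truth
  dy <- simulate_hurdle_dyads(3000, truth$beta_binomial, truth$beta_gamma,
                              shape = truth$shape, seed = 52)
  fit <- fit_hurdle(dy)
  tb <- tidy(fit)
  for (term in c("dyad_originWW", "dyad_originWS", "same_matrilineTRUE")) {
    row_b <- tb[tb$part == "binomial" & tb$term == term, ]
    expect_lt(abs(row_b$estimate - truth$beta_binomial[[term]]),
              3 * row_b$std.error)
    row_g <- tb[tb$part == "gamma" & tb$term == term, ]
    expect_lt(abs(row_g$estimate - truth$beta_gamma[[term]]),
              3 * row_g$std.error)
  }
  # gamma shape estimated in the right region
  expect_lt(abs(fit$gamma_shape - truth$shape) / truth$shape, 0.25)
})

test_that("hurdle origin LRT sums parts and detects injected effects", {
  truth <- synth_scenario("strong_effect")$hurdle_truth
  dy <- simulate_hurdle_dyads(2000, truth$beta_binomial, truth$beta_gamma,
                              shape = truth$shape, seed = 53)
  ht <- hurdle_origin_test(dy)
  expect_equal(ht$joint$chi2, ht$binomial$chi2 + ht$gamma$chi2)
  expect_equal(ht$joint$df, ht$binomial$df + ht$gamma$df)
  expect_lt(ht$joint$p_value, 0.001)
  expect_gte(ht$binomial$chi2, 0)
  expect_gte(ht$gamma$chi2, 0)
})

test_that("tidiers return well-formed tibbles", {
  d <- sim_party_records(30, 6, seed = 61)
  fit <- fit_party_size(d, random_intercepts = "none")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  expect_true("originwild" %in% td$term)
  gl <- glance(fit)
  # the default fit works on the exact per-focal aggregation
  expect_equal(gl$nobs, dplyr::n_distinct(d$focal_id))

  truth <- synth_scenario("null")$hurdle_truth
  dy <- simulate_hurdle_dyads(400, truth$beta_binomial, truth$beta_gamma,
                              seed = 62)
  hf <- fit_hurdle(dy)
  expect_setequal(unique(tidy(hf)$part), c("binomial", "gamma"))
  expect_equal(glance(hf)$n, 400)
})
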