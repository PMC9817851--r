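# broom-style tidiers for fitted objects.

glm_tidy <- function(model) {
  s <- summary(model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::tidy
tidy.party_fit <- function(x, ...) {
  m <- x$model
  if (inherits(m, "merMod")) {
    s <- summary(m)$coefficients
    tibble(term = rownames(s), estimate = s[, "Estimate"],
           std.error = s[, "Std. Error"], statistic = s[, "z value"],
           p.value = s[, "Pr(>|z|)"])
  } else {
    glm_tidy(m)
  }
}

#' @exportS3Method generics::glance
glance.party_fit <- function(x, ...) {
  ll <- logLik(x)
  tibble(logLik = as.numeric(ll), df = attr(ll, "df"),
         AIC = stats::AIC(x$model), nobs = nobs(x),
         response = x$response,
         random_intercepts = x$random_intercepts)
}

#' @exportS3Method generics::tidy
tidy.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(
    glm_tidy(x$binomial) |> mutate(part = "binomial"),
    glm_tidy(x$gamma) |> mutate(part = "gamma")
  ) |> select("part", dplyr::everything())
}

#' @exportS3Method generics::glance
glance.hurdle_fit <- function(x, ...) {
  tibble(loglik_binomial = x$loglik_binomial,
         loglik_gamma = x$loglik_gamma,
         loglik_total = x$loglik_total,
         gamma_shape = x$gamma_shape,
         n = x$n, n_nonzero = x$n_nonzero)
}

#' @exportS3Method generics::tidy
tidy.hurdle_test <- function(x, ...) {
  tibble(part = c("binomial", "gamma", "joint"),
         statistic = c(x$binomial$chi2, x$gamma$chi2, x$joint$chi2),
         df = c(x$binomial$df, x$gamma$df, x$joint$df),
         p.value = c(x$binomial$p_value, x$gamma$p_value,
                     x$joint$p_value))
}

#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) {
  tibble(metric = x$metric,
         estimate = x$observed,
         statistic_type = paste0("difference in ", x$stat, "s (",
                                 x$levels[1], " - ", x$levels[2], ")"),
         p.value = x$p_value,
         n_perm = x$n_perm,
         exhaustive = x$exhaustive,
         n = x$n)
}

#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(observed = x$observed, p.value = x$p_value, n_perm = x$n_perm,
         null_mean = mean(x$null), null_sd = sd(x$null),
         exhaustive = x$exhaustive, stratified = x$stratified)
}

#' @exportS3Method generics::tidy
tidy.lrt_result <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
         loglik_full = x$loglik_full, loglik_null = x$loglik_null)
}

#' @exportS3Method generics::tidy
tidy.origin_test <- function(x, ...) {
  tidy(x$lrt) |> mutate(term = x$term, estimate = x$estimate,
                        std.error = x$se) |>
    select("term", "estimate", "std.error", dplyr::everything())
}
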