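# Party-size Poisson regression with observation-effort offsets, and the
# two-part (hurdle) model for dyadic association indices.

#' Build the party-size modelling table
#'
#' One row per retained focal follow, joined with the focal's
#' demographics. Party size counts every individual in the focal's party
#' *including the focal*; the modelled response `associates` is party size
#' minus one, so its Poisson support starts at zero. Rank and age are
#' z-transformed across the individuals in the dataset. Offsets are logs
#' of: in-view time relative to `baseline_seconds` (observation effort),
#' group size, and the number of family units (matrilines) per group.
#'
#' @param obs An `observation_data` object.
#' @param baseline_seconds Reference follow duration for the effort
#'   offset (the nominal full follow length).
#' @return Tibble with columns `follow_id`, `focal_id`, `date`,
#'   `group_id`, `party_size`, `associates`, `origin`, `sex`, `rank_z`,
#'   `age_z`, `arrival_age_years`, and the three log-offsets.
#' @export
build_party_table <- function(obs, baseline_seconds = 600) {
  stopifnot(inherits(obs, "observation_data"))
  demo <- obs$demographics |>
    mutate(rank_z = z_score(.data$rank), age_z = z_score(.data$age_years))
  group_info <- demo |>
    group_by(.data$group_id) |>
    summarise(
      pop_size = dplyr::n(),
      family_units = dplyr::n_distinct(.data$matriline_id, na.rm = TRUE) +
        sum(is.na(.data$matriline_id)),
      .groups = "drop")

  obs$follows |>
    mutate(party_size = lengths(.data$party_member_ids) + 1L,
           associates = .data$party_size - 1L) |>
    left_join(select(demo, "id", "origin", "sex", "rank_z", "age_z",
                     "arrival_age_years"),
              by = c(focal_id = "id")) |>
    left_join(group_info, by = "group_id") |>
    mutate(
      origin = factor(.data$origin, levels = c("sanctuary", "wild")),
      sex = factor(.data$sex, levels = c("F", "M")),
      log_duration_offset = log(.data$in_view_seconds / baseline_seconds),
      log_popsize_offset = log(.data$pop_size),
      log_family_units_offset = log(.data$family_units)) |>
    select("follow_id", "focal_id", "date", "group_id", "party_size",
           "associates", "origin", "sex", "rank_z", "age_z",
           "arrival_age_years", "log_duration_offset", "log_popsize_offset",
           "log_family_units_offset")
}

z_score <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Party size of a single follow
#'
#' Number of individuals in the focal's party composition, including the
#' focal itself.
#'
#' @param party_member_ids Character vector (or list of vectors) of party
#'   members excluding the focal.
#' @return Integer party size(s), at least 1.
#' @export
party_size <- function(party_member_ids) {
  if (is.list(party_member_ids)) lengths(party_member_ids) + 1L
  else length(party_member_ids) + 1L
}

focal_constant <- function(data, vars) {
  all(vapply(vars, function(v) {
    all(tapply(as.character(data[[v]]), data$focal_id,
               function(x) length(unique(x)) == 1))
  }, logical(1)))
}

build_party_offset <- function(data, demographic_offsets) {
  off <- data$log_duration_offset
  if (demographic_offsets == "separate") {
    off <- off + data$log_popsize_offset + data$log_family_units_offset
  } else if (demographic_offsets == "ratio") {
    off <- off + data$log_popsize_offset - data$log_family_units_offset
  }
  off
}

# Shared fitting engine: Poisson log-link on `response` with the requested
# fixed terms, offsets, and random-intercept structure. Factor terms that
# collapse to a single observed level are dropped so degenerate subsets
# (e.g. a single-sex stratum) still fit.
#
# When every covariate is constant within focal (the default model), the
# per-follow Poisson likelihood factorises through the per-focal totals:
# conditional on a focal's random intercept the follows are independent
# Poissons, so the summed count with a log-sum-exp effort offset is
# sufficient, and the split across follows contributes only a
# parameter-free multinomial constant. Fitting the aggregated
# representation gives identical coefficients and likelihood-ratio
# statistics at a fraction of the cost; `aggregate = FALSE` forces the
# follow-level fit.
fit_party_glm <- function(data, terms, response, random_intercepts,
                          demographic_offsets, aggregate = TRUE, ...) {
  data <- as_tibble(data)
  data$.response <- data[[response]]
  data$.offset <- build_party_offset(data, demographic_offsets)

  keep <- vapply(terms, function(tm) {
    v <- all.vars(as.formula(paste("~", tm)))
    all(vapply(v, function(vv) {
      col <- data[[vv]]
      !(is.factor(col) || is.character(col)) ||
        dplyr::n_distinct(col[!is.na(col)]) > 1
    }, logical(1)))
  }, logical(1))
  terms <- terms[keep]
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")

  if (aggregate) {
    vars <- unique(unlist(lapply(terms, function(tm)
      all.vars(as.formula(paste("~", tm))))))
    if (focal_constant(data, vars)) {
      data <- data |>
        group_by(dplyr::across(dplyr::all_of(c("focal_id", "group_id",
                                               vars)))) |>
        summarise(.response = sum(.data$.response),
                  .offset = log(sum(exp(.data$.offset))),
                  .groups = "drop")
    } else {
      warn("covariates vary within focal; falling back to the follow-level fit")
    }
  }

  if (random_intercepts == "none") {
    fml <- as.formula(paste(".response ~", rhs, "+ offset(.offset)"))
    model <- glm(fml, family = stats::poisson(), data = data, ...)
  } else {
    re <- switch(random_intercepts,
                 focal = "(1 | focal_id)",
                 focal_group = "(1 | focal_id) + (1 | group_id)")
    fml <- as.formula(paste(".response ~", rhs, "+", re, "+ offset(.offset)"))
    model <- lme4::glmer(fml, family = stats::poisson(), data = data, ...)
    if (!is.null(model@optinfo$conv$lme4$messages)) {
      warn(paste("party-size model convergence:",
                 paste(model@optinfo$conv$lme4$messages, collapse = "; ")))
    }
  }
  model
}

#' Fit the party-size Poisson model
#'
#' Poisson log-link regression of party size on origin, standardised rank
#' and age, and sex, with observation effort (log in-view time) and
#' optionally demographic structure (log group size and log family units
#' per group) as offsets. The default response is the associate count
#' (party size minus the focal); `response = "size"` models the full
#' party size. Random intercepts use `lme4::glmer`: per focal
#' (`"focal"`, the default — repeated follows of one individual are not
#' independent), per focal and group (`"focal_group"`), or none
#' (`"none"`, a plain `glm`). This is a deliberately simplified
#' random-effect structure: the target quantity is the likelihood-ratio
#' test on a fixed effect, for which focal-level intercepts capture the
#' dominant dependence.
#'
#' @param party Tibble from [build_party_table()].
#' @param include_origin Include the origin fixed effect (the null model
#'   for the origin LRT omits it).
#' @param response `"associates"` (default) or `"size"`.
#' @param random_intercepts `"focal"`, `"focal_group"`, or `"none"`.
#' @param demographic_offsets `"separate"` (log group size and log family
#'   units as two offsets, the default), `"ratio"` (log of group size per
#'   family unit), or `"none"` (effort offset only).
#' @param aggregate Fit on per-focal totals (exact for focal-level
#'   covariates, much faster; see Details) instead of per-follow rows.
#' @param ... Passed to the underlying `glm`/`glmer` call.
#' @return A `party_fit` object wrapping the fitted model; supports
#'   [tidy()], [glance()], [stats::logLik()], [stats::nobs()].
#' @export
fit_party_size <- function(party, include_origin = TRUE,
                           response = c("associates", "size"),
                           random_intercepts = c("focal", "focal_group", "none"),
                           demographic_offsets = c("separate", "ratio", "none"),
                           aggregate = TRUE, ...) {
  response <- match.arg(response)
  random_intercepts <- match.arg(random_intercepts)
  demographic_offsets <- match.arg(demographic_offsets)
  assert_columns(party, c("associates", "party_size", "origin", "sex",
                          "rank_z", "age_z", "focal_id", "group_id",
                          "log_duration_offset"), "party table")
  if (include_origin && dplyr::n_distinct(party$origin) < 2) {
    abort("include_origin requires both origin levels in the data")
  }
  resp_col <- if (response == "associates") "associates" else "party_size"
  terms <- c(if (include_origin) "origin", "rank_z", "age_z", "sex")
  model <- fit_party_glm(party, terms, resp_col, random_intercepts,
                         demographic_offsets, aggregate = aggregate, ...)
  structure(list(model = model, response = response,
                 random_intercepts = random_intercepts,
                 demographic_offsets = demographic_offsets,
                 include_origin = include_origin,
                 note = "random-effect structure simplified to random intercepts"),
            class = "party_fit")
}

#' @export
logLik.party_fit <- function(object, ...) logLik(object$model, ...)

#' @export
nobs.party_fit <- function(object, ...) nobs(object$model, ...)

#' @export
print.party_fit <- function(x, ...) {
  cat(sprintf("<party_fit> Poisson(log) on %s; random intercepts: %s; offsets: effort + %s\n",
              x$response, x$random_intercepts, x$demographic_offsets))
  print(tidy(x))
  invisible(x)
}

# Wald estimate and SE for a fixed-effect coefficient, glm or merMod.
coef_se <- function(model, term) {
  if (inherits(model, "merMod")) {
    est <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
  } else {
    est <- coef(model)
    V <- vcov(model)
  }
  if (!term %in% names(est)) {
    abort(sprintf("coefficient '%s' not in model (has: %s)", term,
                  paste(names(est), collapse = ", ")))
  }
  c(estimate = unname(est[term]), se = sqrt(V[term, term]))
}

#' Test the origin effect on party size
#'
#' Fits the full party-size model and the null model without the origin
#' term, and compares them with a likelihood-ratio test.
#'
#' @inheritParams fit_party_size
#' @return A list of class `origin_test`: `full` and `null` ([fit_party_size()]
#'   fits), `lrt` (an `lrt_result`), `term` (the tested coefficient name),
#'   and `estimate`/`se` for the origin coefficient.
#' @export
party_origin_test <- function(party, response = c("associates", "size"),
                              random_intercepts = c("focal", "focal_group", "none"),
                              demographic_offsets = c("separate", "ratio", "none"),
                              aggregate = TRUE, ...) {
  # the LRT needs both fits in the same representation
  aggregate <- aggregate &&
    focal_constant(party, c("origin", "rank_z", "age_z", "sex"))
  full <- fit_party_size(party, include_origin = TRUE, response = response,
                         random_intercepts = random_intercepts,
                         demographic_offsets = demographic_offsets,
                         aggregate = aggregate, ...)
  null <- fit_party_size(party, include_origin = FALSE, response = response,
                         random_intercepts = random_intercepts,
                         demographic_offsets = demographic_offsets,
                         aggregate = aggregate, ...)
  est <- coef_se(full$model, "originwild")
  structure(list(full = full, null = null, lrt = lr_test(full, null),
                 term = "originwild",
                 estimate = est[["estimate"]], se = est[["se"]]),
            class = "origin_test")
}

#' @export
print.origin_test <- function(x, ...) {
  cat(sprintf("Origin effect (%s): estimate = %.4g +/- %.4g\n",
              x$term, x$estimate, x$se))
  print(x$lrt)
  invisible(x)
}

#' Test whether the origin effect differs across groups
#'
#' Adds a fixed origin-by-group interaction on top of origin and group
#' main effects and tests it with an LRT. Offered as a fixed-effect
#' approximation to a fully crossed interaction structure.
#'
#' @inheritParams fit_party_size
#' @return An `origin_test`-style list (`full`, `null`, `lrt`).
#' @export
party_interaction_test <- function(party,
                                   response = c("associates", "size"),
                                   random_intercepts = c("focal", "focal_group", "none"),
                                   demographic_offsets = c("separate", "ratio", "none"),
                                   ...) {
  response <- match.arg(response)
  random_intercepts <- match.arg(random_intercepts)
  demographic_offsets <- match.arg(demographic_offsets)
  resp_col <- if (response == "associates") "associates" else "party_size"
  base_terms <- c("origin", "group_id", "rank_z", "age_z", "sex")
  agg <- focal_constant(party, base_terms)
  full <- fit_party_glm(party, c(base_terms, "origin:group_id"), resp_col,
                        random_intercepts, demographic_offsets,
                        aggregate = agg, ...)
  null <- fit_party_glm(party, base_terms, resp_col,
                        random_intercepts, demographic_offsets,
                        aggregate = agg, ...)
  structure(list(full = full, null = null, lrt = lr_test(full, null),
                 term = "origin:group_id"),
            class = "origin_test_lite")
}

#' @export
print.origin_test_lite <- function(x, ...) {
  cat(sprintf("Interaction test (%s):\n", x$term))
  print(x$lrt)
  invisible(x)
}

#' Early- versus later-orphaned contrast on party size
#'
#' Among wild-born individuals only, splits subjects into early
#' (`arrival_age_years < cutoff_years`) and later (`>= cutoff_years`)
#' orphans — arrival age proxies the age at maternal loss — and tests the
#' binary contrast with the same Poisson model family as
#' [fit_party_size()].
#'
#' @inheritParams fit_party_size
#' @param cutoff_years Arrival-age cutoff; an arrival age exactly at the
#'   cutoff counts as *later*-orphaned.
#' @return A list of class `early_late_test`: `full`, `null`, `lrt`,
#'   `estimate`, `se`, and `data` (the wild-born subset with its
#'   `arrival_stratum` column).
#' @export
early_late_contrast <- function(party, cutoff_years = 3,
                                response = c("associates", "size"),
                                random_intercepts = c("focal", "focal_group", "none"),
                                demographic_offsets = c("separate", "ratio", "none"),
                                ...) {
  response <- match.arg(response)
  random_intercepts <- match.arg(random_intercepts)
  demographic_offsets <- match.arg(demographic_offsets)
  assert_columns(party, "arrival_age_years", "party table")
  wild <- party |>
    filter(.data$origin == "wild", !is.na(.data$arrival_age_years)) |>
    mutate(arrival_stratum = factor(
      ifelse(.data$arrival_age_years < cutoff_years, "early", "later"),
      levels = c("later", "early")))
  counts <- table(wild$arrival_stratum)
  if (any(counts == 0) || nrow(wild) == 0) {
    abort(sprintf(
      "early/late contrast needs both strata populated (early: %d, later: %d)",
      counts[["early"]] %||% 0, counts[["later"]] %||% 0))
  }
  resp_col <- if (response == "associates") "associates" else "party_size"
  base_terms <- c("rank_z", "age_z", "sex")
  agg <- focal_constant(wild, c("arrival_stratum", base_terms))
  full <- fit_party_glm(wild, c("arrival_stratum", base_terms), resp_col,
                        random_intercepts, demographic_offsets,
                        aggregate = agg, ...)
  null <- fit_party_glm(wild, base_terms, resp_col,
                        random_intercepts, demographic_offsets,
                        aggregate = agg, ...)
  est <- coef_se(full, "arrival_stratumearly")
  structure(list(full = full, null = null, lrt = lr_test(full, null),
                 term = "arrival_stratumearly",
                 estimate = est[["estimate"]], se = est[["se"]],
                 cutoff_years = cutoff_years, data = wild),
            class = c("early_late_test", "origin_test"))
}

#' Build the dyad-level modelling table
#'
#' One row per within-group dyad of the association matrix, with the
#' dyad-level covariates: `dyad_origin` (`SS`/`WS`/`WW` by the number of
#' wild-born members), `dyad_sex` (`FF`/`MF`/`MM`), `dyad_age`
#' (subadult/adult combination at `adult_cutoff_years`), `same_matriline`,
#' the association index `ai`, the `nonzero` indicator, and a log group
#' size offset. Dyads never co-sampled have `ai = NA` and are excluded by
#' the model fitters.
#'
#' @param A An `assoc_matrix`.
#' @param demographics Demographics tibble covering all matrix ids.
#' @param adult_cutoff_years Age separating subadults from adults.
#' @return Tibble of dyad records.
#' @export
build_dyad_table <- function(A, demographics, adult_cutoff_years = 12) {
  ids <- rownames(A)
  missing <- setdiff(ids, demographics$id)
  if (length(missing) > 0) {
    abort(sprintf("matrix ids absent from demographics: %s",
                  paste(missing, collapse = ", ")))
  }
  demo <- demographics[match(ids, demographics$id), ]
  n <- length(ids)
  if (n < 2) return(empty_dyad_table())

  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  same_group <- demo$group_id[i] == demo$group_id[j]
  i <- i[same_group]; j <- j[same_group]

  n_wild <- (demo$origin[i] == "wild") + (demo$origin[j] == "wild")
  n_male <- (demo$sex[i] == "M") + (demo$sex[j] == "M")
  n_adult <- (demo$age_years[i] >= adult_cutoff_years) +
    (demo$age_years[j] >= adult_cutoff_years)
  grp_size <- table(demographics$group_id)

  tibble(
    id_a = pmin(ids[i], ids[j]),
    id_b = pmax(ids[i], ids[j]),
    group_id = demo$group_id[i],
    ai = unclass(A)[cbind(i, j)],
    nonzero = unclass(A)[cbind(i, j)] > 0,
    dyad_origin = factor(c("SS", "WS", "WW")[n_wild + 1],
                         levels = c("SS", "WS", "WW")),
    dyad_sex = factor(c("FF", "MF", "MM")[n_male + 1],
                      levels = c("FF", "MF", "MM")),
    dyad_age = factor(
      c("subadult-subadult", "subadult-adult", "adult-adult")[n_adult + 1],
      levels = c("subadult-subadult", "subadult-adult", "adult-adult")),
    same_matriline = !is.na(demo$matriline_id[i]) &
      !is.na(demo$matriline_id[j]) &
      demo$matriline_id[i] == demo$matriline_id[j],
    log_popsize_offset = log(as.numeric(grp_size[demo$group_id[i]]))
  )
}

empty_dyad_table <- function() {
  tibble(id_a = character(), id_b = character(), group_id = character(),
         ai = numeric(), nonzero = logical(),
         dyad_origin = factor(character(), levels = c("SS", "WS", "WW")),
         dyad_sex = factor(character(), levels = c("FF", "MF", "MM")),
         dyad_age = factor(character(),
                           levels = c("subadult-subadult", "subadult-adult",
                                      "adult-adult")),
         same_matriline = logical(), log_popsize_offset = numeric())
}

hurdle_terms <- function(dyads, include_origin) {
  terms <- c(if (include_origin) "dyad_origin",
             "dyad_sex", "dyad_age", "same_matriline")
  keep <- vapply(terms, function(tm) {
    col <- dyads[[tm]]
    dplyr::n_distinct(col[!is.na(col)]) > 1
  }, logical(1))
  terms[keep]
}

#' Fit the two-part (hurdle) model for dyadic association indices
#'
#' Association indices are zero for most dyads — absence of association —
#' and continuous positive for the rest, so a single distribution fits
#' poorly. The hurdle model separates the two dimensions: a binomial part
#' (logit link) models whether a dyad is connected at all, over every
#' dyad with a defined index; a Gamma part (log link) models the
#' magnitude of the index over the connected dyads only. Both parts share
#' the dyad covariates (`dyad_origin`, `dyad_sex`, `dyad_age`,
#' `same_matriline`) and a log group-size offset. The Gamma shape is the
#' maximum-likelihood estimate ([MASS::gamma.shape()]), and the total
#' log-likelihood is the sum of the two parts.
#'
#' @param dyads Tibble from [build_dyad_table()] (or
#'   [simulate_hurdle_dyads()]). Rows with missing `ai` are excluded from
#'   both parts.
#' @param include_origin Include the `dyad_origin` term.
#' @param use_offset Include the log group-size offset.
#' @return A `hurdle_fit`: `binomial` and `gamma` `glm` fits,
#'   `gamma_shape`, `loglik_binomial`, `loglik_gamma`, `loglik_total`.
#' @export
fit_hurdle <- function(dyads, include_origin = TRUE, use_offset = TRUE) {
  d <- dyads |> filter(!is.na(.data$ai))
  if (nrow(d) == 0) abort("no dyads with a defined association index")
  if (all(d$ai > 0)) {
    abort("binomial part degenerate: no zero association indices")
  }
  if (all(d$ai == 0)) {
    abort("gamma part unfittable: all association indices are zero")
  }
  off <- if (use_offset) "+ offset(log_popsize_offset)" else ""

  terms_b <- hurdle_terms(d, include_origin)
  rhs_b <- if (length(terms_b) == 0) "1" else paste(terms_b, collapse = " + ")
  bin_fit <- glm(as.formula(paste("nonzero ~", rhs_b, off)),
                 family = stats::binomial(), data = d)

  pos <- d |> filter(.data$ai > 0) |> droplevels()
  terms_g <- hurdle_terms(pos, include_origin)
  rhs_g <- if (length(terms_g) == 0) "1" else paste(terms_g, collapse = " + ")
  gamma_fit <- glm(as.formula(paste("ai ~", rhs_g, off)),
                   family = stats::Gamma(link = "log"), data = pos)

  shape <- MASS::gamma.shape(gamma_fit)$alpha
  ll_gamma <- sum(stats::dgamma(pos$ai, shape = shape,
                                rate = shape / stats::fitted(gamma_fit),
                                log = TRUE))
  ll_bin <- as.numeric(logLik(bin_fit))

  structure(list(binomial = bin_fit, gamma = gamma_fit, gamma_shape = shape,
                 loglik_binomial = ll_bin, loglik_gamma = ll_gamma,
                 loglik_total = ll_bin + ll_gamma,
                 n = nrow(d), n_nonzero = nrow(pos),
                 include_origin = include_origin),
            class = "hurdle_fit")
}

#' @export
logLik.hurdle_fit <- function(object, ...) {
  structure(object$loglik_total,
            df = length(coef(object$binomial)) +
              length(coef(object$gamma)) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
nobs.hurdle_fit <- function(object, ...) object$n

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> %d dyads (%d connected); gamma shape = %.3g\n",
              x$n, x$n_nonzero, x$gamma_shape))
  cat(sprintf("  logLik: binomial %.2f + gamma %.2f = %.2f\n",
              x$loglik_binomial, x$loglik_gamma, x$loglik_total))
  invisible(x)
}

#' Likelihood-ratio test for the dyad-origin effect in the hurdle model
#'
#' Compares the full hurdle model with a reduced model omitting
#' `dyad_origin` from both parts. The test is reported per part
#' (binomial: does origin composition change the *probability* of being
#' connected; gamma: does it change the *magnitude* among connected
#' dyads) and jointly (summed chi-square, summed degrees of freedom).
#'
#' @inheritParams fit_hurdle
#' @return A `hurdle_test`: `full`, `reduced` (`hurdle_fit`s), `binomial`,
#'   `gamma`, and `joint`, each a list with `chi2`, `df`, `p_value`.
#' @export
hurdle_origin_test <- function(dyads, use_offset = TRUE) {
  full <- fit_hurdle(dyads, include_origin = TRUE, use_offset = use_offset)
  reduced <- fit_hurdle(dyads, include_origin = FALSE, use_offset = use_offset)

  part <- function(ll_f, ll_r, df) {
    chi2 <- 2 * (ll_f - ll_r)
    if (chi2 < -1e-6) abort("reduced hurdle part has higher likelihood; parts are not nested")
    chi2 <- max(chi2, 0)
    list(chi2 = chi2, df = df,
         p_value = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1)
  }
  df_b <- length(coef(full$binomial)) - length(coef(reduced$binomial))
  df_g <- length(coef(full$gamma)) - length(coef(reduced$gamma))
  bin <- part(full$loglik_binomial, reduced$loglik_binomial, df_b)
  gam <- part(full$loglik_gamma, reduced$loglik_gamma, df_g)
  joint <- list(chi2 = bin$chi2 + gam$chi2, df = bin$df + gam$df,
                p_value = pchisq(bin$chi2 + gam$chi2, bin$df + gam$df,
                                 lower.tail = FALSE))
  structure(list(full = full, reduced = reduced, binomial = bin,
                 gamma = gam, joint = joint),
            class = "hurdle_test")
}

#' @export
print.hurdle_test <- function(x, ...) {
  cat("Hurdle LRT for dyad_origin:\n")
  cat(sprintf("  binomial: chi2 = %.4g, df = %d, p = %.4g\n",
              x$binomial$chi2, x$binomial$df, x$binomial$p_value))
  cat(sprintf("  gamma:    chi2 = %.4g, df = %d, p = %.4g\n",
              x$gamma$chi2, x$gamma$df, x$gamma$p_value))
  cat(sprintf("  joint:    chi2 = %.4g, df = %d, p = %.4g\n",
              x$joint$chi2, x$joint$df, x$joint$p_value))
  invisible(x)
}

#' Node-level permutation p-value for the dyad-origin effect
#'
#' Dyadic records are not independent — every individual contributes to
#' many dyads — so the asymptotic hurdle LRT can be optimistic. This
#' routine permutes *origin at the individual level*, rebuilds the dyad
#' origin composition, refits the hurdle model, and compares the observed
#' joint LRT statistic with its permutation null.
#'
#' @inheritParams fit_hurdle
#' @param demographics Demographics for the individuals behind the dyads.
#' @param n_perm Number of node-label permutations.
#' @param seed Optional seed.
#' @return A `perm_test`-like list: `observed` (joint chi2), `null`,
#'   `p_value`, `n_perm`.
#' @export
hurdle_origin_permutation <- function(dyads, demographics, n_perm = 100,
                                      seed = NULL, use_offset = TRUE) {
  obs <- hurdle_origin_test(dyads, use_offset = use_offset)$joint$chi2
  ids <- sort(unique(c(dyads$id_a, dyads$id_b)))
  demo <- demographics[match(ids, demographics$id), ]
  null <- with_rng(seed, function() {
    vapply(seq_len(n_perm), function(b) {
      origin_b <- setNames(sample(demo$origin), ids)
      n_wild <- (origin_b[dyads$id_a] == "wild") +
        (origin_b[dyads$id_b] == "wild")
      d <- dyads
      d$dyad_origin <- factor(c("SS", "WS", "WW")[n_wild + 1],
                              levels = c("SS", "WS", "WW"))
      tryCatch(hurdle_origin_test(d, use_offset = use_offset)$joint$chi2,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- !is.na(null)
  p <- (1 + sum(null[ok] >= obs - 1e-12)) / (sum(ok) + 1)
  structure(list(metric = "hurdle joint chi2", observed = obs,
                 null = null[ok], p_value = p, n_perm = sum(ok),
                 seed = seed, levels = c("wild", "sanctuary"),
                 stat = "lrt", exhaustive = FALSE, stratified = FALSE,
                 n = length(ids)),
            class = "perm_test")
}
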