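# Synthetic focal-follow data with known ground truth.
#
# The generator emulates a multi-group sanctuary study: four closed groups
# totalling 78 individuals (42 wild-born, 36 sanctuary-born), daily focal
# follows with an end-of-follow scan completing the party composition, and
# per-day one-zero dyadic sampling of proximity and grooming. Individual
# gregariousness g_i is log-normal (the origin effect shifts its log-mean
# for wild-born individuals); dyadic affinity is a logistic function of
# both members' gregariousness, kinship, an origin-pair shift, and a
# dyad-level latent term whose spread produces the natural excess of
# never-associating dyads that motivates the hurdle model.

#' Configuration for the synthetic focal-follow generator
#'
#' All knobs of [synth_generate()] with defaults mirroring the emulated
#' study system: 4 groups, 78 individuals (42 wild-born / 36
#' sanctuary-born), 200 observation days with 4 follows per group per day
#' (~3200 follows), mean sanctuary-born party size about 7.4 including
#' the focal, and wild-born arrival ages averaging 3.2 years.
#'
#' @param n_groups Number of closed groups.
#' @param group_sizes Integer vector of group sizes.
#' @param wild_per_group Wild-born individuals per group.
#' @param n_days Number of observation days.
#' @param follows_per_day Focal follows per group per day.
#' @param mean_in_view_seconds,sd_in_view_seconds In-view time
#'   distribution (normal, truncated to `[300, baseline_seconds]`).
#' @param baseline_seconds Nominal full follow length.
#' @param mean_party_size Expected party size (including the focal) for a
#'   sanctuary-born individual at full in-view time.
#' @param gregariousness_sd SD of log individual gregariousness.
#' @param origin_effect_party Log-scale shift of gregariousness for
#'   wild-born individuals (0 = null).
#' @param origin_effect_proximity,origin_effect_grooming Logit-scale dyad
#'   affinity shift, applied in proportion to the number of wild-born
#'   members in the dyad (full shift for wild-wild dyads).
#' @param proximity_base Baseline logit of the daily proximity
#'   association probability for an average dyad.
#' @param grooming_scale Multiplier taking daily proximity probability to
#'   daily grooming probability (grooming is the rarer behaviour).
#' @param dyad_sd SD of the dyad-level latent affinity term; large values
#'   produce strong zero-inflation in the association indices.
#' @param matriline_boost Logit increase in affinity for same-matriline
#'   dyads.
#' @param detection_prob Daily probability that an individual is
#'   available to be captured on video.
#' @param n_matrilines_per_group Family units per group.
#' @param prop_female Probability an individual is female.
#' @param arrival_age_mean Mean arrival age (years) of wild-born
#'   individuals.
#' @param grooming_age_min Minimum age for grooming participation.
#' @param one_per_week Thin to at most one follow per focal per week
#'   (with events restricted to what the retained videos identify).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_groups = 4,
                         group_sizes = c(20, 20, 19, 19),
                         wild_per_group = c(11, 11, 10, 10),
                         n_days = 200,
                         follows_per_day = 4,
                         mean_in_view_seconds = 480,
                         sd_in_view_seconds = 80,
                         baseline_seconds = 600,
                         mean_party_size = 7.36,
                         gregariousness_sd = 0.3,
                         origin_effect_party = 0,
                         origin_effect_proximity = 0,
                         origin_effect_grooming = 0,
                         proximity_base = -4,
                         grooming_scale = 0.25,
                         dyad_sd = 2,
                         matriline_boost = 1,
                         detection_prob = 0.6,
                         n_matrilines_per_group = 5,
                         prop_female = 0.5,
                         arrival_age_mean = 3.2,
                         grooming_age_min = 6,
                         one_per_week = FALSE,
                         seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$group_sizes) != cfg$n_groups ||
      length(cfg$wild_per_group) != cfg$n_groups) {
    abort("group_sizes and wild_per_group must have length n_groups")
  }
  if (any(cfg$group_sizes < 2)) abort("every group needs at least 2 members")
  if (any(cfg$wild_per_group < 0 | cfg$wild_per_group > cfg$group_sizes)) {
    abort("wild_per_group must be between 0 and the group size")
  }
  if (cfg$detection_prob <= 0 || cfg$detection_prob > 1 ||
      cfg$prop_female < 0 || cfg$prop_female > 1 ||
      cfg$grooming_scale < 0 || cfg$grooming_scale > 1) {
    abort("probabilities must lie in their valid ranges")
  }
  if (cfg$mean_party_size - 1 >= min(cfg$group_sizes)) {
    abort("infeasible config: expected party size exceeds the smallest group")
  }
  if (cfg$gregariousness_sd <= 0 || cfg$dyad_sd < 0 ||
      cfg$matriline_boost < 0) {
    abort("gregariousness_sd must be positive; dyad_sd and matriline_boost nonnegative")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d groups (%s), %d days x %d follows/group/day, seed %d\n",
              x$n_groups, paste(x$group_sizes, collapse = "+"),
              x$n_days, x$follows_per_day, x$seed))
  cat(sprintf("  effects: party %.3g, proximity %.3g, grooming %.3g\n",
              x$origin_effect_party, x$origin_effect_proximity,
              x$origin_effect_grooming))
  invisible(x)
}

#' Named study scenarios
#'
#' Three fully specified configurations with fixed seeds:
#' * `"null"` — every origin effect 0; used for type-I error calibration.
#' * `"paper_like"` — a small wild-born deficit in party size (log-scale
#'   effect -0.105) and mild negative origin shifts on dyadic affinity;
#'   effects of the magnitude reported for sanctuary-housed chimpanzees.
#' * `"strong_effect"` — effects large enough that every pipeline stage
#'   should detect them; used for power checks.
#'
#' Each scenario also carries `hurdle_truth` — named coefficient vectors
#' of a dyad-level two-part model (binomial-logit and Gamma-log parts)
#' used by [simulate_hurdle_dyads()] for parameter-recovery studies.
#'
#' @param name One of `"null"`, `"paper_like"`, `"strong_effect"`.
#' @return A `synth_config` with an extra `hurdle_truth` element.
#' @export
synth_scenario <- function(name = c("null", "paper_like", "strong_effect")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("null", "paper_like", "strong_effect")) {
    abort("unknown scenario; use 'null', 'paper_like' or 'strong_effect'")
  }
  base_truth <- function(b_origin_bin, b_origin_gam) {
    list(
      beta_binomial = c(
        "(Intercept)" = 0.2, dyad_originWS = b_origin_bin / 2,
        dyad_originWW = b_origin_bin, dyad_sexMF = 0.1, dyad_sexMM = -0.2,
        "dyad_agesubadult-adult" = 0.2, "dyad_ageadult-adult" = 0.3,
        same_matrilineTRUE = 0.8),
      beta_gamma = c(
        "(Intercept)" = -3.2, dyad_originWS = b_origin_gam / 2,
        dyad_originWW = b_origin_gam, dyad_sexMF = 0.05, dyad_sexMM = -0.05,
        "dyad_agesubadult-adult" = 0.1, "dyad_ageadult-adult" = 0.15,
        same_matrilineTRUE = 0.4),
      shape = 2.5)
  }
  cfg <- switch(name,
    null = synth_config(seed = 101),
    paper_like = synth_config(origin_effect_party = -0.105,
                              origin_effect_proximity = -0.1,
                              origin_effect_grooming = -0.1,
                              seed = 202),
    strong_effect = synth_config(origin_effect_party = -0.5,
                                 origin_effect_proximity = -2,
                                 origin_effect_grooming = -2,
                                 seed = 303))
  cfg$scenario <- name
  cfg$hurdle_truth <- switch(name,
    null = base_truth(0, 0),
    paper_like = base_truth(-0.4, -0.15),
    strong_effect = base_truth(-1.5, -0.6))
  cfg
}

resample <- function(x, size, prob = NULL) {
  # sample() interprets a scalar first argument as 1:x; avoid that.
  x[sample.int(length(x), size = size, prob = prob)]
}

#' Generate a synthetic focal-follow dataset with ground truth
#'
#' Runs the generative model described in [synth_config()] and returns a
#' validated [observation_data()] plus the latent quantities used to
#' generate it. Briefly, per group: (i) individual gregariousness
#' `g_i ~ LogNormal` with the wild-born log-mean shifted by
#' `origin_effect_party`; (ii) dyadic daily association probability
#' `w_ij = plogis(base + clog g_i + clog g_j + matriline boost +
#' origin-pair shift + dyad noise)` (clog: centred log); (iii) each day
#' individuals are available with `detection_prob`, focals are drawn from
#' the available set, each follow draws a Poisson party (mean
#' proportional to `g_focal` and in-view time) weighted towards
#' high-affinity partners, and the day's identified set is everyone
#' captured on a video; (iv) identified dyads associate (one-zero, per
#' behaviour) with probability `w_ij` (proximity) or a scaled-down
#' version restricted to individuals old enough to groom.
#'
#' @param config A `synth_config` (or scenario from [synth_scenario()]).
#' @return A list: `data` (an `observation_data`), `truth` (list with
#'   per-individual `gregariousness`, per-group dyadic probability
#'   matrices `w_proximity` / `w_grooming`, the injected `effects`, and
#'   the `config`).
#' @export
synth_generate <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) abort("config must be a synth_config")
  with_rng(config$seed, function() synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  dates <- seq(as.Date("2011-03-01"), by = "day", length.out = cfg$n_days)
  lg_mu <- log(cfg$mean_party_size - 1) - cfg$gregariousness_sd^2 / 2

  demo_list <- list()
  truth_g <- numeric(0)
  w_prox_list <- list()
  w_groom_list <- list()
  follows_acc <- list()
  # events accumulated as parallel vectors; a tibble is built once at the end
  ev_day <- integer(0); ev_beh <- character(0)
  ev_a <- character(0); ev_b <- character(0); ev_g <- character(0)

  for (g in seq_len(cfg$n_groups)) {
    n_g <- cfg$group_sizes[g]
    gid <- paste0("G", g)
    ids <- sprintf("%s_I%02d", gid, seq_len(n_g))
    wild <- sample(c(rep(TRUE, cfg$wild_per_group[g]),
                     rep(FALSE, n_g - cfg$wild_per_group[g])))
    sex <- ifelse(runif(n_g) < cfg$prop_female, "F", "M")
    age <- ifelse(wild, runif(n_g, 8, 40), runif(n_g, 2, 25))
    arrival <- ifelse(wild,
                      pmin(pmax(rgamma(n_g, shape = 2.56,
                                       scale = cfg$arrival_age_mean / 2.56),
                                0.3), 12),
                      NA_real_)
    rank <- runif(n_g)
    matriline <- paste0(gid, "_M",
                        sample.int(cfg$n_matrilines_per_group, n_g,
                                   replace = TRUE))

    lg <- rnorm(n_g, lg_mu + cfg$origin_effect_party * wild,
                cfg$gregariousness_sd)
    g_vec <- exp(lg)
    clog <- lg - lg_mu   # centred log-gregariousness

    # dyadic daily association probabilities
    eps <- matrix(0, n_g, n_g)
    eps[upper.tri(eps)] <- rnorm(n_g * (n_g - 1) / 2, 0, cfg$dyad_sd)
    eps <- eps + t(eps)
    same_mat <- outer(matriline, matriline, `==`)
    wild_frac <- outer(wild, wild, `+`) / 2
    eta <- cfg$proximity_base + outer(clog, clog, `+`) +
      cfg$matriline_boost * same_mat + eps
    w_prox <- plogis(eta + cfg$origin_effect_proximity * wild_frac)
    w_groom <- pmin(1, cfg$grooming_scale *
                      plogis(eta + cfg$origin_effect_grooming * wild_frac))
    can_groom <- age > cfg$grooming_age_min
    w_groom <- w_groom * outer(can_groom, can_groom, `&`)
    diag(w_prox) <- 0
    diag(w_groom) <- 0

    demo_list[[g]] <- tibble(
      id = ids, group_id = gid,
      origin = ifelse(wild, "wild", "sanctuary"),
      sex = sex, age_years = age, arrival_age_years = arrival,
      rank = rank, matriline_id = matriline)
    truth_g <- c(truth_g, setNames(g_vec, ids))
    dimnames(w_prox) <- dimnames(w_groom) <- list(ids, ids)
    w_prox_list[[gid]] <- w_prox
    w_groom_list[[gid]] <- w_groom

    pair_idx <- which(upper.tri(w_prox), arr.ind = TRUE)

    for (d in seq_len(cfg$n_days)) {
      available <- which(runif(n_g) < cfg$detection_prob)
      if (length(available) == 0) next
      k <- min(cfg$follows_per_day, length(available))
      focals <- resample(available, k)

      members <- vector("list", k)
      durs <- pmin(cfg$baseline_seconds,
                   pmax(300, rnorm(k, cfg$mean_in_view_seconds,
                                   cfg$sd_in_view_seconds)))
      for (f in seq_len(k)) {
        foc <- focals[f]
        others <- setdiff(available, foc)
        kk <- min(rpois(1, g_vec[foc] * durs[f] / cfg$baseline_seconds),
                  length(others))
        members[[f]] <- if (kk > 0) {
          resample(others, kk, prob = w_prox[foc, others] + 1e-9)
        } else integer(0)
      }

      identified <- sort(unique(c(focals, unlist(members))))
      follows_acc[[length(follows_acc) + 1]] <- list(
        follow_id = sprintf("%s_D%03d_F%d", gid, d, seq_len(k)),
        focal_id = ids[focals], date = rep(dates[d], k),
        group_id = rep(gid, k), in_view_seconds = durs,
        party_member_ids = lapply(members, function(m) ids[m]))

      if (length(identified) >= 2) {
        present <- pair_idx[, 1] %in% identified & pair_idx[, 2] %in% identified
        idx <- pair_idx[present, , drop = FALSE]
        if (nrow(idx) > 0) {
          hit <- runif(nrow(idx)) < w_prox[idx]
          if (any(hit)) {
            ev_day <- c(ev_day, rep(d, sum(hit)))
            ev_beh <- c(ev_beh, rep("proximity", sum(hit)))
            ev_a <- c(ev_a, ids[idx[hit, 1]])
            ev_b <- c(ev_b, ids[idx[hit, 2]])
            ev_g <- c(ev_g, rep(gid, sum(hit)))
          }
          hit_g <- runif(nrow(idx)) < w_groom[idx]
          if (any(hit_g)) {
            ev_day <- c(ev_day, rep(d, sum(hit_g)))
            ev_beh <- c(ev_beh, rep("grooming", sum(hit_g)))
            ev_a <- c(ev_a, ids[idx[hit_g, 1]])
            ev_b <- c(ev_b, ids[idx[hit_g, 2]])
            ev_g <- c(ev_g, rep(gid, sum(hit_g)))
          }
        }
      }
    }
  }

  demographics <- dplyr::bind_rows(demo_list)
  pull_chr <- function(fld) unlist(lapply(follows_acc, `[[`, fld))
  follows <- tibble(
    follow_id = pull_chr("follow_id"),
    focal_id = pull_chr("focal_id"),
    date = as.Date(unlist(lapply(follows_acc, function(x)
      as.character(x$date)))),
    group_id = pull_chr("group_id"),
    in_view_seconds = pull_chr("in_view_seconds"),
    party_member_ids = do.call(c, lapply(follows_acc, `[[`,
                                         "party_member_ids")))
  events <- tibble(date = dates[ev_day], behaviour = ev_beh,
                   id_a = ev_a, id_b = ev_b, group_id = ev_g)

  if (cfg$one_per_week) {
    week <- as.integer(follows$date - min(follows$date)) %/% 7L
    keep_ids <- follows |>
      mutate(.week = week) |>
      group_by(.data$focal_id, .data$.week) |>
      slice_sample(n = 1) |>
      pull(.data$follow_id)
    follows <- follows |> filter(.data$follow_id %in% keep_ids)
    # events must stay consistent with what the retained videos identify
    ident_day <- follows |>
      mutate(ids = purrr::map2(.data$focal_id, .data$party_member_ids, c)) |>
      group_by(.data$date, .data$group_id) |>
      summarise(identified = list(unique(unlist(.data$ids))),
                .groups = "drop")
    events <- events |>
      inner_join(ident_day, by = c("date", "group_id")) |>
      filter(purrr::map2_lgl(.data$id_a, .data$identified, `%in%`),
             purrr::map2_lgl(.data$id_b, .data$identified, `%in%`)) |>
      select(-"identified")
  }

  data <- observation_data(follows, events, demographics,
                           min_in_view_seconds = 300)
  truth <- list(gregariousness = truth_g,
                w_proximity = w_prox_list,
                w_grooming = w_groom_list,
                effects = list(party = cfg$origin_effect_party,
                               proximity = cfg$origin_effect_proximity,
                               grooming = cfg$origin_effect_grooming),
                config = cfg)
  list(data = data, truth = truth)
}

#' Simulate dyad records directly from a two-part model
#'
#' Model-level simulator for hurdle-model parameter recovery: dyad
#' covariates are drawn from fixed category frequencies, the connection
#' indicator follows the binomial-logit part, and the positive magnitude
#' follows the Gamma-log part, with the supplied coefficients as ground
#' truth. The returned table has the same shape as [build_dyad_table()]
#' output (offset fixed at 0).
#'
#' @param n_dyads Number of dyads.
#' @param beta_binomial,beta_gamma Named coefficient vectors on the
#'   model-matrix scale (names as produced by the default covariate
#'   coding, e.g. `dyad_originWW`; missing names default to 0).
#' @param shape Gamma shape parameter.
#' @param seed Optional seed.
#' @return A dyad tibble ready for [fit_hurdle()].
#' @export
simulate_hurdle_dyads <- function(n_dyads, beta_binomial, beta_gamma,
                                  shape = 2.5, seed = NULL) {
  with_rng(seed, function() {
    d <- tibble(
      id_a = sprintf("A%04d", seq_len(n_dyads)),
      id_b = sprintf("B%04d", seq_len(n_dyads)),
      group_id = "G1",
      dyad_origin = factor(sample(c("SS", "WS", "WW"), n_dyads,
                                  replace = TRUE, prob = c(0.25, 0.5, 0.25)),
                           levels = c("SS", "WS", "WW")),
      dyad_sex = factor(sample(c("FF", "MF", "MM"), n_dyads, replace = TRUE,
                               prob = c(0.3, 0.45, 0.25)),
                        levels = c("FF", "MF", "MM")),
      dyad_age = factor(sample(c("subadult-subadult", "subadult-adult",
                                 "adult-adult"), n_dyads, replace = TRUE,
                               prob = c(0.2, 0.45, 0.35)),
                        levels = c("subadult-subadult", "subadult-adult",
                                   "adult-adult")),
      same_matriline = runif(n_dyads) < 0.15,
      log_popsize_offset = 0)
    X <- stats::model.matrix(~ dyad_origin + dyad_sex + dyad_age +
                               same_matriline, d)
    bb <- setNames(rep(0, ncol(X)), colnames(X))
    bb[names(beta_binomial)[names(beta_binomial) %in% names(bb)]] <-
      beta_binomial[names(beta_binomial) %in% names(bb)]
    bg <- setNames(rep(0, ncol(X)), colnames(X))
    bg[names(beta_gamma)[names(beta_gamma) %in% names(bg)]] <-
      beta_gamma[names(beta_gamma) %in% names(bg)]

    p <- plogis(as.vector(X %*% bb))
    mu <- exp(as.vector(X %*% bg))
    nz <- runif(n_dyads) < p
    ai <- ifelse(nz, rgamma(n_dyads, shape = shape, rate = shape / mu), 0)
    d$ai <- ai
    d$nonzero <- ai > 0
    d
  })
}
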