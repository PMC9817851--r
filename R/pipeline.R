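# End-to-end analysis pipeline and report assembly.

#' Connection rates per dyad-origin type
#'
#' Percentage of dyads with a nonzero association index, per origin
#' composition (`SS`, `WS`, `WW`). Numerator and denominator are carried
#' alongside the percentage so bare rates remain auditable; dyads with an
#' undefined (missing) index are excluded from the denominator and
#' counted separately.
#'
#' @param dyads Tibble from [build_dyad_table()].
#' @return Tibble with `dyad_origin`, `n_connected`, `n_dyads`,
#'   `n_missing`, `pct_connected` (in percent; `NA` for an empty type).
#' @export
dyad_connection_rates <- function(dyads) {
  dyads |>
    group_by(.data$dyad_origin) |>
    summarise(
      n_connected = sum(.data$nonzero, na.rm = TRUE),
      n_dyads = sum(!is.na(.data$ai)),
      n_missing = sum(is.na(.data$ai)),
      .groups = "drop") |>
    tidyr::complete(dyad_origin = factor(c("SS", "WS", "WW"),
                                         levels = c("SS", "WS", "WW")),
                    fill = list(n_connected = 0L, n_dyads = 0L,
                                n_missing = 0L)) |>
    mutate(pct_connected = ifelse(.data$n_dyads > 0,
                                  100 * .data$n_connected / .data$n_dyads,
                                  NA_real_))
}

NET_METRICS <- c("strength", "eigenvector", "reach", "clustering", "affinity")

#' Run the full origin-signature analysis pipeline
#'
#' Executes the whole chain — daily one-zero aggregation, per-group
#' association matrices, node metrics, node-label permutation tests with
#' a Holm correction across the metric family, dyad tables with
#' connection rates and hurdle LRTs, and the party-size origin LRT — and
#' returns a structured report. Deterministic given the configuration and
#' `seed`: permutation seeds are derived per (metric, behaviour) from the
#' master seed.
#'
#' @param config What to analyse: a scenario name (`"null"`,
#'   `"paper_like"`, `"strong_effect"`), a [synth_config()], an
#'   `observation_data` object, a list with elements
#'   `focal`/`events`/`demographics` (CSV paths), or a path to a YAML
#'   file with those keys (optionally `scenario` instead).
#' @param behaviours Behaviours to analyse.
#' @param n_perm Permutations per metric test.
#' @param seed Master seed for all permutation tests.
#' @param index Association index variant.
#' @param adult_cutoff_years Subadult/adult boundary for dyad age classes.
#' @param grooming_age_min Individuals at or below this age are excluded
#'   from grooming networks.
#' @param stratify_by_group Shuffle origin labels within groups in the
#'   permutation tests (default: across all individuals, preserving the
#'   overall ratio).
#' @param random_intercepts Random-intercept structure for the party-size
#'   model (see [fit_party_size()]).
#' @param early_late Also run the early/later-orphaned party-size
#'   contrast (skipped with a note if a stratum is empty).
#' @param min_in_view_seconds Follow inclusion threshold when reading CSVs.
#' @return An `analysis_report` (see [write_report()]).
#' @export
run_pipeline <- function(config,
                         behaviours = c("proximity", "grooming"),
                         n_perm = 1000, seed = 1,
                         index = "twice-weight",
                         adult_cutoff_years = 12,
                         grooming_age_min = 6,
                         stratify_by_group = FALSE,
                         random_intercepts = "focal",
                         early_late = TRUE,
                         min_in_view_seconds = 300) {
  behaviours <- match.arg(behaviours, several.ok = TRUE)
  loaded <- resolve_pipeline_input(config, min_in_view_seconds)
  obs <- loaded$obs
  demo <- obs$demographics
  groups <- setNames(demo$group_id, demo$id)

  # --- party size -----------------------------------------------------
  party <- build_party_table(obs)
  party_summary <- party |>
    group_by(.data$origin) |>
    summarise(mean_party_size = mean(.data$party_size),
              sd_party_size = sd(.data$party_size),
              n_follows = dplyr::n(), .groups = "drop")
  party_test <- party_origin_test(party, random_intercepts = random_intercepts)
  el <- if (early_late) {
    tryCatch(early_late_contrast(party,
                                 random_intercepts = random_intercepts),
             error = function(e) {
               inform(paste("early/late contrast skipped:",
                            conditionMessage(e)))
               NULL
             })
  } else NULL

  # --- behaviour networks --------------------------------------------
  networks <- list()
  test_rows <- list()
  for (b in behaviours) {
    daily <- aggregate_daily(obs, b)
    keep_ids <- if (b == "grooming") {
      demo$id[demo$age_years > grooming_age_min]
    } else demo$id

    mats <- list(); metrics_list <- list(); dyads_list <- list()
    for (g in sort(unique(demo$group_id))) {
      ids_g <- intersect(keep_ids, demo$id[demo$group_id == g])
      if (length(ids_g) < 2) next
      A <- build_assoc_matrix(daily[daily$group_id == g, ], ids_g,
                              index = index, groups = groups)
      mats[[g]] <- A
      metrics_list[[g]] <- node_metrics(A) |> mutate(group_id = g)
      dyads_list[[g]] <- build_dyad_table(A, demo, adult_cutoff_years)
    }
    metrics <- dplyr::bind_rows(metrics_list) |>
      left_join(select(demo, "id", "origin"), by = "id")
    dyads <- dplyr::bind_rows(dyads_list)

    perms <- purrr::map(NET_METRICS, function(m) {
      node_permutation_test(
        metrics, m, label_col = "origin", n_perm = n_perm,
        seed = derive_seed(seed, paste(b, m)),
        stratify_by = if (stratify_by_group) "group_id" else NULL)
    })
    names(perms) <- NET_METRICS

    rates <- dyad_connection_rates(dyads)
    hurdle <- tryCatch(hurdle_origin_test(dyads),
                       error = function(e) {
                         inform(paste("hurdle model skipped for", b, ":",
                                      conditionMessage(e)))
                         NULL
                       })
    ai_by_origin <- dyads |>
      filter(!is.na(.data$ai), .data$ai > 0) |>
      group_by(.data$dyad_origin) |>
      summarise(mean_ai = mean(.data$ai), sd_ai = sd(.data$ai),
                n = dplyr::n(), .groups = "drop")

    networks[[b]] <- list(matrices = mats, metrics = metrics,
                          perm_tests = perms, dyads = dyads,
                          connection_rates = rates,
                          ai_by_origin = ai_by_origin,
                          hurdle = hurdle)
    test_rows[[b]] <- tibble(
      behaviour = b, metric = NET_METRICS,
      observed = unname(purrr::map_dbl(perms, "observed")),
      p_raw = unname(purrr::map_dbl(perms, "p_value")),
      n_perm = unname(purrr::map_int(perms, ~ as.integer(.x$n_perm))),
      seed = unname(purrr::map_int(perms, ~ as.integer(.x$seed))))
  }

  tests_table <- dplyr::bind_rows(test_rows)
  if (nrow(tests_table) > 0) {
    tests_table$p_holm <- holm_correct(tests_table$p_raw)
  }

  hurdle_ps <- purrr::compact(purrr::map(networks,
                                         ~ .x$hurdle$joint$p_value))
  signature <- isTRUE(party_test$lrt$p_value < 0.05) ||
    any(unlist(hurdle_ps) < 0.05) ||
    (nrow(tests_table) > 0 && any(tests_table$p_holm < 0.05))

  structure(list(
    headline = if (signature) "origin signature detected"
               else "no origin signature detected",
    party = list(summary = party_summary, test = party_test,
                 early_late = el, table = party),
    networks = networks,
    tests_table = tests_table,
    provenance = list(
      config = loaded$provenance, seed = seed, n_perm = n_perm,
      index = index, adult_cutoff_years = adult_cutoff_years,
      grooming_age_min = grooming_age_min,
      stratify_by_group = stratify_by_group,
      random_intercepts = random_intercepts,
      note = "party-size model uses simplified random intercepts",
      package_version = as.character(utils::packageVersion("focalnet")))
  ), class = "analysis_report")
}

resolve_pipeline_input <- function(config, min_in_view_seconds) {
  if (is.character(config) && length(config) == 1 &&
      config %in% c("null", "paper_like", "strong_effect")) {
    cfg <- synth_scenario(config)
    return(list(obs = synth_generate(cfg)$data,
                provenance = list(scenario = config, seed = cfg$seed)))
  }
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    spec <- yaml::read_yaml(config)
    if (!is.null(spec$scenario)) {
      cfg <- synth_scenario(spec$scenario)
      return(list(obs = synth_generate(cfg)$data,
                  provenance = list(scenario = spec$scenario,
                                    seed = cfg$seed, file = config)))
    }
    return(list(obs = read_observations(spec$focal, spec$events,
                                        spec$demographics,
                                        min_in_view_seconds),
                provenance = c(spec, list(file = config))))
  }
  if (inherits(config, "synth_config")) {
    return(list(obs = synth_generate(config)$data,
                provenance = unclass(config)[!vapply(config, is.function,
                                                     logical(1))]))
  }
  if (inherits(config, "observation_data")) {
    return(list(obs = config, provenance = list(input = "observation_data")))
  }
  if (is.list(config) && all(c("focal", "events", "demographics") %in%
                             names(config))) {
    return(list(obs = read_observations(config$focal, config$events,
                                        config$demographics,
                                        min_in_view_seconds),
                provenance = config))
  }
  abort("unrecognised pipeline config; see ?run_pipeline")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Origin-signature analysis report ==\n")
  cat("Headline:", x$headline, "\n\n")
  cat("-- Party size --\n")
  ps <- x$party$summary
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %s-born: %.2f +/- %.2f (n = %d follows)\n",
                ps$origin[i], ps$mean_party_size[i], ps$sd_party_size[i],
                ps$n_follows[i]))
  }
  cat(sprintf("  origin LRT: chi2 = %.3f, p = %.3f; estimate = %.3f +/- %.3f\n",
              x$party$test$lrt$chi2, x$party$test$lrt$p_value,
              x$party$test$estimate, x$party$test$se))
  if (!is.null(x$party$early_late)) {
    cat(sprintf("  early/late LRT: chi2 = %.3f, p = %.3f; estimate = %.3f +/- %.3f\n",
                x$party$early_late$lrt$chi2, x$party$early_late$lrt$p_value,
                x$party$early_late$estimate, x$party$early_late$se))
  }
  for (b in names(x$networks)) {
    nb <- x$networks[[b]]
    cat(sprintf("\n-- %s --\n", b))
    r <- nb$connection_rates
    cat("  connected dyads:",
        paste(sprintf("%s %.2f%% (%d/%d)", r$dyad_origin, r$pct_connected,
                      r$n_connected, r$n_dyads), collapse = ", "), "\n")
    if (!is.null(nb$hurdle)) {
      cat(sprintf("  hurdle LRT (dyad_origin): binomial p = %.3f, gamma p = %.3f, joint p = %.3f\n",
                  nb$hurdle$binomial$p_value, nb$hurdle$gamma$p_value,
                  nb$hurdle$joint$p_value))
    }
    tt <- x$tests_table[x$tests_table$behaviour == b, ]
    for (i in seq_len(nrow(tt))) {
      cat(sprintf("  %-12s diff = %+.4f  p = %.3f  p(Holm) = %.3f\n",
                  tt$metric[i], tt$observed[i], tt$p_raw[i], tt$p_holm[i]))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (all numeric results plus provenance),
#' `summary.txt` (the printed report), `metrics.csv` (the pooled node
#' metrics per behaviour), one association-matrix CSV per group and
#' behaviour under `matrices/`, and the permutation null distributions
#' under `nulls/`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param write_nulls Also dump permutation null distributions.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir, write_nulls = TRUE) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(file.path(dir, "matrices"), showWarnings = FALSE,
             recursive = TRUE)
  if (write_nulls) dir.create(file.path(dir, "nulls"), showWarnings = FALSE)

  jsonlite::write_json(report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "summary.txt"))

  metrics <- purrr::imap(report$networks, function(nb, b) {
    nb$metrics |> mutate(behaviour = b)
  }) |> dplyr::bind_rows()
  readr::write_csv(metrics, file.path(dir, "metrics.csv"))

  for (b in names(report$networks)) {
    for (g in names(report$networks[[b]]$matrices)) {
      write_assoc_matrix(report$networks[[b]]$matrices[[g]],
                         file.path(dir, "matrices",
                                   sprintf("%s_%s.csv", b, g)))
    }
    if (write_nulls) {
      for (m in names(report$networks[[b]]$perm_tests)) {
        pt <- report$networks[[b]]$perm_tests[[m]]
        readr::write_csv(tibble(null_stat = pt$null),
                         file.path(dir, "nulls",
                                   sprintf("%s_%s.csv", b, m)))
      }
    }
  }
  invisible(dir)
}

lrt_as_list <- function(l) {
  if (is.null(l)) return(NULL)
  list(chi2 = l$chi2, df = l$df, p_value = l$p_value,
       loglik_full = l$loglik_full, loglik_null = l$loglik_null)
}

report_as_list <- function(report) {
  list(
    headline = report$headline,
    party = list(
      summary = report$party$summary,
      lrt = lrt_as_list(report$party$test$lrt),
      estimate = report$party$test$estimate,
      se = report$party$test$se,
      early_late = if (!is.null(report$party$early_late)) list(
        lrt = lrt_as_list(report$party$early_late$lrt),
        estimate = report$party$early_late$estimate,
        se = report$party$early_late$se,
        cutoff_years = report$party$early_late$cutoff_years)
    ),
    networks = purrr::map(report$networks, function(nb) {
      list(
        connection_rates = nb$connection_rates,
        ai_by_origin = nb$ai_by_origin,
        hurdle = if (!is.null(nb$hurdle)) list(
          binomial = nb$hurdle$binomial,
          gamma = nb$hurdle$gamma,
          joint = nb$hurdle$joint)
      )
    }),
    metric_tests = report$tests_table,
    provenance = report$provenance
  )
}
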