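# Node-label permutation tests, Holm correction, likelihood-ratio tests,
# and leave-one-out stability diagnostics.

#' Node-label permutation test for a group difference in a network metric
#'
#' Tests whether a per-individual network metric differs between two
#' attribute classes (e.g. wild- vs sanctuary-born) by permuting the
#' labels across individuals while keeping the network — and hence the
#' metric values — fixed. Label counts are preserved by construction. The
#' default statistic is the difference in class means (first level minus
#' second; for origin labels, wild minus sanctuary), and the test is
#' two-tailed on its absolute value.
#'
#' With `exhaustive = TRUE` all `choose(n, k)` label assignments are
#' enumerated and the exact permutation p-value (the proportion of
#' assignments at least as extreme as the observed one) is returned.
#' Otherwise `n_perm` Monte-Carlo permutations are drawn and the add-one
#' estimate `(1 + #extreme) / (n_perm + 1)` is used, so p can never be 0.
#'
#' @param data Tibble with one row per individual.
#' @param metric Name of the metric column. Rows with a missing metric are
#'   dropped (with a message).
#' @param label_col Name of the two-level label column (default `origin`).
#' @param n_perm Number of Monte-Carlo permutations (ignored when
#'   exhaustive).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param stat `"mean"` or `"median"` difference.
#' @param stratify_by Optional column name; labels are then shuffled
#'   within each stratum (e.g. group), preserving per-stratum ratios.
#' @param exhaustive Enumerate all label assignments (feasible for small
#'   networks only; capped at `max_exhaustive` assignments).
#' @param max_exhaustive Safety cap for enumeration.
#' @return An object of class `perm_test` with elements `metric`,
#'   `observed`, `null` (the null statistics), `p_value`, `n_perm`,
#'   `seed`, `levels`, `stat`, `exhaustive`.
#' @export
node_permutation_test <- function(data, metric, label_col = "origin",
                                  n_perm = 1000, seed = NULL,
                                  stat = c("mean", "median"),
                                  stratify_by = NULL, exhaustive = FALSE,
                                  max_exhaustive = 2e5) {
  stat <- match.arg(stat)
  assert_columns(data, c(metric, label_col), "metrics table")
  y <- data[[metric]]
  lab <- as.character(data[[label_col]])
  strata <- if (is.null(stratify_by)) NULL else as.character(data[[stratify_by]])

  keep <- !is.na(y) & !is.na(lab)
  if (any(!keep)) {
    inform(sprintf("dropping %d individual(s) with missing %s",
                   sum(!keep), metric))
    y <- y[keep]; lab <- lab[keep]
    if (!is.null(strata)) strata <- strata[keep]
  }

  lev <- sort(unique(lab))
  if (length(lev) != 2) {
    abort(sprintf("label column '%s' must have exactly 2 observed levels, got %d",
                  label_col, length(lev)))
  }
  if (setequal(lev, c("wild", "sanctuary"))) lev <- c("wild", "sanctuary")
  if (min(table(lab)) < 2) abort("need at least 2 individuals per label")

  stat_fun <- if (stat == "mean") mean else median
  diff_for <- function(labels) {
    stat_fun(y[labels == lev[1]]) - stat_fun(y[labels == lev[2]])
  }
  observed <- diff_for(lab)
  tol <- 1e-12

  if (exhaustive) {
    n <- length(y)
    k <- sum(lab == lev[1])
    m_total <- choose(n, k)
    if (m_total > max_exhaustive) {
      abort(sprintf("exhaustive enumeration needs %.0f assignments (cap %g); use Monte-Carlo",
                    m_total, max_exhaustive))
    }
    sets <- utils::combn(n, k)
    tot <- if (stat == "mean") sum(y) else NULL
    null <- apply(sets, 2, function(sel) {
      if (stat == "mean") sum(y[sel]) / k - (tot - sum(y[sel])) / (n - k)
      else median(y[sel]) - median(y[-sel])
    })
    p <- mean(abs(null) >= abs(observed) - tol)
    n_used <- ncol(sets)
  } else {
    if (!is_scalar_number(n_perm) || n_perm < 1) {
      abort("n_perm must be a positive integer")
    }
    null <- with_rng(seed, function() {
      vapply(seq_len(n_perm), function(b) {
        perm <- if (is.null(strata)) sample(lab) else permute_within(lab, strata)
        diff_for(perm)
      }, numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(observed) - tol)) / (n_perm + 1)
    n_used <- n_perm
  }

  structure(list(metric = metric, observed = observed, null = null,
                 p_value = p, n_perm = n_used, seed = seed, levels = lev,
                 stat = stat, exhaustive = exhaustive,
                 stratified = !is.null(stratify_by), n = length(y)),
            class = "perm_test")
}

permute_within <- function(lab, strata) {
  out <- lab
  for (s in unique(strata)) {
    i <- which(strata == s)
    out[i] <- lab[i][sample.int(length(i))]
  }
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s: %s(%s) - %s(%s) = %.4g\n", x$metric, x$stat,
              x$levels[1], x$stat, x$levels[2], x$observed))
  cat(sprintf("  %s p = %.4g  (%d %s, n = %d individuals)\n",
              if (x$exhaustive) "exact" else "Monte-Carlo", x$p_value,
              x$n_perm, if (x$exhaustive) "assignments" else "permutations",
              x$n))
  invisible(x)
}

#' Bonferroni-Holm step-down correction
#'
#' Adjusts a family of p-values by the step-down Holm procedure
#' (`stats::p.adjust(method = "holm")`), returning them in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param labels Optional names for the returned vector.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_correct(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_correct <- function(p_values, labels = NULL) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p_values must be numbers in [0, 1]")
  }
  out <- p.adjust(p_values, method = "holm")
  if (!is.null(labels)) names(out) <- labels
  out
}

#' Likelihood-ratio test between nested fitted models
#'
#' Compares a full model to a reduced model nested within it (same data,
#' same offsets) via `chi2 = 2 (logLik_full - logLik_reduced)` on
#' `df = df_full - df_reduced` degrees of freedom. Identical models (zero
#' degrees of freedom and zero likelihood gain) return `p = 1`; a reduced
#' model with a *higher* likelihood than the full model violates nesting
#' and is an error.
#'
#' @param full,reduced Fitted models supporting [stats::logLik()] and
#'   [stats::nobs()] (e.g. `glm`, `glmerMod`, [fit_party_size()] fits).
#' @return An `lrt_result`: list with `chi2`, `df`, `p_value`,
#'   `loglik_full`, `loglik_null`.
#' @export
lr_test <- function(full, reduced) {
  ll_f <- logLik(full)
  ll_r <- logLik(reduced)
  n_f <- tryCatch(nobs(full), error = function(e) NA_integer_)
  n_r <- tryCatch(nobs(reduced), error = function(e) NA_integer_)
  if (!is.na(n_f) && !is.na(n_r) && n_f != n_r) {
    abort(sprintf("models are fitted to different numbers of observations (%d vs %d)",
                  n_f, n_r))
  }
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  chi2 <- 2 * (as.numeric(ll_f) - as.numeric(ll_r))
  if (df < 0) abort("'full' has fewer parameters than 'reduced'; models are not nested in that order")
  if (chi2 < -1e-6) {
    abort(sprintf("reduced model has higher log-likelihood than the full model (delta = %.3g); models are not nested on the same data",
                  chi2 / 2))
  }
  chi2 <- max(chi2, 0)
  if (df == 0 && chi2 > 1e-6) {
    abort("models have equal parameter counts but different likelihoods; not nested")
  }
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p_value = p,
                 loglik_full = as.numeric(ll_f),
                 loglik_null = as.numeric(ll_r)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Leave-one-subject-out stability of a model coefficient
#'
#' Refits a model once per excluded subject and compares the coefficient
#' of interest with the full-data estimate. A subject is flagged when its
#' exclusion moves the estimate by more than `threshold` full-data
#' standard errors. Refit failures are recorded per subject, not fatal.
#'
#' @param data Model data, one or more rows per subject.
#' @param fit_fun Function `data -> fitted object`.
#' @param extract_fun Function `fit -> c(estimate, se)` for the
#'   coefficient of interest (a length-2 numeric).
#' @param subject_col Column identifying subjects (default `focal_id`).
#' @param threshold Flagging threshold in units of the full-data SE.
#' @return Tibble with one row per subject: `subject`, `estimate`,
#'   `delta`, `delta_se`, `flagged`, `error`; the full-data estimate and
#'   SE are attached as attributes `full_estimate` / `full_se`.
#' @export
loo_stability <- function(data, fit_fun, extract_fun,
                          subject_col = "focal_id", threshold = 1) {
  assert_columns(data, subject_col, "data")
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 3) abort("need at least 3 subjects")

  full <- extract_fun(fit_fun(data))
  if (length(full) < 2 || !is.finite(full[1]) || !is.finite(full[2])) {
    abort("extract_fun must return c(estimate, se) for the full-data fit")
  }
  est0 <- full[1]; se0 <- full[2]

  rows <- purrr::map(subjects, function(s) {
    d <- data[data[[subject_col]] != s, , drop = FALSE]
    res <- tryCatch({
      v <- extract_fun(fit_fun(d))
      list(estimate = v[1], error = NA_character_)
    }, error = function(e) list(estimate = NA_real_,
                                error = conditionMessage(e)))
    tibble(subject = s, estimate = res$estimate,
           delta = res$estimate - est0,
           delta_se = (res$estimate - est0) / se0,
           flagged = !is.na(res$estimate) &&
             abs(res$estimate - est0) > threshold * se0,
           error = res$error)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "full_estimate") <- est0
  attr(out, "full_se") <- se0
  out
}
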