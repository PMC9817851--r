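# Independent brute-force oracles used across tests. These deliberately
# share no code with the package internals: everything is computed by
# per-day classification, explicit summation loops, or enumeration.

# Random daily one-zero records over ids A, B, C, ... for one group.
make_random_daily <- function(n_ids, n_days, p_ident = 0.7, p_assoc = 0.3,
                              seed = 1, behaviour = "proximity") {
  set.seed(seed)
  ids <- sprintf("ID%02d", seq_len(n_ids))
  rows <- lapply(seq_len(n_days), function(d) {
    ident <- sort(ids[stats::runif(n_ids) < p_ident])
    keys <- character(0)
    if (length(ident) >= 2) {
      prs <- utils::combn(ident, 2)
      hit <- stats::runif(ncol(prs)) < p_assoc
      keys <- sort(paste(prs[1, hit], prs[2, hit], sep = "|"))
    }
    tibble::tibble(date = as.Date("2020-01-01") + d, group_id = "G1",
                   behaviour = behaviour,
                   identified = list(ident), dyads = list(keys))
  })
  daily <- dplyr::bind_rows(rows)
  daily[lengths(daily$identified) > 0, ]
}

# Per-day classification of one dyad's sampling history.
oracle_dyad_counts <- function(daily, a, b) {
  x <- y_a <- y_b <- y_ab <- 0
  key <- paste(min(a, b), max(a, b), sep = "|")
  for (d in seq_len(nrow(daily))) {
    ia <- a %in% daily$identified[[d]]
    ib <- b %in% daily$identified[[d]]
    as_ <- key %in% daily$dyads[[d]]
    if (ia && ib && as_) x <- x + 1
    else if (ia && ib) y_ab <- y_ab + 1
    else if (ia) y_a <- y_a + 1
    else if (ib) y_b <- y_b + 1
  }
  c(x = x, y_a = y_a, y_b = y_b, y_ab = y_ab)
}

# Element-wise twice-weight matrix via the printed formula; dyads with a
# zero denominator or a never-identified member carry no information (NA).
oracle_ai_matrix <- function(daily, ids) {
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  days_seen <- sapply(ids, function(id)
    sum(vapply(daily$identified, function(s) id %in% s, logical(1))))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (days_seen[i] == 0 || days_seen[j] == 0) next
      cts <- oracle_dyad_counts(daily, ids[i], ids[j])
      den <- cts["x"] + 2 * cts["y_ab"] + cts["y_a"] + cts["y_b"]
      val <- if (den > 0) unname(cts["x"] / den) else NA_real_
      # a < b ordering in oracle_dyad_counts: y_a belongs to min(id)
      M[i, j] <- M[j, i] <- val
    }
  }
  M
}

# Explicit-summation metric oracles on a plain matrix (NA treated as 0).
oracle_strength <- function(A) {
  A[is.na(A)] <- 0; diag(A) <- 0
  sapply(seq_len(nrow(A)), function(i) sum(A[i, ]))
}

oracle_reach <- function(A) {
  A[is.na(A)] <- 0; diag(A) <- 0
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) tot <- tot + A[i, j] * A[j, k]
    tot
  })
}

oracle_clustering <- function(A) {
  A[is.na(A)] <- 0; diag(A) <- 0
  n <- nrow(A); amax <- max(A)
  sapply(seq_len(n), function(i) {
    num <- den <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != k) {
        num <- num + A[i, j] * A[j, k] * A[k, i]
        den <- den + A[i, j] * A[i, k]
      }
    }
    if (amax * den > 0) num / (amax * den) else 0
  })
}

oracle_power_iteration <- function(A, tol = 1e-13, max_iter = 100000) {
  A[is.na(A)] <- 0; diag(A) <- 0
  v <- rep(1 / sqrt(nrow(A)), nrow(A))
  for (it in seq_len(max_iter)) {
    w <- as.vector(A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration hit the zero vector")
    w <- w / nw
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  if (sum(v) < 0) v <- -v
  v
}

# Exact permutation p-value by enumerating all C(n, k) label assignments.
oracle_exact_perm_p <- function(y, lab, level1) {
  n <- length(y)
  k <- sum(lab == level1)
  obs <- mean(y[lab == level1]) - mean(y[lab != level1])
  sets <- utils::combn(n, k)
  nulls <- apply(sets, 2, function(sel) mean(y[sel]) - mean(y[-sel]))
  mean(abs(nulls) >= abs(obs) - 1e-12)
}

# Random symmetric nonnegative association-like matrix with some zeros.
random_sym_matrix <- function(n, seed, p_zero = 0.3) {
  set.seed(seed)
  M <- matrix(0, n, n)
  vals <- stats::runif(n * (n - 1) / 2)
  vals[stats::runif(length(vals)) < p_zero] <- 0
  M[upper.tri(M)] <- vals
  M <- M + t(M)
  dimnames(M) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  M
}
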