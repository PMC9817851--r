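# Per-individual weighted network metrics from an association matrix.
# Definitions follow the SOCPROG conventions for weighted networks:
# strength (weighted degree), eigenvector centrality (leading eigenvector,
# unit Euclidean norm), reach (two-step strength, (A s)_i), clustering
# (Holme-style weighted proportion of closed triples), and affinity
# (reach / strength, the AI-weighted mean strength of the associates).
# Missing matrix entries mean "no observed association" here and enter as 0.

metric_matrix <- function(A) {
  if (!is.matrix(A)) abort("A must be a matrix")
  M <- unclass(A)
  M[is.na(M)] <- 0
  if (any(M < 0)) abort("association weights must be nonnegative")
  if (max(abs(M - t(M))) > 1e-10) abort("association matrix must be symmetric")
  diag(M) <- 0
  M
}

pick_ids <- function(values, A, ids) {
  names(values) <- rownames(A)
  if (is.null(ids)) return(values)
  miss <- setdiff(ids, rownames(A))
  if (length(miss) > 0) {
    abort(sprintf("unknown individual(s): %s", paste(miss, collapse = ", ")))
  }
  values[ids]
}

#' Node strength (weighted degree)
#'
#' Sum of an individual's association indices to all group mates.
#'
#' @param A An association matrix (missing entries treated as 0).
#' @param ids Optional ids to return (default: all, in matrix order).
#' @return Named numeric vector.
#' @export
ai_strength <- function(A, ids = NULL) {
  pick_ids(rowSums(metric_matrix(A)), A, ids)
}

#' Eigenvector centrality of the association network
#'
#' Components of the leading eigenvector of the (symmetric, nonnegative)
#' association matrix, oriented nonnegative and scaled to unit Euclidean
#' norm. In a disconnected network only the component carrying the
#' dominant eigenvalue gets nonzero scores; a warning is issued.
#'
#' @inheritParams ai_strength
#' @return Named numeric vector with unit Euclidean norm.
#' @export
ai_eigenvector <- function(A, ids = NULL) {
  M <- metric_matrix(A)
  if (all(M == 0)) {
    abort("eigenvector centrality is undefined for a network with no edges")
  }
  if (n_components(M) > 1) {
    warn("association network is disconnected; centrality is reported from the leading eigenvector of the full matrix")
  }
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-8] <- 0
  pick_ids(v, A, ids)
}

n_components <- function(M) {
  n <- nrow(M)
  adj <- M > 0
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] & !seen))
    }
  }
  comps
}

#' Reach (two-step connectedness)
#'
#' The association-weighted sum of the associates' strengths,
#' `sum_j A_ij s_j`; equivalently the row sums of the squared matrix.
#'
#' @inheritParams ai_strength
#' @return Named numeric vector.
#' @export
ai_reach <- function(A, ids = NULL) {
  M <- metric_matrix(A)
  pick_ids(as.vector(M %*% rowSums(M)), A, ids)
}

#' Weighted clustering coefficient
#'
#' Proportion of an individual's weighted open triples that are closed,
#' `(A^3)_ii / (a_max * sum_{j != k} A_ij A_ik)` with `a_max` the largest
#' matrix entry; defined as 0 when the individual has fewer than two
#' weighted associates (denominator 0). Always in `[0, 1]`.
#'
#' @inheritParams ai_strength
#' @return Named numeric vector in `[0, 1]`.
#' @export
ai_clustering <- function(A, ids = NULL) {
  M <- metric_matrix(A)
  a_max <- max(M)
  s <- rowSums(M)
  num <- diag(M %*% M %*% M)
  den <- a_max * (s^2 - rowSums(M^2))
  pick_ids(ifelse(den > 0, num / den, 0), A, ids)
}

#' Affinity (mean strength of associates)
#'
#' The association-weighted mean strength of an individual's associates,
#' `reach_i / strength_i`; missing for isolated individuals.
#'
#' @inheritParams ai_strength
#' @return Named numeric vector; `NA` where strength is 0.
#' @export
ai_affinity <- function(A, ids = NULL) {
  M <- metric_matrix(A)
  s <- rowSums(M)
  r <- as.vector(M %*% s)
  pick_ids(ifelse(s > 0, r / s, NA_real_), A, ids)
}

#' All five node metrics as a tibble
#'
#' One row per individual with strength, eigenvector centrality, reach,
#' clustering and affinity. If the network has no edges at all the
#' eigenvector column is `NA` (with a warning) rather than an error, so a
#' sparse behaviour network does not abort a pipeline.
#'
#' @param A An association matrix.
#' @return Tibble with columns `id`, `strength`, `eigenvector`, `reach`,
#'   `clustering`, `affinity`.
#' @export
node_metrics <- function(A) {
  M <- metric_matrix(A)
  eig <- if (all(M == 0)) {
    warn("network has no edges; eigenvector centrality is undefined (NA)")
    setNames(rep(NA_real_, nrow(A)), rownames(A))
  } else {
    ai_eigenvector(A)
  }
  tibble(
    id = rownames(A),
    strength = unname(ai_strength(A)),
    eigenvector = unname(eig),
    reach = unname(ai_reach(A)),
    clustering = unname(ai_clustering(A)),
    affinity = unname(ai_affinity(A))
  )
}

#' Origin-wise summary of node metrics
#'
#' Mean and standard deviation of each metric per origin class, the
#' conventional presentation for wild- versus sanctuary-born comparisons.
#'
#' @param metrics Tibble from [node_metrics()] (rows from several group
#'   networks may be bound together first).
#' @param demographics Demographics tibble with `id` and `origin`; ignored
#'   if `metrics` already has an `origin` column.
#' @return Tibble with one row per (metric, origin): `metric`, `origin`,
#'   `mean`, `sd`, `n`.
#' @export
summarise_metrics <- function(metrics, demographics = NULL) {
  if (!"origin" %in% names(metrics)) {
    if (is.null(demographics)) {
      abort("supply demographics or a metrics table with an 'origin' column")
    }
    metrics <- left_join(metrics,
                         select(demographics, "id", "origin"), by = "id")
  }
  metrics |>
    tidyr::pivot_longer(cols = c("strength", "eigenvector", "reach",
                                 "clustering", "affinity"),
                        names_to = "metric", values_to = "value") |>
    group_by(.data$metric, .data$origin) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n = sum(!is.na(.data$value)), .groups = "drop")
}
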