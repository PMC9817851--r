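# Per-dyad sampling counts and association-index matrices.

ASSOC_INDICES <- c("twice-weight", "half-weight", "simple-ratio")

#' Association index from dyadic sampling counts
#'
#' Computes an association index from the day-partition counts of a dyad:
#' `x` days associated, `y_ab` days both identified but not associated,
#' `y_a` / `y_b` days only one of the two identified. The default
#' twice-weight index is `x / (x + 2 y_ab + y_a + y_b)`; it down-weights
#' joint-identification-without-association days twice, making it the
#' least biased choice when associated individuals are more likely to be
#' observed than lone ones. Half-weight
#' (`x / (x + y_ab + (y_a + y_b)/2)`) and the simple ratio
#' (`x / (x + y_ab + y_a + y_b)`) are available for sensitivity analysis.
#'
#' @param x,y_ab,y_a,y_b Nonnegative counts (vectorised).
#' @param index One of `"twice-weight"`, `"half-weight"`, `"simple-ratio"`.
#' @return Index values in `[0, 1]`; `NA` where the denominator is zero
#'   (a never-co-sampled dyad carries no information — `NA`, not 0).
#' @examples
#' assoc_index(x = 2, y_ab = 1, y_a = 1, y_b = 0)  # 0.4
#' @export
assoc_index <- function(x, y_ab, y_a, y_b, index = "twice-weight") {
  index <- match.arg(index, ASSOC_INDICES)
  if (any(c(x, y_ab, y_a, y_b) < 0, na.rm = TRUE)) {
    abort("sampling counts must be nonnegative")
  }
  denom <- switch(index,
    "twice-weight" = x + 2 * y_ab + y_a + y_b,
    "half-weight"  = x + y_ab + (y_a + y_b) / 2,
    "simple-ratio" = x + y_ab + y_a + y_b)
  ifelse(denom > 0, x / denom, NA_real_)
}

#' Day-partition sampling counts for one dyad
#'
#' Classifies every daily record by what it contributes to the dyad's
#' sampling history: associated (`x`), both identified without association
#' (`y_ab`), or only one identified (`y_a`, `y_b`). Days on which neither
#' was identified do not enter any count.
#'
#' @param daily Daily records from [aggregate_daily()], for one behaviour.
#' @param id_a,id_b Distinct individual ids.
#' @return One-row tibble: `id_a`, `id_b`, `x`, `y_a`, `y_b`, `y_ab`.
#' @export
dyad_counts <- function(daily, id_a, id_b) {
  if (id_a == id_b) abort("a dyad consists of two distinct individuals")
  key <- dyad_key(id_a, id_b)
  in_a <- purrr::map_lgl(daily$identified, ~ id_a %in% .x)
  in_b <- purrr::map_lgl(daily$identified, ~ id_b %in% .x)
  assoc <- purrr::map_lgl(daily$dyads, ~ key %in% .x)
  tibble(
    id_a = min(id_a, id_b), id_b = max(id_a, id_b),
    x = sum(in_a & in_b & assoc),
    y_a = sum(xor(in_a, in_b) & (if (id_a < id_b) in_a else in_b)),
    y_b = sum(xor(in_a, in_b) & (if (id_a < id_b) in_b else in_a)),
    y_ab = sum(in_a & in_b & !assoc)
  )
}

#' Build an association matrix over a set of individuals
#'
#' Computes the symmetric association-index matrix for all listed
#' individuals from daily one-zero records. Individuals never identified
#' on any day yield all-missing rows; the diagonal is always `NA`. When a
#' `groups` lookup is supplied, cross-group dyads are masked as missing —
#' groups are closed networks and such dyads are never formed.
#'
#' @param daily Daily records from [aggregate_daily()] (one behaviour).
#' @param ids Character vector of individuals to include (the matrix order).
#' @param index Association index variant, see [assoc_index()].
#' @param groups Optional named character vector mapping id to group.
#' @return A numeric matrix of class `assoc_matrix` with `ids` as dimnames
#'   and attributes `behaviour` and `index`.
#' @export
build_assoc_matrix <- function(daily, ids, index = "twice-weight",
                               groups = NULL) {
  index <- match.arg(index, ASSOC_INDICES)
  if (length(ids) == 0) abort("at least one individual is required")
  if (anyDuplicated(ids)) abort("ids must be unique")
  n <- length(ids)

  # Day-by-individual identification incidence and per-day association.
  n_days <- nrow(daily)
  ident <- matrix(FALSE, n_days, n)
  assoc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (d in seq_len(n_days)) {
    ident[d, ] <- ids %in% daily$identified[[d]]
    keys <- daily$dyads[[d]]
    if (length(keys) > 0) {
      parts <- split_dyad_key(keys)
      ia <- match(parts$a, ids)
      ib <- match(parts$b, ids)
      keep <- !is.na(ia) & !is.na(ib)
      if (any(keep)) {
        assoc[cbind(ia[keep], ib[keep])] <- assoc[cbind(ia[keep], ib[keep])] + 1
        assoc[cbind(ib[keep], ia[keep])] <- assoc[cbind(ib[keep], ia[keep])] + 1
      }
    }
  }

  both <- crossprod(ident)            # days both identified
  days_each <- diag(both)             # days each identified
  y_ab <- both - assoc
  y_a <- matrix(days_each, n, n) - both        # rows: days only i identified
  y_b <- t(y_a)

  ai <- matrix(
    assoc_index(as.vector(assoc), as.vector(y_ab),
                as.vector(y_a), as.vector(y_b), index = index),
    n, n, dimnames = list(ids, ids))
  diag(ai) <- NA_real_
  # a never-identified individual carries no sampling information at all
  ai[days_each == 0, ] <- NA_real_
  ai[, days_each == 0] <- NA_real_

  if (!is.null(groups)) {
    g <- groups[ids]
    cross <- outer(g, g, `!=`)
    ai[cross] <- NA_real_
  }

  structure(ai,
            behaviour = if (n_days > 0) daily$behaviour[[1]] else NA_character_,
            index = index,
            class = c("assoc_matrix", "matrix", "array"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d individuals, behaviour = %s, index = %s\n",
              nrow(x), attr(x, "behaviour") %||% "?", attr(x, "index")))
  cat(sprintf("  %d of %d dyads non-missing; mean AI (non-missing) = %.4g\n",
              sum(!is.na(x[upper.tri(x)])), sum(upper.tri(x)),
              mean(x[upper.tri(x)], na.rm = TRUE)))
  invisible(x)
}

#' Write / read an association matrix as square CSV
#'
#' The exchange format is a square CSV with the individual ids as header
#' row and first column, and empty cells for missing dyads.
#'
#' @param A An `assoc_matrix`.
#' @param path CSV path.
#' @return `write_assoc_matrix()` returns `path` invisibly;
#'   `read_assoc_matrix()` returns an `assoc_matrix` (behaviour/index
#'   attributes are not stored in the CSV and come back as `NA`/default).
#' @export
write_assoc_matrix <- function(A, path) {
  df <- as.data.frame(unclass(A))
  df <- cbind(id = rownames(A), df)
  readr::write_csv(as_tibble(df), path, na = "")
  invisible(path)
}

#' @rdname write_assoc_matrix
#' @export
read_assoc_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(id = "c", .default = "d"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  structure(m, behaviour = NA_character_, index = "twice-weight",
            class = c("assoc_matrix", "matrix", "array"))
}
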