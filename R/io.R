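# Reading, validating and normalising focal-follow observation data, the
# per-day one-zero sampling reduction, and inter-observer agreement.

BEHAVIOURS <- c("proximity", "grooming")

#' Assemble and validate a focal-follow observation dataset
#'
#' Bundles the three tables every downstream analysis consumes — focal
#' follows, dyadic behaviour events, and demographics — into a single
#' validated object. Referential integrity is enforced: every individual
#' appearing in a follow or event must exist in the demographics table and
#' belong to the group the record claims.
#'
#' @param follows Tibble of focal follows with columns `follow_id`,
#'   `focal_id`, `date` (class `Date`), `group_id`, `in_view_seconds`, and
#'   `party_member_ids` (a list-column of character vectors, the focal
#'   excluded).
#' @param events Tibble of dyadic behaviour events with columns `date`,
#'   `behaviour` (`"proximity"` or `"grooming"`), `id_a`, `id_b`,
#'   `group_id`. Dyads are unordered; directionality is not recorded.
#' @param demographics Tibble with columns `id`, `group_id`, `origin`
#'   (`"wild"` or `"sanctuary"`), `sex` (`"F"`/`"M"`), `age_years`,
#'   `arrival_age_years` (missing for sanctuary-born), `rank`,
#'   `matriline_id` (may be missing).
#' @param min_in_view_seconds Minimum in-view time for a follow to enter the
#'   analysis; follows below the threshold are dropped (with a message) and
#'   kept in `attr(x, "excluded_follows")`. The conventional field protocol
#'   requires at least 5 minutes of a 10-minute follow; set to `0` to keep
#'   everything.
#'
#' @return An object of class `observation_data`: a list with elements
#'   `follows`, `events`, `demographics` (all tibbles).
#' @seealso [read_observations()] to build one from CSV files,
#'   [aggregate_daily()] for the one-zero sampling reduction.
#' @export
observation_data <- function(follows, events, demographics,
                             min_in_view_seconds = 300) {
  demographics <- as_tibble(demographics)
  follows <- as_tibble(follows)
  events <- as_tibble(events)

  assert_columns(demographics,
                 c("id", "group_id", "origin", "sex", "age_years",
                   "arrival_age_years", "rank", "matriline_id"),
                 "demographics")
  assert_columns(follows,
                 c("follow_id", "focal_id", "date", "group_id",
                   "in_view_seconds", "party_member_ids"),
                 "follows")
  assert_columns(events,
                 c("date", "behaviour", "id_a", "id_b", "group_id"),
                 "events")

  if (anyDuplicated(demographics$id)) {
    abort(sprintf("duplicate individual id(s) in demographics: %s",
                  paste(unique(demographics$id[duplicated(demographics$id)]),
                        collapse = ", ")))
  }
  if (!all(demographics$origin %in% c("wild", "sanctuary"))) {
    abort("demographics$origin must be 'wild' or 'sanctuary'")
  }
  if (!all(demographics$sex %in% c("F", "M"))) {
    abort("demographics$sex must be 'F' or 'M'")
  }
  if (any(demographics$age_years < 0, na.rm = TRUE)) {
    abort("age_years must be nonnegative")
  }
  bad_arrival <- demographics$origin == "sanctuary" &
    !is.na(demographics$arrival_age_years)
  if (any(bad_arrival)) {
    abort(sprintf(
      "sanctuary-born individuals cannot have an arrival age: %s",
      paste(demographics$id[bad_arrival], collapse = ", ")))
  }

  group_of <- setNames(demographics$group_id, demographics$id)

  # follows ------------------------------------------------------------
  if (anyDuplicated(follows$follow_id)) {
    abort(sprintf("duplicate follow_id(s): %s",
                  paste(unique(follows$follow_id[duplicated(follows$follow_id)]),
                        collapse = ", ")))
  }
  if (!inherits(follows$date, "Date") || anyNA(follows$date)) {
    abort("follows$date must be valid Date values (ISO-8601 in files)")
  }
  if (!is.list(follows$party_member_ids)) {
    abort("follows$party_member_ids must be a list-column of character vectors")
  }
  if (any(!is.finite(follows$in_view_seconds)) ||
      any(follows$in_view_seconds <= 0)) {
    abort("in_view_seconds must be positive")
  }
  check_known_ids(follows$focal_id, group_of, "follows$focal_id")
  party_ids <- unique(unlist(follows$party_member_ids))
  check_known_ids(party_ids, group_of, "follows$party_member_ids")
  grp_mismatch <- follows$group_id != unname(group_of[follows$focal_id])
  if (any(grp_mismatch)) {
    abort(sprintf("follow(s) %s place the focal in the wrong group",
                  paste(follows$follow_id[grp_mismatch], collapse = ", ")))
  }
  self_in_party <- purrr::map2_lgl(follows$focal_id, follows$party_member_ids,
                                   ~ .x %in% .y)
  if (any(self_in_party)) {
    abort(sprintf("focal listed among its own party members in follow(s): %s",
                  paste(follows$follow_id[self_in_party], collapse = ", ")))
  }

  # events -------------------------------------------------------------
  if (nrow(events) > 0) {
    if (!inherits(events$date, "Date") || anyNA(events$date)) {
      abort("events$date must be valid Date values (ISO-8601 in files)")
    }
    if (!all(events$behaviour %in% BEHAVIOURS)) {
      abort(sprintf("events$behaviour must be one of: %s",
                    paste(BEHAVIOURS, collapse = ", ")))
    }
    check_known_ids(events$id_a, group_of, "events$id_a")
    check_known_ids(events$id_b, group_of, "events$id_b")
    if (any(events$id_a == events$id_b)) {
      abort("events must involve two distinct individuals")
    }
    cross <- group_of[events$id_a] != group_of[events$id_b] |
      events$group_id != unname(group_of[events$id_a])
    if (any(cross)) {
      abort(sprintf("event row(s) %s pair individuals across groups or carry the wrong group_id",
                    paste(which(cross), collapse = ", ")))
    }
  }

  excluded <- follows[follows$in_view_seconds < min_in_view_seconds, ]
  if (nrow(excluded) > 0) {
    inform(sprintf(
      "Excluding %d follow(s) with in-view time below %g s (kept in attr 'excluded_follows')",
      nrow(excluded), min_in_view_seconds))
    follows <- follows[follows$in_view_seconds >= min_in_view_seconds, ]
  }

  structure(
    list(follows = follows, events = events, demographics = demographics),
    excluded_follows = excluded,
    min_in_view_seconds = min_in_view_seconds,
    class = "observation_data"
  )
}

check_known_ids <- function(ids, group_of, what) {
  unknown <- setdiff(ids, names(group_of))
  if (length(unknown) > 0) {
    abort(sprintf("%s refers to individual(s) absent from demographics: %s",
                  what, paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.observation_data <- function(x, ...) {
  d <- x$demographics
  cat("<observation_data>\n")
  cat(sprintf("  %d individuals (%d wild-born, %d sanctuary-born) in %d group(s)\n",
              nrow(d), sum(d$origin == "wild"), sum(d$origin == "sanctuary"),
              dplyr::n_distinct(d$group_id)))
  cat(sprintf("  %d focal follows over %d day(s); %d behaviour events\n",
              nrow(x$follows), dplyr::n_distinct(x$follows$date),
              nrow(x$events)))
  invisible(x)
}

#' Read a focal-follow dataset from CSV files
#'
#' Reads the three comma-delimited tables (UTF-8, header row mandatory,
#' empty fields as missing) and validates them with [observation_data()].
#' In the follows file, `party_member_ids` is a single column with ids
#' separated by `";"` (empty for a lone focal). Dates must be ISO-8601.
#'
#' @param focal_path,events_path,demographics_path Paths to the CSV files.
#' @inheritParams observation_data
#' @return An `observation_data` object.
#' @export
read_observations <- function(focal_path, events_path, demographics_path,
                              min_in_view_seconds = 300) {
  demographics <- readr::read_csv(
    demographics_path, show_col_types = FALSE,
    col_types = readr::cols(
      id = "c", group_id = "c", origin = "c", sex = "c",
      age_years = "d", arrival_age_years = "d", rank = "d",
      matriline_id = "c"))
  follows_raw <- readr::read_csv(
    focal_path, show_col_types = FALSE,
    col_types = readr::cols(
      follow_id = "c", focal_id = "c", date = "c", group_id = "c",
      in_view_seconds = "d", party_member_ids = "c"))
  events_raw <- readr::read_csv(
    events_path, show_col_types = FALSE,
    col_types = readr::cols(date = "c", behaviour = "c", id_a = "c",
                            id_b = "c", group_id = "c"))

  follows <- follows_raw |>
    mutate(date = parse_iso_date(.data$date, "follows"),
           party_member_ids = purrr::map(.data$party_member_ids, split_id_list))
  events <- events_raw |>
    mutate(date = parse_iso_date(.data$date, "events"))

  observation_data(follows, events, demographics,
                   min_in_view_seconds = min_in_view_seconds)
}

parse_iso_date <- function(x, what) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) | is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("malformed date in %s row(s): %s (values: %s)", what,
                  paste(head(bad, 5), collapse = ", "),
                  paste(head(x[bad], 5), collapse = ", ")))
  }
  out
}

split_id_list <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Write an observation dataset to the three-CSV exchange format
#'
#' Inverse of [read_observations()]: writes `follows.csv`, `events.csv`
#' and `demographics.csv` into `dir`.
#'
#' @param obs An `observation_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_observations <- function(obs, dir) {
  stopifnot(inherits(obs, "observation_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("follows.csv", "events.csv", "demographics.csv"))
  follows_flat <- obs$follows |>
    mutate(party_member_ids = purrr::map_chr(.data$party_member_ids,
                                             paste, collapse = ";"))
  readr::write_csv(follows_flat, paths[1])
  readr::write_csv(obs$events, paths[2])
  readr::write_csv(obs$demographics, paths[3])
  invisible(paths)
}

#' Reduce events and follows to daily one-zero records
#'
#' Applies the per-day 1/0 sampling rule: for each calendar day and group,
#' an unordered dyad is scored as associated (once) if it has at least one
#' event of the requested behaviour that day, regardless of how many events
#' occurred. The day's *identified* set is every individual captured on
#' video that day — as a focal or as a member of any focal's party. Days
#' with no follows for a group yield no record.
#'
#' @param obs An `observation_data` object.
#' @param behaviour `"proximity"` or `"grooming"`.
#' @return A tibble with one row per (date, group): columns `date`,
#'   `group_id`, `behaviour`, `identified` (list of sorted ids) and
#'   `dyads` (list of `"a|b"` keys of dyads associated that day).
#' @export
aggregate_daily <- function(obs, behaviour = c("proximity", "grooming")) {
  stopifnot(inherits(obs, "observation_data"))
  behaviour <- match.arg(behaviour)

  ident <- obs$follows |>
    mutate(ids = purrr::map2(.data$focal_id, .data$party_member_ids, c)) |>
    group_by(.data$date, .data$group_id) |>
    summarise(identified = list(sort(unique(unlist(.data$ids)))),
              .groups = "drop")

  ev <- obs$events |>
    filter(.data$behaviour == !!behaviour) |>
    mutate(key = dyad_key(.data$id_a, .data$id_b)) |>
    group_by(.data$date, .data$group_id) |>
    summarise(dyads = list(sort(unique(.data$key))), .groups = "drop")

  daily <- ident |>
    left_join(ev, by = c("date", "group_id")) |>
    mutate(dyads = purrr::map(.data$dyads, ~ .x %||% character(0)),
           behaviour = behaviour) |>
    arrange(.data$date, .data$group_id) |>
    select("date", "group_id", "behaviour", "identified", "dyads")

  # Event days without any follow would leave associated individuals
  # unidentified; that breaks the sampling-period semantics.
  orphan <- anti_join(ev, ident, by = c("date", "group_id"))
  if (nrow(orphan) > 0) {
    abort(sprintf(
      "%s events on %s (group %s) have no focal follow that day; every associated individual must be identified",
      behaviour, format(orphan$date[1]), orphan$group_id[1]))
  }
  bad <- purrr::map2_lgl(daily$identified, daily$dyads, function(ids, keys) {
    if (length(keys) == 0) return(FALSE)
    parts <- split_dyad_key(keys)
    !all(c(parts$a, parts$b) %in% ids)
  })
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "on %s (group %s) an associated dyad involves an individual not identified that day",
      format(daily$date[i]), daily$group_id[i]))
  }
  daily
}

#' Export daily records in long format
#'
#' Flattens the output of [aggregate_daily()] to one row per identified
#' individual (`status = "identified"`) and one row per associated dyad
#' (`status = "associated"`), suitable for CSV export.
#'
#' @param daily A daily-record tibble from [aggregate_daily()].
#' @param path Optional CSV path; when given the tibble is also written.
#' @return The long-format tibble (`date`, `group_id`, `behaviour`,
#'   `id_or_dyad`, `status`).
#' @export
daily_long <- function(daily, path = NULL) {
  long <- dplyr::bind_rows(
    daily |>
      select("date", "group_id", "behaviour", id_or_dyad = "identified") |>
      tidyr::unnest_longer("id_or_dyad") |>
      mutate(status = "identified"),
    daily |>
      select("date", "group_id", "behaviour", id_or_dyad = "dyads") |>
      tidyr::unnest_longer("id_or_dyad") |>
      mutate(status = "associated")
  ) |>
    arrange(.data$date, .data$group_id, .data$status, .data$id_or_dyad)
  if (!is.null(path)) readr::write_csv(long, path)
  long
}

#' Cohen's kappa for inter-observer agreement
#'
#' Chance-corrected agreement between two coders assigning categories to
#' the same items: `(p_o - p_e) / (1 - p_e)`, with expected agreement
#' `p_e` from the product of the marginal category frequencies. Field
#' protocols typically require kappa of at least 0.85 before coders work
#' independently.
#'
#' @param codes_a,codes_b Equal-length vectors of category labels.
#' @return Kappa in `[-1, 1]`; exactly 1 for perfect agreement (including
#'   the degenerate single-category case).
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "a", "b"))
#' @export
cohens_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) {
    abort("codes_a and codes_b must have the same length")
  }
  if (length(codes_a) < 1) abort("at least one coded item is required")
  lev <- sort(unique(c(as.character(codes_a), as.character(codes_b))))
  a <- factor(as.character(codes_a), levels = lev)
  b <- factor(as.character(codes_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o >= 1 - .Machine$double.eps^0.5) 1 else NaN)
  }
  (p_o - p_e) / (1 - p_e)
}
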