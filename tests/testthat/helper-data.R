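# Small hand-built fixtures, constructed in code at test time.

toy_demographics <- function() {
  tibble::tibble(
    id = c("ann", "bob", "cleo", "dan"),
    group_id = "G1",
    origin = c("wild", "sanctuary", "wild", "sanctuary"),
    sex = c("F", "M", "F", "M"),
    age_years = c(15, 8, 22, 30),
    arrival_age_years = c(2.5, NA, 4, NA),
    rank = c(0.9, 0.2, 0.5, 0.7),
    matriline_id = c("M1", "M1", "M2", NA))
}

toy_follows <- function() {
  tibble::tibble(
    follow_id = c("f1", "f2", "f3"),
    focal_id = c("ann", "bob", "ann"),
    date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-02")),
    group_id = "G1",
    in_view_seconds = c(600, 450, 580),
    party_member_ids = list(c("bob", "cleo"), c("ann"), character(0)))
}

toy_events <- function() {
  tibble::tibble(
    date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-01")),
    behaviour = c("proximity", "proximity", "grooming"),
    id_a = c("ann", "bob", "ann"),
    id_b = c("bob", "ann", "cleo"),
    group_id = "G1")
}

toy_obs <- function(...) {
  observation_data(toy_follows(), toy_events(), toy_demographics(), ...)
}

# A compact generator configuration for fast unit tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_groups = 2, group_sizes = c(12, 12), wild_per_group = c(6, 6),
         n_days = 60, follows_per_day = 3),
    list(...))
  do.call(synth_config, args)
}

# Write an observation dataset to CSVs in a temp dir; returns the paths.
write_toy_csvs <- function(obs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- write_observations(obs, dir)
  list(focal = paths[1], events = paths[2], demographics = paths[3])
}
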