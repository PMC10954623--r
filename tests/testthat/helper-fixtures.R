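# Programmatic fixtures shared across test files. Everything is built in
# code at test time; no binary data.

KM_PER_DEG <- 6371.0088 * pi / 180   # km per degree along a great circle

# points laid out in km offsets from an origin on the equator, where
# longitude degrees convert to km exactly (great circles along the equator)
equator_points <- function(x_km, y_km = rep(0, length(x_km)), lat0 = 0,
                           lon0 = 0) {
  data.frame(lat = lat0 + y_km / KM_PER_DEG,
             lon = lon0 + x_km / KM_PER_DEG)
}

# a tiny 4-hospital network with uniform accrual, for simulator examples
four_hospitals <- function() {
  data.frame(hospital_id = sprintf("H%d", 1:4),
             name = paste("site", 1:4),
             lat = c(10, 12, 14, 16), lon = c(76, 78, 80, 78),
             district_id = sprintf("D%d", 1:4),
             region = c("South", "South", "East", "North"),
             ownership = c("public", "private", "public", "public"),
             accrual_weight = rep(1, 4),
             stringsAsFactors = FALSE)
}

write_case_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# minimal valid case-table data frame, overridable per test
make_cases <- function(n = 3, ...) {
  df <- data.frame(
    episode_id = sprintf("E%d", seq_len(n)),
    child_id = sprintf("C%d", seq_len(n)),
    lat = seq(10, by = 0.1, length.out = n),
    lon = seq(76, by = 0.1, length.out = n),
    district_id = rep_len("D1", n), subdistrict_id = rep_len("S1", n),
    region = rep_len("South", n), sex = rep_len("M", n),
    age_months = rep_len(6L, n),
    hospital_id = rep_len("H1", n),
    surveillance_mode = rep_len("prospective", n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}
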