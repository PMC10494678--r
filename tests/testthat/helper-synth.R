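# shared fixtures, built in code

small_params <- function(...) {
  defaults <- list(
    n_regions = 4L, munis_per_region = 5L,
    admissions_per_muni_year = 8, births_per_muni_year = 40,
    seed = 42L
  )
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

# independent haversine implementation (asin form), the distance oracle
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# degrees of latitude spanning `km` kilometres along a meridian (exact for
# the haversine sphere), used to construct registries with known distances
deg_for_km <- function(km) km / 6371 * 180 / pi

# hand-built registry: one region per entry of `region`, seat = first
# municipality listed in each region
manual_registry <- function(codes, region, lat, lon,
                            macro = NULL, seat = NULL) {
  if (is.null(seat)) seat <- !duplicated(region)
  if (is.null(macro)) {
    macros <- c("leste", "oeste", "noroeste", "norte")
    macro <- macros[(region - 1) %% 4 + 1]
  }
  tibble::tibble(
    code = as.integer(codes),
    name = sprintf("M%06d", codes),
    region_id = as.integer(region),
    macroregion = macro,
    seat_lat = lat,
    seat_lon = lon,
    is_region_seat = seat
  )
}

# expand an OD table back to unit admission records
od_to_records <- function(od) {
  start <- as.integer(substr(od$biennium_label, 1, 4))
  tibble::tibble(
    residence_code = rep(od$origin_code, od$flow),
    occurrence_code = rep(od$destination_code, od$flow),
    year = rep(start, od$flow),
    age_days = 0L
  )
}

# random displaced OD table over a registry, for property-style tests
random_od <- function(registry, n_pairs, seed, n_biennia = 2L) {
  withr::with_seed(seed, {
    codes <- registry$code
    o <- sample(codes, n_pairs * 3L, replace = TRUE)
    d <- sample(codes, n_pairs * 3L, replace = TRUE)
    keep <- o != d
    key <- !duplicated(paste(o, d)[keep])
    o <- o[keep][key][seq_len(min(n_pairs, sum(key)))]
    d <- d[keep][key][seq_len(length(o))]
    bi <- sample(seq_len(n_biennia), length(o), replace = TRUE)
    tibble::tibble(
      origin_code = o,
      destination_code = d,
      biennium_label = biennium_labels()[bi],
      biennium_index = bi,
      flow = sample(1:20, length(o), replace = TRUE)
    )
  })
}
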