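#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km between points given in
#' decimal degrees. Used for all origin-destination distances, taken between
#' the municipal seat coordinates of the two municipalities.
#'
#' @param lat1,lon1,lat2,lon2 Numeric vectors of coordinates in degrees
#'   (recycled to a common length).
#' @return Numeric vector of distances in km; symmetric, non-negative and
#'   zero exactly for identical points.
#' @examples
#' great_circle_km(-25, -51, -25, -50)
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  for (v in list(lat1, lat2)) {
    if (anyNA(v) || any(v < -90 | v > 90)) {
      stop("latitudes must lie in [-90, 90]", call. = FALSE)
    }
  }
  for (v in list(lon1, lon2)) {
    if (anyNA(v) || any(v < -180 | v > 180)) {
      stop("longitudes must lie in [-180, 180]", call. = FALSE)
    }
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

# Attach seat-to-seat distance (km) and origin/destination region ids to an
# OD table.
od_augment <- function(od, registry) {
  stop_if_not_df_with(od, c("origin_code", "destination_code",
                            "biennium_label", "biennium_index", "flow"), "od")
  check_registry(registry)
  missing_dest <- setdiff(od$destination_code, registry$code)
  missing_orig <- setdiff(od$origin_code, registry$code)
  if (length(missing_dest) || length(missing_orig)) {
    stop("OD table contains codes absent from the registry: ",
         paste(head(c(missing_orig, missing_dest), 5), collapse = ", "),
         call. = FALSE)
  }
  geo <- registry[, c("code", "region_id", "seat_lat", "seat_lon")]
  od <- dplyr::left_join(
    od,
    setNames(geo, c("origin_code", "origin_region", "o_lat", "o_lon")),
    by = "origin_code"
  )
  od <- dplyr::left_join(
    od,
    setNames(geo, c("destination_code", "destination_region", "d_lat", "d_lon")),
    by = "destination_code"
  )
  od$dist_km <- great_circle_km(od$o_lat, od$o_lon, od$d_lat, od$d_lon)
  od
}

#' Mean outgoing edge per origin municipality
#'
#' For each origin municipality and biennium, computes the flow-weighted mean
#' distance to its destinations,
#' \deqn{d_i = \frac{\sum_k f_k \, d(O_i, D_k)}{\sum_k f_k},}
#' where \eqn{f_k} is the admission count of the pair \eqn{(O_i, D_k)} and
#' \eqn{d(\cdot)} the seat-to-seat great-circle distance, together with the
#' total outflow \eqn{F_i = \sum_k f_k}.
#'
#' @param od OD table from [aggregate_od()] (displaced, in-state pairs).
#' @param registry Municipality registry providing seat coordinates.
#' @return A tibble with one row per origin x biennium: `origin_code`,
#'   `biennium_label`, `biennium_index`, `region_id` (of the origin),
#'   `outflow` (\eqn{F_i}), `mean_edge_km` (\eqn{d_i}).
#' @export
origin_mean_edge <- function(od, registry) {
  if (nrow(od) == 0L) stop("no OD pairs supplied", call. = FALSE)
  od <- od_augment(od, registry)
  out <- dplyr::summarise(
    dplyr::group_by(od, .data$origin_code, .data$biennium_label,
                    .data$biennium_index, region_id = .data$origin_region),
    outflow = sum(.data$flow),
    mean_edge_km = sum(.data$flow * .data$dist_km) / sum(.data$flow),
    .groups = "drop"
  )
  out
}

#' Flow-weighted mean displacement distance per health region
#'
#' Aggregates the per-origin mean edges of [origin_mean_edge()] to the health
#' region: for region \eqn{j} with origins \eqn{i = 1, \dots, n_j},
#' \deqn{m_j = \frac{\sum_i F_i \, d_i}{\sum_i F_i}.}
#' Because both levels weight by flow, \eqn{m_j} equals the single-pass
#' flow-weighted mean of seat-to-seat distances over all the region's
#' displaced admission records — the identity the test suite checks.
#'
#' @param origin_summaries Output of [origin_mean_edge()].
#' @return A tibble with one row per region x biennium: `region_id`,
#'   `biennium_label`, `biennium_index`, `n_origins` (\eqn{n_j}), `outflow`
#'   (\eqn{\sum_i F_i}), `weighted_distance_km` (\eqn{m_j}).
#' @export
region_weighted_distance <- function(origin_summaries) {
  stop_if_not_df_with(origin_summaries,
                      c("region_id", "biennium_label", "biennium_index",
                        "outflow", "mean_edge_km"),
                      "origin_summaries")
  if (nrow(origin_summaries) == 0L) {
    stop("no origin summaries supplied; a region with zero displaced flow has no defined distance",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(origin_summaries, .data$region_id, .data$biennium_label,
                    .data$biennium_index),
    n_origins = dplyr::n(),
    weighted_distance_km =
      sum(.data$outflow * .data$mean_edge_km) / sum(.data$outflow),
    outflow = sum(.data$outflow), # last: must not shadow the weighting column
    .groups = "drop"
  )
  out[, c("region_id", "biennium_label", "biennium_index", "n_origins",
          "outflow", "weighted_distance_km")]
}

#' Share of admissions occurring outside the residence municipality
#'
#' Per health region of residence and biennium:
#' 100 x (displaced in-state admissions) / (all in-state neonatal admissions
#' of the region's residents). Out-of-state admissions enter neither
#' numerator nor denominator.
#'
#' @param partition Output of [partition_displaced()] on neonatal records.
#' @param registry Municipality registry.
#' @inheritParams assign_biennium
#' @return Tibble: `region_id`, `biennium_label`, `biennium_index`,
#'   `n_admissions` (in-state), `pct_displaced`.
#' @export
pct_displaced <- function(partition, registry, start_year = 2008L,
                          n_biennia = 6L) {
  stopifnot(is.list(partition),
            all(c("same_municipality", "displaced") %in% names(partition)))
  check_registry(registry)
  instate <- dplyr::bind_rows(
    dplyr::mutate(partition$same_municipality, .displaced = FALSE),
    dplyr::mutate(partition$displaced, .displaced = TRUE)
  )
  if (nrow(instate) == 0L) {
    return(tibble::tibble(region_id = integer(), biennium_label = character(),
                          biennium_index = integer(), n_admissions = integer(),
                          pct_displaced = numeric()))
  }
  bi <- assign_biennium(instate$year, start_year, n_biennia)
  instate$biennium_label <- bi$label
  instate$biennium_index <- bi$index
  instate <- dplyr::left_join(
    instate,
    setNames(registry[, c("code", "region_id")], c("residence_code", "region_id")),
    by = "residence_code"
  )
  dplyr::summarise(
    dplyr::group_by(instate, .data$region_id, .data$biennium_label,
                    .data$biennium_index),
    n_admissions = dplyr::n(),
    pct_displaced = 100 * mean(.data$.displaced),
    .groups = "drop"
  )
}

#' Share of displaced admissions staying within the health region
#'
#' Per origin health region and biennium: 100 x (displaced flow whose
#' destination municipality belongs to the same region) / (total displaced
#' flow of the region's origins). The denominator is displaced admissions
#' only.
#'
#' @inheritParams origin_mean_edge
#' @return Tibble: `region_id`, `biennium_label`, `biennium_index`,
#'   `displaced_flow`, `pct_same_region`.
#' @export
pct_same_region <- function(od, registry) {
  if (nrow(od) == 0L) {
    return(tibble::tibble(region_id = integer(), biennium_label = character(),
                          biennium_index = integer(), displaced_flow = integer(),
                          pct_same_region = numeric()))
  }
  od <- od_augment(od, registry)
  dplyr::summarise(
    dplyr::group_by(od, region_id = .data$origin_region, .data$biennium_label,
                    .data$biennium_index),
    displaced_flow = sum(.data$flow),
    pct_same_region = 100 *
      sum(.data$flow[.data$destination_region == .data$origin_region]) /
      sum(.data$flow),
    .groups = "drop"
  )
}

#' Regional health and service-supply indicators
#'
#' Per health region and biennium, from the vital-records and bed tables:
#' NICU beds per 1,000 live births (bed counts averaged over the biennium's
#' two year-end values), the percentage of live births with weight < 1,500 g,
#' gestational age < 28 weeks, 5-minute Apgar <= 7, maternal age >= 35
#' years, and the neonatal mortality rate (TMN), deaths at age 0-27 days per
#' 1,000 live births. Regions with zero births in a biennium get `NA` for
#' every indicator.
#'
#' @param births,deaths,beds Tables as produced by [generate_vital_records()]
#'   and [generate_bed_counts()] (or read from SINASC/SIM/CNES-like CSVs).
#' @param registry Municipality registry.
#' @inheritParams assign_biennium
#' @return Tibble with one row per region x biennium and columns `n_births`,
#'   `nicu_beds_per_1000`, `pct_low_weight`, `pct_ga_lt28`, `pct_apgar5_le7`,
#'   `pct_maternal_35plus`, `tmn`.
#' @export
compute_indicators <- function(births, deaths, beds, registry,
                               start_year = 2008L, n_biennia = 6L) {
  stop_if_not_df_with(births, c("residence_code", "year", "birth_weight_g",
                                "gestational_age_weeks", "apgar5",
                                "maternal_age_years"), "births")
  stop_if_not_df_with(deaths, c("residence_code", "year", "age_at_death_days"),
                      "deaths")
  stop_if_not_df_with(beds, c("municipality_code", "year", "nicu_beds"), "beds")
  check_registry(registry)
  region_of <- setNames(registry$region_id, registry$code)
  add_keys <- function(df, code_col) {
    bi <- assign_biennium(df$year, start_year, n_biennia)
    df$biennium_label <- bi$label
    df$biennium_index <- bi$index
    df$region_id <- unname(region_of[as.character(df[[code_col]])])
    if (anyNA(df$region_id)) {
      stop("codes absent from the registry in `", code_col, "`", call. = FALSE)
    }
    df
  }

  b <- dplyr::summarise(
    dplyr::group_by(add_keys(births, "residence_code"), .data$region_id,
                    .data$biennium_label, .data$biennium_index),
    n_births = dplyr::n(),
    pct_low_weight = 100 * mean(.data$birth_weight_g < 1500),
    pct_ga_lt28 = 100 * mean(.data$gestational_age_weeks < 28),
    pct_apgar5_le7 = 100 * mean(.data$apgar5 <= 7),
    pct_maternal_35plus = 100 * mean(.data$maternal_age_years >= 35),
    .groups = "drop"
  )

  grid <- expand.grid(
    region_id = sort(unique(registry$region_id)),
    biennium_index = seq_len(n_biennia)
  )
  grid$biennium_label <- biennium_labels(start_year, n_biennia)[grid$biennium_index]
  out <- dplyr::left_join(tibble::as_tibble(grid), b,
                          by = c("region_id", "biennium_label", "biennium_index"))

  if (nrow(deaths)) {
    d <- dplyr::summarise(
      dplyr::group_by(add_keys(deaths, "residence_code"), .data$region_id,
                      .data$biennium_index),
      neonatal_deaths = sum(.data$age_at_death_days <= 27),
      .groups = "drop"
    )
    out <- dplyr::left_join(out, d, by = c("region_id", "biennium_index"))
  } else {
    out$neonatal_deaths <- 0L
  }
  out$neonatal_deaths[is.na(out$neonatal_deaths)] <- 0L

  if (nrow(beds)) {
    k <- dplyr::summarise(
      dplyr::group_by(add_keys(beds, "municipality_code"), .data$region_id,
                      .data$biennium_index, .data$year),
      beds_year = sum(.data$nicu_beds), .groups = "drop"
    )
    k <- dplyr::summarise( # mean of the biennium's two year totals
      dplyr::group_by(k, .data$region_id, .data$biennium_index),
      nicu_beds = mean(.data$beds_year), .groups = "drop"
    )
    out <- dplyr::left_join(out, k, by = c("region_id", "biennium_index"))
  } else {
    out$nicu_beds <- 0
  }
  out$nicu_beds[is.na(out$nicu_beds)] <- 0

  out$tmn <- 1000 * out$neonatal_deaths / out$n_births
  out$nicu_beds_per_1000 <- 1000 * out$nicu_beds / out$n_births
  zero <- is.na(out$n_births) | out$n_births == 0
  ind_cols <- c("nicu_beds_per_1000", "pct_low_weight", "pct_ga_lt28",
                "pct_apgar5_le7", "pct_maternal_35plus", "tmn")
  for (cl in ind_cols) out[[cl]][zero] <- NA_real_
  out[, c("region_id", "biennium_label", "biennium_index", "n_births",
          ind_cols)]
}

#' Percent variation between two periods
#'
#' The between-biennium comparison measure \eqn{100 (B - A) / A} used for
#' in-degree, inflow, weighted distances and displacement proportions (A =
#' earlier biennium, B = later). A zero baseline has no defined variation and
#' yields `NA` with a warning.
#'
#' @param a Baseline value(s).
#' @param b Comparison value(s).
#' @return `100 * (b - a) / a`, `NA` where `a == 0`.
#' @examples
#' percent_variation(123.18, 59.86)
#' percent_variation(13, 273)
#' @export
percent_variation <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("`a` and `b` must be numeric", call. = FALSE)
  }
  out <- 100 * (b - a) / a
  zero <- !is.na(a) & a == 0
  if (any(zero)) {
    warning("percent variation undefined for zero baseline; returning NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Full region x biennium summary table
#'
#' Runs the whole per-region pipeline: neonatal filtering, displacement
#' partition, OD aggregation, the two-level flow-weighted distance
#' \eqn{m_j}, displacement proportions and the health/access indicators,
#' joined into one row per health region x biennium (the machine-readable
#' analogue of the study's regional tables, and the panel for the trend
#' models). Region-biennium cells with zero displaced flow carry `NA` (not
#' zero) distance and same-region metrics.
#'
#' @param hospitalizations Raw hospitalization records (any infant age).
#' @inheritParams compute_indicators
#' @return A list: `summary` (region x biennium tibble), `od` (the displaced
#'   in-state OD table), `partition` (see [partition_displaced()]).
#' @export
build_region_summary <- function(hospitalizations, births, deaths, beds,
                                 registry, start_year = 2008L,
                                 n_biennia = 6L) {
  neo <- filter_neonatal(hospitalizations)
  part <- partition_displaced(neo, registry)
  od <- aggregate_od(part$displaced, start_year, n_biennia)

  disp <- pct_displaced(part, registry, start_year, n_biennia)
  ind <- compute_indicators(births, deaths, beds, registry,
                            start_year, n_biennia)
  out <- dplyr::left_join(
    ind, disp, by = c("region_id", "biennium_label", "biennium_index")
  )
  if (nrow(od)) {
    dist <- region_weighted_distance(origin_mean_edge(od, registry))
    same <- pct_same_region(od, registry)
    out <- dplyr::left_join(out, dist,
                            by = c("region_id", "biennium_label", "biennium_index"))
    out <- dplyr::left_join(out, same,
                            by = c("region_id", "biennium_label", "biennium_index"))
  } else {
    out$n_origins <- NA_integer_
    out$outflow <- NA_integer_
    out$weighted_distance_km <- NA_real_
    out$displaced_flow <- NA_integer_
    out$pct_same_region <- NA_real_
  }
  list(summary = out, od = od, partition = part)
}

#' Write the region x biennium summary as CSV
#'
#' @param summary The `summary` tibble from [build_region_summary()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_region_summary_csv <- function(summary, path) {
  stop_if_not_df_with(summary, c("region_id", "biennium_label"), "summary")
  readr::write_csv(summary, path)
  invisible(path)
}
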