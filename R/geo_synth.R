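#' Parameters for the synthetic state generator
#'
#' Bundles every knob of the synthetic geography and record generators into a
#' validated list. Defaults emulate a Parana-like state: 22 health regions
#' ("regionais de saude") grouped into 4 macroregions, one seat municipality
#' per region, twelve years of data grouped into six biennia (2008-2019),
#' neonatal admissions concentrated at region seats with gravity-style
#' distance decay, and vital-records attributes at configurable prevalences.
#'
#' `displacement_prob` is the probability that an admission occurs outside the
#' municipality of residence; `out_of_state_prob` is the probability, *given*
#' displacement, that the destination lies outside the state (the study data
#' keep roughly 1% of displaced admissions out of state). `seat_attraction`
#' multiplies the destination weight of region seats and `distance_decay` is
#' the exponent of the inverse-distance term, so displaced admissions flow
#' predominantly to the nearest regional pole.
#'
#' @param n_regions Number of health regions (default 22).
#' @param munis_per_region Municipalities per region, a single integer
#'   (default 18, giving 396 municipalities).
#' @param years Inclusive year range covered by the records (default
#'   `2008:2019`, i.e. six biennia).
#' @param admissions_per_muni_year Expected infant hospital admissions (ages
#'   0-364 days) per municipality-year.
#' @param p_neonatal_age Probability an admission is of a neonate (age 0-27
#'   days); the remainder get ages 28-364 so the neonatal filter has something
#'   to remove.
#' @param displacement_prob Probability an admission occurs outside the
#'   residence municipality.
#' @param seat_attraction Relative destination weight of region seats
#'   (>= 1; 1 removes the seat pull).
#' @param distance_decay Exponent of inverse seat-to-seat distance in the
#'   destination weights (> 0 concentrates flows on nearby destinations).
#' @param out_of_state_prob Probability, given displacement, that the
#'   destination is the [OUT_OF_STATE] sentinel.
#' @param births_per_muni_year Expected live births per municipality-year.
#' @param indicator_prevalences Named list of per-birth probabilities:
#'   `low_weight` (< 1,500 g), `ga_lt28` (gestational age < 28 weeks),
#'   `apgar5_le7` (5-minute Apgar <= 7), `maternal_35plus` (maternal age
#'   >= 35 years).
#' @param neonatal_death_rate Neonatal deaths (age 0-27 days) per 1,000 live
#'   births.
#' @param postneonatal_death_rate Post-neonatal infant deaths (28-364 days)
#'   per 1,000 live births; generated so the neonatal-death filter is
#'   exercised.
#' @param seat_bed_mean,nonseat_bed_mean Expected NICU beds (types I-III
#'   pooled) at seat / non-seat municipalities.
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return A list of class `synth_params`.
#' @seealso [generate_state()] for the one-call generator.
#' @export
synth_params <- function(n_regions = 22L,
                         munis_per_region = 18L,
                         years = 2008:2019,
                         admissions_per_muni_year = 50,
                         p_neonatal_age = 0.8,
                         displacement_prob = 0.39,
                         seat_attraction = 500,
                         distance_decay = 2.5,
                         out_of_state_prob = 0.01,
                         births_per_muni_year = 380,
                         indicator_prevalences = list(
                           low_weight = 0.0125,
                           ga_lt28 = 0.0048,
                           apgar5_le7 = 0.02,
                           maternal_35plus = 0.129
                         ),
                         neonatal_death_rate = 8.2,
                         postneonatal_death_rate = 2.5,
                         seat_bed_mean = 30,
                         nonseat_bed_mean = 0.2,
                         seed = 1L) {
  if (!is.numeric(n_regions) || n_regions < 1) {
    stop("`n_regions` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(munis_per_region) || munis_per_region < 1) {
    stop("`munis_per_region` must be >= 1", call. = FALSE)
  }
  if (munis_per_region > 99) {
    stop("`munis_per_region` must be <= 99 (6-digit code space)", call. = FALSE)
  }
  if (!is.numeric(years) || length(years) < 1 || any(years != as.integer(years))) {
    stop("`years` must be a vector of integer years", call. = FALSE)
  }
  check_probability(p_neonatal_age, "p_neonatal_age")
  check_probability(displacement_prob, "displacement_prob")
  check_probability(out_of_state_prob, "out_of_state_prob")
  check_nonnegative(admissions_per_muni_year, "admissions_per_muni_year")
  check_nonnegative(births_per_muni_year, "births_per_muni_year")
  check_nonnegative(seat_attraction, "seat_attraction")
  check_nonnegative(distance_decay, "distance_decay")
  check_nonnegative(neonatal_death_rate, "neonatal_death_rate")
  check_nonnegative(postneonatal_death_rate, "postneonatal_death_rate")
  check_nonnegative(seat_bed_mean, "seat_bed_mean")
  check_nonnegative(nonseat_bed_mean, "nonseat_bed_mean")
  needed <- c("low_weight", "ga_lt28", "apgar5_le7", "maternal_35plus")
  if (!is.list(indicator_prevalences) ||
      !all(needed %in% names(indicator_prevalences))) {
    stop("`indicator_prevalences` must name: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  for (nm in needed) check_probability(indicator_prevalences[[nm]], nm)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31 - 16) {
    stop("`seed` must be a single integer below 2^31 - 16", call. = FALSE)
  }

  structure(list(
    n_regions = as.integer(n_regions),
    munis_per_region = as.integer(munis_per_region),
    years = as.integer(sort(years)),
    admissions_per_muni_year = admissions_per_muni_year,
    p_neonatal_age = p_neonatal_age,
    displacement_prob = displacement_prob,
    seat_attraction = seat_attraction,
    distance_decay = distance_decay,
    out_of_state_prob = out_of_state_prob,
    births_per_muni_year = births_per_muni_year,
    indicator_prevalences = indicator_prevalences[needed],
    neonatal_death_rate = neonatal_death_rate,
    postneonatal_death_rate = postneonatal_death_rate,
    seat_bed_mean = seat_bed_mean,
    nonseat_bed_mean = nonseat_bed_mean,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# Split n regions into the 4 macroregions as evenly as possible, in the fixed
# order leste, oeste, noroeste, norte (leste gets the remainder first, like
# the 7/5/5/5 split of the 22 real regions).
macroregion_assignment <- function(n_regions) {
  macros <- c("leste", "oeste", "noroeste", "norte")
  sizes <- rep(n_regions %/% 4L, 4L)
  extra <- n_regions %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(macros, times = sizes)[seq_len(n_regions)]
}

#' Generate a synthetic municipality registry
#'
#' Lays the state out on a rectangular lattice: the four macroregions occupy
#' the quadrants of a bounding box roughly 600 x 440 km, each macroregion's
#' health regions tile its quadrant, and each region's municipalities sit on a
#' jittered grid inside the region patch with the region seat at the patch
#' centre. This reproduces the "regions within macroregions" adjacency
#' structure (and realistic within/between-region distances of tens to a
#' couple of hundred km) without real shapefiles.
#'
#' @param params A [synth_params()] object.
#' @return A tibble with one row per municipality: `code` (6-digit integer),
#'   `name`, `region_id` (1..n_regions), `macroregion`, `seat_lat`,
#'   `seat_lon` (degrees; the municipal seat location) and `is_region_seat`.
#' @examples
#' reg <- generate_registry(synth_params(n_regions = 4, munis_per_region = 3))
#' table(reg$macroregion)
#' @export
generate_registry <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, {
    n_regions <- params$n_regions
    mpr <- params$munis_per_region
    macro_of_region <- macroregion_assignment(n_regions)

    # bounding box (degrees); ~6 x 4 degrees at latitude -25
    lon_rng <- c(-54.5, -48.5)
    lat_rng <- c(-26.5, -22.5)
    macro_box <- list( # quadrants: leste E, oeste W, noroeste NW, norte NE
      leste    = list(lon = c(mean(lon_rng), lon_rng[2]), lat = c(lat_rng[1], mean(lat_rng))),
      oeste    = list(lon = c(lon_rng[1], mean(lon_rng)), lat = c(lat_rng[1], mean(lat_rng))),
      noroeste = list(lon = c(lon_rng[1], mean(lon_rng)), lat = c(mean(lat_rng), lat_rng[2])),
      norte    = list(lon = c(mean(lon_rng), lon_rng[2]), lat = c(mean(lat_rng), lat_rng[2]))
    )

    rows <- vector("list", n_regions)
    for (macro in unique(macro_of_region)) {
      ids <- which(macro_of_region == macro)
      k <- length(ids)
      ncol_ <- ceiling(sqrt(k))
      nrow_ <- ceiling(k / ncol_)
      box <- macro_box[[macro]]
      for (pos in seq_along(ids)) {
        j <- ids[pos]
        ci <- (pos - 1L) %% ncol_
        ri <- (pos - 1L) %/% ncol_
        patch_lon <- box$lon[1] + diff(box$lon) * c(ci, ci + 1) / ncol_
        patch_lat <- box$lat[1] + diff(box$lat) * c(ri, ri + 1) / nrow_

        # municipalities on a jittered grid inside the patch; seat at centre
        g <- ceiling(sqrt(mpr))
        cell <- expand.grid(x = seq_len(g), y = seq_len(g))[seq_len(mpr), , drop = FALSE]
        fx <- (cell$x - 0.5) / g + runif(mpr, -0.3, 0.3) / g
        fy <- (cell$y - 0.5) / g + runif(mpr, -0.3, 0.3) / g
        lon <- patch_lon[1] + diff(patch_lon) * pmin(pmax(fx, 0.02), 0.98)
        lat <- patch_lat[1] + diff(patch_lat) * pmin(pmax(fy, 0.02), 0.98)
        lon[1] <- mean(patch_lon) # seat centrally placed
        lat[1] <- mean(patch_lat)

        rows[[j]] <- tibble::tibble(
          code = 400000L + j * 1000L + seq_len(mpr),
          name = c(sprintf("Sede %02d", j),
                   sprintf("Municipio %02d-%02d", j, seq_len(mpr))[-1]),
          region_id = j,
          macroregion = macro,
          seat_lat = lat,
          seat_lon = lon,
          is_region_seat = seq_len(mpr) == 1L
        )
      }
    }
    registry <- dplyr::bind_rows(rows)

    # guarantee distinct coordinates (grid + jitter collisions are only
    # possible in degenerate configurations, but the invariant is hard)
    dup <- duplicated(registry[, c("seat_lat", "seat_lon")])
    while (any(dup)) {
      registry$seat_lat[dup] <- registry$seat_lat[dup] + runif(sum(dup), 1e-4, 2e-4)
      dup <- duplicated(registry[, c("seat_lat", "seat_lon")])
    }
    registry
  })
}

check_registry <- function(registry) {
  stop_if_not_df_with(
    registry,
    c("code", "region_id", "macroregion", "seat_lat", "seat_lon", "is_region_seat"),
    "registry"
  )
  if (anyDuplicated(registry$code)) {
    stop("registry codes must be unique", call. = FALSE)
  }
  if (any(registry$code == OUT_OF_STATE)) {
    stop("registry must not contain the OUT_OF_STATE sentinel code", call. = FALSE)
  }
  seats <- tapply(registry$is_region_seat, registry$region_id, sum)
  if (any(seats != 1L)) {
    stop("each region must have exactly one seat municipality", call. = FALSE)
  }
  invisible(registry)
}

# Pairwise haversine distance matrix (km) between all municipality seats.
seat_distance_matrix <- function(registry) {
  p <- cbind(registry$seat_lon, registry$seat_lat)
  n <- nrow(p)
  m <- matrix(0, n, n, dimnames = list(registry$code, registry$code))
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(p[i, , drop = FALSE], p, r = 6371)
  }
  m
}

#' Generate synthetic hospitalization records
#'
#' Draws per municipality-year admission counts (Poisson), ages with a
#' configurable mass on days 0-27 and a tail up to 364 days, and destinations:
#' with probability `displacement_prob` the admission occurs outside the
#' residence municipality; displaced destinations go out of state (sentinel
#' [OUT_OF_STATE]) with probability `out_of_state_prob`, otherwise they are
#' drawn among the other municipalities with weight
#' `seat_attraction^is_seat * distance^(-distance_decay)` — a gravity pull
#' towards nearby regional poles.
#'
#' @param registry Municipality registry from [generate_registry()].
#' @param params A [synth_params()] object.
#' @return A tibble with columns `residence_code`, `occurrence_code`, `year`,
#'   `age_days`, one row per admission.
#' @export
generate_hospitalizations <- function(registry, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  check_registry(registry)
  if (nrow(registry) == 0L) stop("registry is empty", call. = FALSE)

  withr::with_seed(params$seed + 1L, {
    n_muni <- nrow(registry)
    n_years <- length(params$years)
    counts <- rpois(n_muni * n_years, params$admissions_per_muni_year)
    residence <- rep(rep(registry$code, times = n_years), times = counts)
    year <- rep(rep(params$years, each = n_muni), times = counts)
    n <- length(residence)

    neon <- runif(n) < params$p_neonatal_age
    age <- integer(n)
    age[neon] <- sample(0:27, sum(neon), replace = TRUE)
    age[!neon] <- sample(28:364, sum(!neon), replace = TRUE)

    occurrence <- residence
    displaced <- runif(n) < params$displacement_prob
    oos <- displaced & (runif(n) < params$out_of_state_prob)
    occurrence[oos] <- OUT_OF_STATE

    instate_disp <- displaced & !oos
    if (any(instate_disp) && n_muni > 1L) {
      dm <- seat_distance_matrix(registry)
      seat_w <- ifelse(registry$is_region_seat, params$seat_attraction, 1)
      idx_of <- setNames(seq_len(n_muni), registry$code)
      for (i in seq_len(n_muni)) {
        sel <- which(instate_disp & residence == registry$code[i])
        if (!length(sel)) next
        d <- dm[i, ]
        w <- seat_w * d^(-params$distance_decay)
        w[i] <- 0 # destination must differ from residence
        occurrence[sel] <- registry$code[
          sample.int(n_muni, length(sel), replace = TRUE, prob = w)
        ]
      }
    } else if (any(instate_disp)) {
      # single-municipality registry: displacement impossible in state
      occurrence[instate_disp] <- residence[instate_disp]
    }

    tibble::tibble(
      residence_code = residence,
      occurrence_code = occurrence,
      year = year,
      age_days = age
    )
  })
}

#' Generate synthetic live-birth and infant-death records
#'
#' Live births are drawn per municipality-year (Poisson) with independent
#' Bernoulli indicators at the configured prevalences for very low birth
#' weight (< 1,500 g), gestational age < 28 weeks, 5-minute Apgar <= 7 and
#' maternal age >= 35 years; continuous attributes are then drawn consistent
#' with each indicator. Neonatal deaths (age at death 0-27 days) arise at
#' `neonatal_death_rate` per 1,000 births and post-neonatal infant deaths
#' (28-364 days) at `postneonatal_death_rate` per 1,000.
#'
#' @inheritParams generate_hospitalizations
#' @return A list with tibbles `births` (`residence_code`, `year`,
#'   `birth_weight_g`, `gestational_age_weeks`, `apgar5`,
#'   `maternal_age_years`) and `deaths` (`residence_code`, `year`,
#'   `age_at_death_days`).
#' @export
generate_vital_records <- function(registry, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  check_registry(registry)
  if (nrow(registry) == 0L) stop("registry is empty", call. = FALSE)

  withr::with_seed(params$seed + 2L, {
    n_muni <- nrow(registry)
    n_years <- length(params$years)
    counts <- rpois(n_muni * n_years, params$births_per_muni_year)
    residence <- rep(rep(registry$code, times = n_years), times = counts)
    year <- rep(rep(params$years, each = n_muni), times = counts)
    n <- length(residence)
    prev <- params$indicator_prevalences

    low_w <- runif(n) < prev$low_weight
    weight <- numeric(n)
    weight[low_w] <- runif(sum(low_w), 500, 1499)
    weight[!low_w] <- pmax(1500, rnorm(sum(!low_w), 3200, 450))

    ga28 <- runif(n) < prev$ga_lt28
    ga <- numeric(n)
    ga[ga28] <- sample(22:27, sum(ga28), replace = TRUE)
    ga[!ga28] <- pmin(pmax(round(rnorm(sum(!ga28), 39, 1.8)), 28), 43)

    ap_low <- runif(n) < prev$apgar5_le7
    apgar <- integer(n)
    apgar[ap_low] <- sample(0:7, sum(ap_low), replace = TRUE)
    apgar[!ap_low] <- sample(8:10, sum(!ap_low), replace = TRUE,
                             prob = c(0.1, 0.45, 0.45))

    m35 <- runif(n) < prev$maternal_35plus
    mage <- integer(n)
    mage[m35] <- sample(35:45, sum(m35), replace = TRUE)
    mage[!m35] <- sample(15:34, sum(!m35), replace = TRUE)

    births <- tibble::tibble(
      residence_code = residence,
      year = year,
      birth_weight_g = weight,
      gestational_age_weeks = ga,
      apgar5 = apgar,
      maternal_age_years = mage
    )

    is_neo_death <- runif(n) < params$neonatal_death_rate / 1000
    is_post_death <- !is_neo_death &
      runif(n) < params$postneonatal_death_rate / 1000
    n_neo <- sum(is_neo_death)
    n_post <- sum(is_post_death)
    deaths <- tibble::tibble(
      residence_code = c(residence[is_neo_death], residence[is_post_death]),
      year = c(year[is_neo_death], year[is_post_death]),
      age_at_death_days = c(
        sample(0:27, n_neo, replace = TRUE,
               prob = 0.75^(0:27)), # early-neonatal concentration
        sample(28:364, n_post, replace = TRUE)
      )
    )

    list(births = births, deaths = deaths)
  })
}

#' Generate synthetic NICU bed counts
#'
#' Pooled type I-III NICU beds are concentrated at region seats: each
#' municipality draws a Poisson base count (mean `seat_bed_mean` at seats,
#' `nonseat_bed_mean` elsewhere) held constant across the configured years.
#'
#' @inheritParams generate_hospitalizations
#' @return A tibble with columns `municipality_code`, `year`, `nicu_beds`.
#' @export
generate_bed_counts <- function(registry, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  check_registry(registry)
  if (nrow(registry) == 0L) stop("registry is empty", call. = FALSE)

  withr::with_seed(params$seed + 3L, {
    base <- rpois(
      nrow(registry),
      ifelse(registry$is_region_seat, params$seat_bed_mean, params$nonseat_bed_mean)
    )
    tibble::tibble(
      municipality_code = rep(registry$code, times = length(params$years)),
      year = rep(params$years, each = nrow(registry)),
      nicu_beds = rep(base, times = length(params$years))
    )
  })
}

#' Generate a full synthetic state in one call
#'
#' @inheritParams generate_registry
#' @return A list with elements `registry`, `hospitalizations`, `births`,
#'   `deaths`, `beds` and the `params` used.
#' @examples
#' st <- generate_state(synth_params(n_regions = 4, munis_per_region = 4,
#'                                   admissions_per_muni_year = 5,
#'                                   births_per_muni_year = 20))
#' sapply(st[c("registry", "hospitalizations", "births")], nrow)
#' @export
generate_state <- function(params = synth_params()) {
  registry <- generate_registry(params)
  vit <- generate_vital_records(registry, params)
  list(
    registry = registry,
    hospitalizations = generate_hospitalizations(registry, params),
    births = vit$births,
    deaths = vit$deaths,
    beds = generate_bed_counts(registry, params),
    params = params
  )
}

#' Write the synthetic tables as CSV files
#'
#' Writes `registry.csv`, `hospitalizations.csv`, `births.csv`, `deaths.csv`
#' and `beds.csv` (UTF-8, comma-separated, "." decimal, header row) into
#' `dir`.
#'
#' @param state A list as returned by [generate_state()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synth_tables <- function(state, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("registry", "hospitalizations", "births", "deaths", "beds")
  paths <- file.path(dir, paste0(tabs, ".csv"))
  for (i in seq_along(tabs)) {
    readr::write_csv(state[[tabs[i]]], paths[i])
  }
  invisible(setNames(paths, tabs))
}

#' Export the municipality registry as GeoJSON points
#'
#' One Point feature per municipality at its seat coordinates, with the
#' registry columns as feature properties.
#'
#' @param registry Municipality registry.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
registry_to_geojson <- function(registry, path) {
  check_registry(registry)
  features <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(r$seat_lon, r$seat_lat)
      ),
      properties = list(
        code = r$code, name = r$name, region_id = r$region_id,
        macroregion = r$macroregion, is_region_seat = r$is_region_seat
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
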