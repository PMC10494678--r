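test_that("great-circle distance matches an independent haversine oracle", {
  withr::with_seed(21L, {
    lat1 <- runif(200, -60, 60); lon1 <- runif(200, -180, 180)
    lat2 <- runif(200, -60, 60); lon2 <- runif(200, -180, 180)
  })
  got <- great_circle_km(lat1, lon1, lat2, lon2)
  want <- oracle_haversine_km(lat1, lon1, lat2, lon2)
  expect_equal(got, want, tolerance = 1e-9)
  # identity and symmetry
  expect_equal(great_circle_km(lat1, lon1, lat1, lon1), rep(0, 200))
  expect_equal(great_circle_km(lat2, lon2, lat1, lon1), got, tolerance = 1e-12)
  expect_true(all(got >= 0))
  expect_error(great_circle_km(91, 0, 0, 0), "latitude")
  expect_error(great_circle_km(0, 181, 0, 0), "longitude")
})

test_that("mean outgoing edge is the flow-weighted mean of pair distances", {
  # registry on one meridian: seat-to-seat distances are exactly 10 and 20 km
  reg <- manual_registry(
    codes = c(100001, 100002, 100003),
    region = c(1, 1, 1),
    lat = c(0, deg_for_km(10), deg_for_km(20)),
    lon = c(0, 0, 0)
  )
  od <- tibble::tibble(
    origin_code = 100001L, destination_code = c(100002L, 100003L),
    biennium_label = "2008-2009", biennium_index = 1L, flow = c(1L, 3L)
  )
  s <- origin_mean_edge(od, reg)
  expect_equal(s$mean_edge_km, 17.5, tolerance = 1e-9)
  expect_equal(s$outflow, 4L)

  # single destination: d_i equals that distance whatever the flow
  s1 <- origin_mean_edge(od[2, ], reg)
  expect_equal(s1$mean_edge_km, 20, tolerance = 1e-9)

  expect_error(origin_mean_edge(od[0, ], reg), "no OD pairs")
})

test_that("per-origin mean edge equals the brute-force record-level mean", {
  reg <- generate_registry(small_params())
  for (seed in 1:10) {
    od <- random_od(reg, 50, seed = seed)
    s <- origin_mean_edge(od, reg)
    recs <- od_to_records(od)
    aug <- neonet:::od_augment(aggregate_od(recs), reg)
    # expand to unit records and average per origin x biennium
    unit <- tibble::tibble(
      origin = rep(aug$origin_code, aug$flow),
      bi = rep(aug$biennium_index, aug$flow),
      d = rep(aug$dist_km, aug$flow)
    )
    brute <- tapply(unit$d, paste(unit$origin, unit$bi), mean)
    expect_equal(as.numeric(brute[paste(s$origin_code, s$biennium_index)]),
                 s$mean_edge_km, tolerance = 1e-9)
  }
})

test_that("regional weighted distance reduces correctly in simple cases", {
  summaries <- tibble::tibble(
    region_id = 1L, biennium_label = "2008-2009", biennium_index = 1L,
    origin_code = c(1L, 2L), outflow = c(2L, 2L), mean_edge_km = c(10, 30)
  )
  m <- region_weighted_distance(summaries)
  expect_equal(m$weighted_distance_km, 20)
  expect_equal(m$n_origins, 2L)

  one <- region_weighted_distance(summaries[1, ])
  expect_equal(one$weighted_distance_km, 10)
  expect_error(region_weighted_distance(summaries[0, ]), "zero displaced flow")
})

test_that("two-level weighted distance equals the single-pass record-level mean", {
  reg <- generate_registry(small_params())
  for (seed in 11:20) {
    od <- random_od(reg, 80, seed = seed)
    m <- region_weighted_distance(origin_mean_edge(od, reg))
    aug <- neonet:::od_augment(od, reg)
    for (i in seq_len(nrow(m))) {
      sel <- aug$origin_region == m$region_id[i] &
        aug$biennium_index == m$biennium_index[i]
      brute <- weighted.mean(aug$dist_km[sel], aug$flow[sel])
      expect_equal(m$weighted_distance_km[i], brute, tolerance = 1e-9)
      # bounds: within [min, max] of underlying pair distances
      expect_gte(m$weighted_distance_km[i], min(aug$dist_km[sel]))
      expect_lte(m$weighted_distance_km[i], max(aug$dist_km[sel]))
    }
  }
})

test_that("distance metrics and same-region share are flow-scale equivariant", {
  reg <- generate_registry(small_params())
  od <- random_od(reg, 60, seed = 31L)
  od7 <- dplyr::mutate(od, flow = flow * 7L)
  expect_equal(origin_mean_edge(od, reg)$mean_edge_km,
               origin_mean_edge(od7, reg)$mean_edge_km, tolerance = 1e-12)
  expect_equal(region_weighted_distance(origin_mean_edge(od, reg))$weighted_distance_km,
               region_weighted_distance(origin_mean_edge(od7, reg))$weighted_distance_km,
               tolerance = 1e-12)
  expect_equal(pct_same_region(od, reg)$pct_same_region,
               pct_same_region(od7, reg)$pct_same_region, tolerance = 1e-12)
})

test_that("share of admissions outside the residence municipality is recounted", {
  reg <- generate_registry(small_params())
  all_disp <- tibble::tibble(
    residence_code = reg$code[1], occurrence_code = reg$code[2],
    year = 2008L, age_days = 0L
  )
  part_all <- partition_displaced(all_disp, reg)
  expect_equal(pct_displaced(part_all, reg)$pct_displaced, 100)

  none_disp <- dplyr::mutate(all_disp, occurrence_code = residence_code)
  part_none <- partition_displaced(none_disp, reg)
  expect_equal(pct_displaced(part_none, reg)$pct_displaced, 0)

  # brute-force recount on synthetic data
  p <- small_params(admissions_per_muni_year = 100, seed = 3L)
  h <- filter_neonatal(generate_hospitalizations(generate_registry(p), p))
  part <- partition_displaced(h, generate_registry(p))
  got <- pct_displaced(part, reg)
  region_of <- setNames(reg$region_id, reg$code)
  instate <- h[h$occurrence_code != OUT_OF_STATE, ]
  for (i in seq_len(nrow(got))) {
    bi <- assign_biennium(instate$year)$index
    sel <- region_of[as.character(instate$residence_code)] == got$region_id[i] &
      bi == got$biennium_index[i]
    brute <- 100 * mean(instate$occurrence_code[sel] != instate$residence_code[sel])
    expect_equal(got$pct_displaced[i], brute)
  }
  expect_true(all(got$pct_displaced >= 0 & got$pct_displaced <= 100))
})

test_that("same-region share uses displaced flow as denominator", {
  reg <- manual_registry(
    codes = c(1, 2, 3, 4),
    region = c(1, 1, 2, 2),
    lat = c(0, deg_for_km(5), deg_for_km(50), deg_for_km(55)),
    lon = rep(0, 4)
  )
  inside <- tibble::tibble(origin_code = 1L, destination_code = 2L,
                           biennium_label = "2008-2009", biennium_index = 1L,
                           flow = 5L)
  expect_equal(pct_same_region(inside, reg)$pct_same_region, 100)
  outside <- dplyr::mutate(inside, destination_code = 3L)
  expect_equal(pct_same_region(outside, reg)$pct_same_region, 0)

  mixed <- dplyr::bind_rows(inside, outside)
  expect_equal(pct_same_region(mixed, reg)$pct_same_region, 50)

  # brute force on random flows
  regs <- generate_registry(small_params())
  od <- random_od(regs, 70, seed = 17L)
  aug <- neonet:::od_augment(od, regs)
  got <- pct_same_region(od, regs)
  for (i in seq_len(nrow(got))) {
    sel <- aug$origin_region == got$region_id[i] &
      aug$biennium_index == got$biennium_index[i]
    brute <- 100 * sum(aug$flow[sel & aug$destination_region == aug$origin_region]) /
      sum(aug$flow[sel])
    expect_equal(got$pct_same_region[i], brute)
  }
})

test_that("regional indicators follow their per-1,000 and percentage definitions", {
  reg <- manual_registry(codes = c(1, 2), region = c(1, 1),
                         lat = c(0, 1), lon = c(0, 1))
  births <- tibble::tibble(
    residence_code = 1L, year = 2008L,
    birth_weight_g = 3000, gestational_age_weeks = 39,
    apgar5 = 9L, maternal_age_years = 25L
  )[rep(1, 1000), ]
  deaths <- tibble::tibble(residence_code = 1L, year = 2008L,
                           age_at_death_days = 5L)
  beds <- tibble::tibble(municipality_code = integer(), year = integer(),
                         nicu_beds = integer())
  ind <- compute_indicators(births, deaths, beds, reg)
  row1 <- ind[ind$biennium_index == 1L, ]
  expect_equal(row1$tmn, 1.0)
  expect_equal(row1$pct_apgar5_le7, 0)
  expect_equal(row1$pct_low_weight, 0)
  # biennia without births are missing, not zero
  expect_true(all(is.na(ind$tmn[ind$biennium_index > 1L])))

  # a post-neonatal death does not enter the TMN numerator
  deaths2 <- tibble::tibble(residence_code = 1L, year = 2008L,
                            age_at_death_days = c(5L, 40L))
  expect_equal(compute_indicators(births, deaths2, beds, reg)$tmn[1], 1.0)

  # NICU beds averaged over the biennium's two years, per 1,000 births
  beds2 <- tibble::tibble(municipality_code = 1L, year = c(2008L, 2009L),
                          nicu_beds = c(2L, 4L))
  expect_equal(compute_indicators(births, deaths, beds2, reg)$nicu_beds_per_1000[1],
               1000 * 3 / 1000)
})

test_that("synthetic cohorts recover the configured prevalences in the summary", {
  p <- synth_params(n_regions = 2, munis_per_region = 4,
                    births_per_muni_year = 600, admissions_per_muni_year = 30,
                    seed = 19L)
  st <- generate_state(p)
  res <- build_region_summary(st$hospitalizations, st$births, st$deaths,
                              st$beds, st$registry)
  s <- res$summary
  n <- sum(s$n_births)
  pooled <- function(col) sum(s[[col]] / 100 * s$n_births) / n
  for (chk in list(c("pct_apgar5_le7", p$indicator_prevalences$apgar5_le7),
                   c("pct_low_weight", p$indicator_prevalences$low_weight),
                   c("pct_maternal_35plus", p$indicator_prevalences$maternal_35plus))) {
    prob <- as.numeric(chk[2])
    se <- sqrt(prob * (1 - prob) / n)
    expect_lt(abs(pooled(chk[1]) - prob), 3 * se)
  }
  expect_true(all(s$pct_displaced >= 0 & s$pct_displaced <= 100))
  expect_true(all(s$pct_same_region >= 0 & s$pct_same_region <= 100, na.rm = TRUE))
  expect_true(all(s$tmn >= 0, na.rm = TRUE))
})

test_that("percent variation follows 100 (B - A) / A", {
  expect_equal(percent_variation(123.18, 59.86), -51.40, tolerance = 1e-4)
  expect_equal(percent_variation(13, 273), 2000)
  expect_equal(percent_variation(5, 5), 0)
  expect_warning(out <- percent_variation(0, 3), "zero baseline")
  expect_true(is.na(out))
  # sign matches sign of (B - A) for positive baselines
  withr::with_seed(2L, {
    a <- runif(100, 0.1, 50); b <- runif(100, 0.1, 50)
  })
  expect_equal(sign(percent_variation(a, b)), sign(b - a))
  expect_error(percent_variation("a", 1), "numeric")
})
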