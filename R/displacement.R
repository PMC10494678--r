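#' Normalize municipality codes to 6 digits
#'
#' Administrative hospitalization tables sometimes carry 7-digit municipality
#' codes (6 digits plus a check digit); registries use 6 digits. 7-digit
#' codes are accepted and the trailing check digit is dropped; 6-digit codes
#' (including the [OUT_OF_STATE] sentinel) pass through unchanged.
#'
#' @param code Integer vector of municipality codes.
#' @return Integer vector of 6-digit codes.
#' @examples
#' normalize_muni_code(c(410690L, 4106902L))
#' @export
normalize_muni_code <- function(code) {
  if (!is.numeric(code)) stop("`code` must be numeric", call. = FALSE)
  code <- as.integer(code)
  seven <- !is.na(code) & code >= 1000000L
  code[seven] <- code[seven] %/% 10L
  code
}

#' Keep only neonatal-period admissions
#'
#' Selects admissions of children aged 0 to 27 days (the neonatal period),
#' the closed age window that defines the study population. Input order is
#' preserved.
#'
#' @param records Hospitalization records with an `age_days` column.
#' @return The records with `0 <= age_days <= 27`.
#' @examples
#' recs <- tibble::tibble(residence_code = 1, occurrence_code = 1,
#'                        year = 2008, age_days = c(0, 27, 28, 365))
#' filter_neonatal(recs)$age_days
#' @export
filter_neonatal <- function(records) {
  stop_if_not_df_with(records, "age_days", "records")
  if (anyNA(records$age_days) || any(records$age_days < 0)) {
    stop("`age_days` must be present and non-negative for every record",
         call. = FALSE)
  }
  records[records$age_days <= 27, , drop = FALSE]
}

#' Partition neonatal admissions by displacement status
#'
#' Splits admission records into three disjoint, exhaustive groups:
#' `same_municipality` (occurrence equals residence), `displaced` (occurrence
#' is another in-state municipality) and `out_of_state` (occurrence is the
#' [OUT_OF_STATE] sentinel). Out-of-state admissions are excluded from all
#' distance, proportion and network metrics downstream, but their share of
#' all displaced admissions (in-state displaced + out-of-state) is reported
#' here — in the study data it is roughly 1%.
#'
#' @param records Hospitalization records (`residence_code`,
#'   `occurrence_code`, `year`, `age_days`), typically already passed through
#'   [filter_neonatal()].
#' @param registry Municipality registry; destination codes must be present
#'   in it or be the sentinel.
#' @return A list with tibbles `same_municipality`, `displaced`,
#'   `out_of_state` and the scalar `out_of_state_share` (proportion of
#'   displaced admissions, in 0-1; `NaN` when nothing is displaced).
#' @export
partition_displaced <- function(records, registry) {
  stop_if_not_df_with(records, c("residence_code", "occurrence_code"), "records")
  check_registry(registry)
  records$residence_code <- normalize_muni_code(records$residence_code)
  records$occurrence_code <- normalize_muni_code(records$occurrence_code)

  is_oos <- records$occurrence_code == OUT_OF_STATE
  unknown <- !is_oos & !(records$occurrence_code %in% registry$code)
  if (any(unknown)) {
    stop(sprintf(
      "%d record(s) have occurrence codes absent from the registry (and not the out-of-state sentinel), e.g. %s",
      sum(unknown), records$occurrence_code[which(unknown)[1]]
    ), call. = FALSE)
  }
  if (any(!(records$residence_code %in% registry$code))) {
    stop("some residence codes are absent from the registry", call. = FALSE)
  }

  same <- !is_oos & records$occurrence_code == records$residence_code
  displaced <- !is_oos & !same
  list(
    same_municipality = records[same, , drop = FALSE],
    displaced = records[displaced, , drop = FALSE],
    out_of_state = records[is_oos, , drop = FALSE],
    out_of_state_share = sum(is_oos) / (sum(is_oos) + sum(displaced))
  )
}

#' Map an admission year to its biennium
#'
#' The study period 2008-2019 is grouped into six biennia, 2008-2009 (index
#' 1) through 2018-2019 (index 6). The biennium is derived from the admission
#' year alone.
#'
#' @param year Integer vector of years.
#' @param start_year First year of the first biennium (default 2008).
#' @param n_biennia Number of biennia covered (default 6).
#' @return A tibble with columns `label` ("YYYY-YYYY") and `index` (1-based),
#'   one row per input year.
#' @examples
#' assign_biennium(c(2008, 2019))
#' @export
assign_biennium <- function(year, start_year = 2008L, n_biennia = 6L) {
  if (!is.numeric(year) || anyNA(year) || any(year != as.integer(year))) {
    stop("`year` must be integer-valued", call. = FALSE)
  }
  last <- start_year + 2L * n_biennia - 1L
  if (any(year < start_year | year > last)) {
    stop(sprintf("year outside the covered range %d-%d", start_year, last),
         call. = FALSE)
  }
  index <- (as.integer(year) - start_year) %/% 2L + 1L
  first <- start_year + 2L * (index - 1L)
  tibble::tibble(label = sprintf("%d-%d", first, first + 1L), index = index)
}

#' All biennium labels of the covered period
#'
#' @inheritParams assign_biennium
#' @return Character vector of the `n_biennia` labels in order.
#' @export
biennium_labels <- function(start_year = 2008L, n_biennia = 6L) {
  first <- start_year + 2L * (seq_len(n_biennia) - 1L)
  sprintf("%d-%d", first, first + 1L)
}

#' Aggregate displaced admissions into an origin-destination table
#'
#' Each distinct (origin municipality, destination municipality, biennium)
#' triple is one displacement, with flow equal to the number of admission
#' rows it groups. Input records must all be displaced and in state (use
#' [partition_displaced()] first).
#'
#' @param records Displaced in-state hospitalization records.
#' @inheritParams assign_biennium
#' @return A tibble with columns `origin_code`, `destination_code`,
#'   `biennium_label`, `biennium_index`, `flow`, one row per distinct pair
#'   and biennium; flows sum to `nrow(records)`.
#' @export
aggregate_od <- function(records, start_year = 2008L, n_biennia = 6L) {
  stop_if_not_df_with(records, c("residence_code", "occurrence_code", "year"),
                      "records")
  if (nrow(records) == 0L) {
    return(tibble::tibble(
      origin_code = integer(), destination_code = integer(),
      biennium_label = character(), biennium_index = integer(),
      flow = integer()
    ))
  }
  records$residence_code <- normalize_muni_code(records$residence_code)
  records$occurrence_code <- normalize_muni_code(records$occurrence_code)
  if (any(records$occurrence_code == OUT_OF_STATE)) {
    stop("out-of-state records must be excluded before OD aggregation",
         call. = FALSE)
  }
  if (any(records$occurrence_code == records$residence_code)) {
    stop("records occurring in the residence municipality are not displacements",
         call. = FALSE)
  }
  bi <- assign_biennium(records$year, start_year, n_biennia)
  records$biennium_label <- bi$label
  records$biennium_index <- bi$index
  dplyr::count(
    records,
    origin_code = .data$residence_code,
    destination_code = .data$occurrence_code,
    .data$biennium_label, .data$biennium_index,
    name = "flow"
  )
}

#' Write / read an origin-destination table as CSV
#'
#' Flat schema: `origin_code,destination_code,biennium_label,biennium_index,flow`.
#'
#' @param od An OD tibble from [aggregate_od()].
#' @param path File path.
#' @return `write_od_csv()` returns `path` invisibly; `read_od_csv()` returns
#'   the OD tibble.
#' @export
write_od_csv <- function(od, path) {
  stop_if_not_df_with(od, c("origin_code", "destination_code",
                            "biennium_label", "flow"), "od")
  readr::write_csv(od, path)
  invisible(path)
}

#' @rdname write_od_csv
#' @export
read_od_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    origin_code = readr::col_integer(),
    destination_code = readr::col_integer(),
    biennium_label = readr::col_character(),
    biennium_index = readr::col_integer(),
    flow = readr::col_integer()
  ))
}
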