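#' Simulate a region x biennium panel from the random-intercept model
#'
#' Draws responses from
#' \deqn{y_{jt} = \beta_0 + \beta_1 t + u_j + \varepsilon_{jt},\qquad
#'       u_j \sim N(0, \tau^2),\ \varepsilon_{jt} \sim N(0, \sigma^2),}
#' with units \eqn{j = 1..n_{units}} (health regions) and times
#' \eqn{t = 1..n_{times}} (biennia). This is the parameter-recovery harness
#' for [fit_trend()] and [fit_tmn_model()].
#'
#' @param beta Length-2 numeric: intercept \eqn{\beta_0} and biennium slope
#'   \eqn{\beta_1}.
#' @param tau Random-intercept SD \eqn{\tau \ge 0}.
#' @param sigma Residual SD \eqn{\sigma \ge 0}.
#' @param n_units,n_times Panel dimensions (defaults 22 regions x 6 biennia,
#'   a 132-row panel).
#' @param seed Integer seed.
#' @return A tibble with columns `region_id`, `biennium_index`, `response`.
#' @export
simulate_panel <- function(beta = c(9.25, -0.35), tau = 0.94, sigma = 1.34,
                           n_units = 22L, n_times = 6L, seed = 1L) {
  if (length(beta) != 2L || !is.numeric(beta)) {
    stop("`beta` must be c(intercept, slope)", call. = FALSE)
  }
  check_nonnegative(tau, "tau")
  check_nonnegative(sigma, "sigma")
  withr::with_seed(seed, {
    u <- rnorm(n_units, 0, tau)
    grid <- expand.grid(region_id = seq_len(n_units),
                        biennium_index = seq_len(n_times))
    grid$response <- beta[1] + beta[2] * grid$biennium_index +
      u[grid$region_id] + rnorm(nrow(grid), 0, sigma)
    tibble::as_tibble(grid[order(grid$region_id, grid$biennium_index), ])
  })
}

# extract a tidy fit object from a fitted lmerMod
summarise_merMod <- function(fit, varcomp_ci, boot_nsim) {
  est <- lme4::fixef(fit)
  # vcov can fail on fully degenerate (zero-residual) fits; report NA CIs
  V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, length(est)) else sqrt(diag(V))
  z <- qnorm(0.975)
  fixed <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau <- vc$sdcor[vc$grp != "Residual"][1]
  sig <- vc$sdcor[vc$grp == "Residual"][1]

  vci <- matrix(NA_real_, 2, 2,
                dimnames = list(c(".sig01", ".sigma"), c("2.5 %", "97.5 %")))
  if (varcomp_ci != "none") {
    ci <- tryCatch(
      suppressWarnings(suppressMessages(
        if (varcomp_ci == "profile") {
          stats::confint(fit, parm = c(".sig01", ".sigma"),
                         method = "profile", quiet = TRUE)
        } else {
          stats::confint(fit, parm = c(".sig01", ".sigma"),
                         method = "boot", nsim = boot_nsim, quiet = TRUE)
        }
      )),
      error = function(e) NULL
    )
    if (!is.null(ci)) vci[rownames(ci), ] <- ci
  }

  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    fixed_effects = fixed,
    random_intercept_sd = tibble::tibble(
      estimate = tau, ci_low = vci[".sig01", 1], ci_high = vci[".sig01", 2]
    ),
    residual_sd = tibble::tibble(
      estimate = sig, ci_low = vci[".sigma", 1], ci_high = vci[".sigma", 2]
    ),
    n_obs = stats::nobs(fit),
    n_units = lme4::ngrps(fit)[[1]],
    converged = opt_ok && !any(grepl("failed to converge", unlist(msgs))),
    singular = lme4::isSingular(fit),
    collinearity_warning = FALSE,
    condition_number = NA_real_,
    model = fit
  ), class = "neonet_fit")
}

#' Biennial trend of an indicator (random-intercept linear model)
#'
#' Fits, by restricted maximum likelihood (REML),
#' \deqn{y_{jt} = \beta_0 + \beta_1 t + u_j + \varepsilon_{jt}}
#' with a random intercept \eqn{u_j} per health region to accommodate the
#' repeated biennial measurements of each region. \eqn{\beta_1} is the
#' biennium effect (change in the indicator per biennium). Fixed effects get
#' Wald 95% CIs; the random-intercept and residual SDs get profile or
#' parametric-bootstrap CIs (`varcomp_ci`). Rows with a missing response or
#' covariate are dropped listwise.
#'
#' @param panel A region x biennium table (e.g. the `summary` of
#'   [build_region_summary()] or [simulate_panel()] output).
#' @param response Name of the response column.
#' @param covariates Optional character vector of additional fixed-effect
#'   columns.
#' @param unit,time Names of the unit and time columns (defaults
#'   `"region_id"`, `"biennium_index"`; the time variable is the biennium
#'   coded 1..6).
#' @param varcomp_ci CI method for the variance components: `"profile"`
#'   (default), `"boot"`, or `"none"` to skip (fast, e.g. in simulation
#'   loops).
#' @param boot_nsim Bootstrap replicates when `varcomp_ci = "boot"`.
#' @return An object of class `neonet_fit`: list with `fixed_effects`
#'   (term, estimate, se, 95% CI), `random_intercept_sd`, `residual_sd`,
#'   `n_obs`, `n_units`, `converged`, `singular` and the underlying `model`.
#'   Non-convergence is reported via `converged = FALSE`, never silently.
#' @examples
#' pan <- simulate_panel(seed = 7)
#' fit <- fit_trend(pan, varcomp_ci = "none")
#' fit$fixed_effects
#' @export
fit_trend <- function(panel, response = "response", covariates = NULL,
                      unit = "region_id", time = "biennium_index",
                      varcomp_ci = c("profile", "boot", "none"),
                      boot_nsim = 200L) {
  varcomp_ci <- match.arg(varcomp_ci)
  stop_if_not_df_with(panel, c(response, unit, time, covariates), "panel")
  if (length(unique(panel[[unit]])) < 2L) {
    stop("need at least 2 units for a random-intercept model", call. = FALSE)
  }
  if (length(unique(panel[[time]])) < 2L) {
    stop("need at least 2 time points to estimate a trend", call. = FALSE)
  }

  cols <- c(response, time, covariates, unit)
  dat <- panel[, cols, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  rhs <- c(time, covariates, sprintf("(1 | %s)", unit))
  form <- stats::as.formula(
    paste(response, "~", paste(rhs, collapse = " + "))
  )

  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  out <- summarise_merMod(fit, varcomp_ci, boot_nsim)

  if (length(covariates)) {
    mm <- model.matrix(
      stats::as.formula(paste("~", paste(c(time, covariates), collapse = "+"))),
      dat
    )
    kn <- kappa(mm, exact = TRUE)
    out$condition_number <- kn
    if (kn > 1e3) {
      out$collinearity_warning <- TRUE
      warning(sprintf(
        "design matrix condition number %.3g suggests collinearity among covariates",
        kn
      ), call. = FALSE)
    }
  }
  out$response <- response
  out
}

#' Adjusted models for the neonatal mortality rate
#'
#' Fits the three nested random-intercept models of the TMN analysis on a
#' region x biennium summary:
#' * Model 1: biennium only (identical to [fit_trend()] on the TMN);
#' * Model 2: biennium + flow-weighted mean displacement distance;
#' * Model 3: biennium + distance + % admissions outside the residence
#'   municipality + NICU beds/1,000 live births + the four birth indicators
#'   (% < 1,500 g, % GA < 28 w, % Apgar5 <= 7, % maternal age >= 35).
#' Covariates enter raw (per-unit interpretation). Estimation contract as in
#' [fit_trend()].
#'
#' @param panel Region x biennium summary with the TMN and covariate columns
#'   (as produced by [build_region_summary()]).
#' @param model Which model to fit: 1, 2 or 3.
#' @param response Response column (default `"tmn"`).
#' @inheritParams fit_trend
#' @return A `neonet_fit` object (see [fit_trend()]).
#' @export
fit_tmn_model <- function(panel, model = 3L, response = "tmn",
                          varcomp_ci = c("profile", "boot", "none"),
                          boot_nsim = 200L) {
  if (!model %in% 1:3) stop("`model` must be 1, 2 or 3", call. = FALSE)
  covs <- switch(model,
    NULL,
    "weighted_distance_km",
    c("weighted_distance_km", "pct_displaced", "nicu_beds_per_1000",
      "pct_low_weight", "pct_ga_lt28", "pct_apgar5_le7",
      "pct_maternal_35plus")
  )
  fit <- fit_trend(panel, response = response, covariates = covs,
                   varcomp_ci = match.arg(varcomp_ci), boot_nsim = boot_nsim)
  fit$tmn_model <- model
  fit
}

#' @export
print.neonet_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept linear model (REML): %s ~ biennium%s\n",
    x$response %||% "response",
    if (nrow(x$fixed_effects) > 2L) " + covariates" else ""
  ))
  cat(sprintf("  %d observations, %d units; converged: %s%s\n",
              x$n_obs, x$n_units, x$converged,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  cat("Fixed effects (95% CI):\n")
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    cat(sprintf("  %-22s %8.3f  [%.3f; %.3f]\n", fe$term[i], fe$estimate[i],
                fe$ci_low[i], fe$ci_high[i]))
  }
  cat(sprintf("Random intercept SD: %.3f  Residual SD: %.3f\n",
              x$random_intercept_sd$estimate, x$residual_sd$estimate))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a fitted model into a term table
#'
#' Flattens a `neonet_fit` into the model-results layout
#' (`model`, `term`, `estimate`, `ci_low`, `ci_high`, `group`), the
#' machine-readable analogue of the trend/TMN coefficient tables.
#'
#' @param fit A `neonet_fit` object.
#' @param model Optional model label for the `model` column.
#' @return A tibble.
#' @export
tidy_fit <- function(fit, model = NULL) {
  stopifnot(inherits(fit, "neonet_fit"))
  model <- model %||% fit$tmn_model %||% fit$response %||% ""
  dplyr::bind_rows(
    tibble::tibble(model = as.character(model), term = fit$fixed_effects$term,
                   estimate = fit$fixed_effects$estimate,
                   ci_low = fit$fixed_effects$ci_low,
                   ci_high = fit$fixed_effects$ci_high, group = "fixed"),
    tibble::tibble(model = as.character(model), term = "sd_intercept",
                   estimate = fit$random_intercept_sd$estimate,
                   ci_low = fit$random_intercept_sd$ci_low,
                   ci_high = fit$random_intercept_sd$ci_high,
                   group = "random"),
    tibble::tibble(model = as.character(model), term = "sd_residual",
                   estimate = fit$residual_sd$estimate,
                   ci_low = fit$residual_sd$ci_low,
                   ci_high = fit$residual_sd$ci_high, group = "random")
  )
}
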