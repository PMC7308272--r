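# truncated-normal draw by resampling (vectorized rejection)
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  pmin(pmax(out, lower), upper)
}

round_locs <- function(x, upper) pmin(pmax(round(x, 1), 0.1), upper)

# SD of a normal truncated to [lower, upper]
truncnorm_sd <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  sd * sqrt(1 + (a * da - b * db) / z - ((da - db) / z)^2)
}

#' Default parameters for synthetic cohorts
#'
#' The distributions a synthetic trisomy-21 (DS) versus adult-control
#' cohort is drawn from. Scales follow the published summary profile of
#' such cohorts: DS nuclear PIR 1.19 +/- 0.06 rising with age (Spearman
#' rho ~ 0.67 over ages 6–55), control nuclear PIR 1.25 +/- 0.04 over ages
#' 50–60; dot opacities in 50% of DS eyes with 1–50 dots (mean ~ 15.6,
#' median ~ 9), dot PIR 1.33 +/- 0.12 (range 1.14–1.68), dot PAR
#' 0.004–0.14, and 46.8% of dots central; controls carry no cortical, PSC
#' or dot opacity. The age–PIR slope and residual SD are derived from the
#' target correlation and marginal SD
#' (`slope = rho * sd_pir / sd_age`, `resid = sd_pir * sqrt(1 - rho^2)`).
#'
#' @return A named list of parameter blocks consumed by
#'   [generate_cohort()].
#' @export
cohort_params <- function() {
  # age SDs are taken after truncation to the recruitment window so the
  # realized age-PIR correlation hits its target
  ds_rho <- 0.67; ds_sd_pir <- 0.06
  ds_age_sd <- truncnorm_sd(24.1, 14.3, 6, 55)
  ct_rho <- 0.28; ct_sd_pir <- 0.04
  ct_age_sd <- truncnorm_sd(54.0, 3.4, 50, 60)
  ds_slope <- ds_rho * ds_sd_pir / ds_age_sd
  ct_slope <- ct_rho * ct_sd_pir / ct_age_sd
  list(
    ds_age = list(mean = 24.1, sd = 14.3, min = 6, max = 55),
    control_age = list(mean = 54.0, sd = 3.4, min = 50, max = 60),
    ds_npir = list(
      slope = ds_slope,
      intercept = 1.19 - ds_slope * 24.1,
      resid_sd = ds_sd_pir * sqrt(1 - ds_rho^2),
      min = 1.05, max = 1.50
    ),
    control_npir = list(
      slope = ct_slope,
      intercept = 1.25 - ct_slope * 54.0,
      resid_sd = ct_sd_pir * sqrt(1 - ct_rho^2),
      min = 1.10, max = 1.40
    ),
    dot_prevalence = 0.5,
    dot_count = list(mu = 15.63, size = 1, min = 1, max = 50),
    dot_pir = list(mean = 1.33, sd = 0.12, min = 1.14, max = 1.68),
    dot_par = list(meanlog = log(0.02), sdlog = 0.9, min = 0.004, max = 0.14),
    central_fraction = 0.468,
    areal_opacity = list(prevalence = 2 / 54, pir = c(1.1, 1.6),
                         par = c(0.01, 0.24)),
    ds_va = list(mean = 0.371, sd = 0.215, min = 0.05, max = 0.80),
    control_va = list(mean = -0.053, sd = 0.123, min = -0.20, max = 0.38),
    ds_locs = list(NO = c(0.50, 0.49), NC = c(0.48, 0.58),
                   C = c(0.75, 0.71), P = c(0.38, 0.74)),
    control_locs = list(NO = c(1.83, 0.34), NC = c(1.69, 0.45),
                        C = c(0.17, 0.37), P = c(0.10, 0.0))
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws one record per eye for a DS group and an adult control group:
#' age, logMAR visual acuity, LOCS III grades and the full opacity-metric
#' block. Nuclear PIR follows a linear age trend plus residual noise
#' (yielding the target Spearman association); half of DS eyes carry dot
#' opacities; controls never carry cortical, PSC or dot opacity. The
#' per-record linear predictor is stored as `nuclear_pir_expected` so
#' recovery can be tested against ground truth. Metrics are drawn at the
#' summary level — phantom images for any record are available on demand
#' through [scene_spec_from_record()].
#'
#' @param n_ds,n_control Eyes per group (default 54 and 46).
#' @param params Parameter blocks, see [cohort_params()].
#' @param seed Integer seed; the cohort is deterministic per seed.
#'
#' @return A tibble of class `lens_cohort`, one row per eye.
#' @examples
#' cohort <- generate_cohort(n_ds = 10, n_control = 10, seed = 3)
#' dplyr::count(cohort, group, has_dots = dot_count > 0)
#' @export
generate_cohort <- function(n_ds = 54, n_control = 46,
                            params = cohort_params(), seed = 1) {
  stopifnot(n_ds >= 1, n_control >= 1)
  p <- params
  with_seed(seed, {
    ds_age <- rnorm_trunc(n_ds, p$ds_age$mean, p$ds_age$sd,
                          p$ds_age$min, p$ds_age$max)
    ct_age <- rnorm_trunc(n_control, p$control_age$mean, p$control_age$sd,
                          p$control_age$min, p$control_age$max)
    ds_mu <- p$ds_npir$intercept + p$ds_npir$slope * ds_age
    ct_mu <- p$control_npir$intercept + p$control_npir$slope * ct_age
    ds_npir <- pmin(pmax(ds_mu + stats::rnorm(n_ds, 0, p$ds_npir$resid_sd),
                         p$ds_npir$min), p$ds_npir$max)
    ct_npir <- pmin(pmax(ct_mu + stats::rnorm(n_control, 0, p$control_npir$resid_sd),
                         p$control_npir$min), p$control_npir$max)

    has_dots <- stats::rbinom(n_ds, 1, p$dot_prevalence) == 1
    counts <- integer(n_ds)
    counts[has_dots] <- pmin(pmax(
      stats::rnbinom(sum(has_dots), mu = p$dot_count$mu, size = p$dot_count$size),
      p$dot_count$min), p$dot_count$max)
    dot_pir <- ifelse(has_dots,
                      rnorm_trunc(n_ds, p$dot_pir$mean, p$dot_pir$sd,
                                  p$dot_pir$min, p$dot_pir$max), 0)
    dot_par <- ifelse(has_dots,
                      pmin(pmax(stats::rlnorm(n_ds, p$dot_par$meanlog,
                                              p$dot_par$sdlog),
                                p$dot_par$min), p$dot_par$max), 0)
    n_central <- stats::rbinom(n_ds, counts, p$central_fraction)

    ar <- p$areal_opacity
    cort_op <- stats::rbinom(n_ds, 1, ar$prevalence) == 1
    psc_op <- stats::rbinom(n_ds, 1, ar$prevalence) == 1
    cort_pir <- ifelse(cort_op, stats::runif(n_ds, ar$pir[1], ar$pir[2]), 0)
    cort_par <- ifelse(cort_op, stats::runif(n_ds, ar$par[1], ar$par[2]), 0)
    psc_pir <- ifelse(psc_op, stats::runif(n_ds, ar$pir[1], ar$pir[2]), 0)
    psc_par <- ifelse(psc_op, stats::runif(n_ds, ar$par[1], ar$par[2]), 0)

    ds_va <- rnorm_trunc(n_ds, p$ds_va$mean, p$ds_va$sd,
                         p$ds_va$min, p$ds_va$max)
    ct_va <- rnorm_trunc(n_control, p$control_va$mean, p$control_va$sd,
                         p$control_va$min, p$control_va$max)

    locs_draw <- function(n, block) {
      tibble::tibble(
        NO = round_locs(stats::rnorm(n, block$NO[1], block$NO[2]), 6.9),
        NC = round_locs(stats::rnorm(n, block$NC[1], block$NC[2]), 6.9),
        C = round_locs(stats::rnorm(n, block$C[1], block$C[2]), 5.9),
        P = round_locs(stats::rnorm(n, block$P[1], block$P[2]), 5.9)
      )
    }
    ds_locs <- locs_draw(n_ds, p$ds_locs)
    ct_locs <- locs_draw(n_control, p$control_locs)

    ds <- tibble::tibble(
      eye_id = sprintf("DS_%03d", seq_len(n_ds)),
      group = "DS",
      age_years = ds_age,
      visual_acuity_logmar = ds_va,
      nuclear_pir = ds_npir,
      nuclear_pir_expected = ds_mu,
      cortical_pir = cort_pir, cortical_par = cort_par,
      psc_pir = psc_pir, psc_par = psc_par,
      dot_pir = dot_pir, dot_par = dot_par,
      dot_count = as.integer(counts),
      dot_count_central = as.integer(n_central),
      central_proportion = ifelse(counts > 0, n_central / counts, NA_real_)
    )
    ds <- dplyr::bind_cols(ds, ds_locs)
    ct <- tibble::tibble(
      eye_id = sprintf("CT_%03d", seq_len(n_control)),
      group = "control",
      age_years = ct_age,
      visual_acuity_logmar = ct_va,
      nuclear_pir = ct_npir,
      nuclear_pir_expected = ct_mu,
      cortical_pir = 0, cortical_par = 0, psc_pir = 0, psc_par = 0,
      dot_pir = 0, dot_par = 0,
      dot_count = 0L, dot_count_central = 0L,
      central_proportion = NA_real_
    )
    ct <- dplyr::bind_cols(ct, ct_locs)
    out <- dplyr::bind_rows(ds, ct)
    out$group <- factor(out$group, levels = c("DS", "control"))
    class(out) <- c("lens_cohort", class(out))
    out
  })
}

#' Phantom scene spec for one cohort record
#'
#' Maps a cohort record's summary metrics back to a renderable
#' [scene_spec()]: the aqueous level is fixed at 100 so the nucleus level
#' is `100 * nuclear_pir`, the cortex sits at 105, and the dot level is
#' `dot_pir * 105`. Rendering is on demand — generate the scene with
#' [generate_scene()] when a record needs pixels.
#'
#' @param record A one-row slice of a [generate_cohort()] tibble.
#' @param seed Seed for the scene (defaults to a hash of the eye id).
#' @param ... Further arguments passed to [scene_spec()] (e.g. raster
#'   shape, speckle).
#'
#' @return A [scene_spec()].
#' @export
scene_spec_from_record <- function(record, seed = NULL, ...) {
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1L)
  if (is.null(seed)) {
    seed <- sum(utf8ToInt(as.character(record$eye_id))) %% 100000L
  }
  cortex <- 105
  aqueous <- 100
  scene_spec(
    aqueous_level = aqueous,
    cortex_level = cortex,
    nucleus_level = max(record$nuclear_pir * aqueous, cortex),
    dot_count = record$dot_count,
    dot_level = if (record$dot_count > 0) record$dot_pir * cortex else 1.33 * cortex,
    central_fraction = if (record$dot_count > 0) {
      record$dot_count_central / record$dot_count
    } else 0.468,
    seed = seed,
    ...
  )
}
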