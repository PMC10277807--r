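## Synthetic survey world: regions -> countries -> 264 demographic strata,
## with a known log-scale intake surface per dietary factor, population
## weight tables and country-year availability covariates. Everything is
## deterministic given the configured seed and records its own ground truth
## so downstream recovery tests can compare against it.

#' Default dietary factor set
#'
#' Ten factors: the nine AHEI components plus total energy. Units follow the
#' scoring conventions (servings/day for foods, g/day for whole grains,
#' mg/day for seafood omega-3 and sodium, % energy for PUFA, kcal/day for
#' energy). `global_mean` is the world geometric-mean intake on the natural
#' scale and `sigma_within` the within-population log-SD of individual
#' intakes.
#'
#' @return `data.table` with columns `factor`, `unit`, `global_mean`,
#'   `sigma_within`.
#' @export
default_factors <- function() {
  data.table(
    factor = c("fruit", "vegetables", "whole_grains", "ssb", "legumes_nuts",
               "red_processed_meat", "seafood_omega3", "pufa", "sodium",
               "energy"),
    unit = c("servings/day", "servings/day", "g/day", "servings/day",
             "servings/day", "servings/day", "mg/day", "% energy", "mg/day",
             "kcal/day"),
    global_mean = c(1.5, 2.0, 40, 0.8, 0.6, 0.8, 150, 5, 3500, 2100),
    sigma_within = c(0.6, 0.5, 0.6, 0.8, 0.7, 0.6, 0.8, 0.3, 0.4, 0.25)
  )
}

#' Factor set covering all three diet patterns
#'
#' The default ten factors plus the four additional factors needed by the
#' DASH and MED definitions (low-fat dairy, fish, MUFA:SFA ratio, total
#' dairy).
#'
#' @return `data.table` in the same shape as [default_factors()].
#' @export
pattern_factors <- function() {
  extra <- data.table(
    factor = c("low_fat_dairy", "fish", "mufa_sfa_ratio", "dairy"),
    unit = c("servings/day", "servings/day", "ratio", "servings/day"),
    global_mean = c(0.8, 0.5, 1.1, 1.5),
    sigma_within = c(0.7, 0.8, 0.3, 0.6)
  )
  rbind(default_factors(), extra)
}

#' Effect-size configuration of the true intake surface
#'
#' Magnitudes (log scale) of the generative effects. `sd_region` and
#' `sd_country` govern mean-zero normal region and country intercepts;
#' `sd_slope` the per-year country time slopes whose correlation with the
#' country intercept is `rho`; `slope_mean` a common secular trend. The
#' `sex`/`edu_mid`/`edu_high`/`urban` pairs give the mean and SD from which
#' each factor's additive demographic effects are drawn. `age_sd` scales the
#' random smooth age curve. `covariate_noise_sd` adds measurement noise to
#' the country-year availability covariate (default 0: the covariate is an
#' exact index of the country's intercept-plus-trend path).
#'
#' @param zero if `TRUE`, all effects and noise are zero: every stratum's
#'   true mean equals the factor's `global_mean`.
#' @param ... named overrides of the defaults listed above.
#' @return named list of effect parameters.
#' @export
effect_config <- function(zero = FALSE, ...) {
  cfg <- list(
    sd_region = 0.25, sd_country = 0.15, sd_slope = 0.004,
    slope_mean = 0, rho = 0.5,
    sex_mean = 0, sex_sd = 0.06,
    edu_mid_mean = 0.03, edu_mid_sd = 0.03,
    edu_high_mean = 0.06, edu_high_sd = 0.04,
    urban_mean = 0, urban_sd = 0.05,
    age_sd = 0.15,
    covariate_noise_sd = 0
  )
  if (zero) cfg[] <- lapply(cfg, function(x) 0)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown effect parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' World configuration
#'
#' @param n_regions number of world regions.
#' @param countries_per_region countries in each region. The default desk
#'   scale is 3 regions of 4 countries.
#' @param years calendar years of the analysis; must include both endpoints
#'   1990 and 2018.
#' @param factors factor table as from [default_factors()]; each factor has
#'   exactly one unit.
#' @param effects effect-size list from [effect_config()].
#' @param seed master integer seed; all generation stages derive their own
#'   stream from it.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_regions = 3, countries_per_region = 4,
                         years = c(1990, 2000, 2010, 2018),
                         factors = default_factors(),
                         effects = effect_config(), seed = 1L) {
  stopifnot(n_regions >= 1, countries_per_region >= 1)
  if (!all(c(1990, 2018) %in% years)) {
    stop("years must include both analysis endpoints 1990 and 2018")
  }
  factors <- as.data.table(factors)
  need <- c("factor", "unit", "global_mean", "sigma_within")
  if (!all(need %in% names(factors))) {
    stop("factors must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(factors$factor)) {
    stop("each factor must appear exactly once (one unit per factor)")
  }
  structure(list(n_regions = as.integer(n_regions),
                 countries_per_region = as.integer(countries_per_region),
                 years = sort(unique(as.integer(years))),
                 factors = factors, effects = effects,
                 seed = as.integer(seed)),
            class = "world_config")
}

## natural cubic spline basis over age-band midpoints; interior knots at
## every third midpoint
age_spline_basis <- function(age, knot_step = 3L) {
  mids <- age_bands()$age_mid
  knots <- mids[seq(knot_step + 1L, length(mids) - knot_step, by = knot_step)]
  splines::ns(age, knots = knots, Boundary.knots = range(mids))
}

#' Reference energy intakes by age band
#'
#' Smooth reference total-energy intakes (kcal/day) over the 22 age bands,
#' rising through childhood, peaking in early adulthood and declining in old
#' age. Used by the world generator to shape the energy factor's age curve.
#'
#' @return `data.table` with columns `age_group`, `energy_kcal`.
#' @export
reference_energy_table <- function() {
  ab <- age_bands()
  a <- ab$age_mid
  e <- 2400 * (1 - exp(-(a + 2) / 8)) * exp(-((pmax(a, 25) - 25) / 90)^2)
  e <- pmax(e, 700)
  data.table(age_group = ab$age_group, energy_kcal = round(e))
}

#' Build a synthetic world with known ground truth
#'
#' Generates the true intake surface (global log-mean, region and country
#' intercepts, country time slopes with intercept-slope correlation,
#' additive sex/education/urbanicity effects and a smooth age curve per
#' factor), population weight tables covering all 264 strata for every
#' country-year, and country-year availability covariates. All ground-truth
#' parameters are retained in the returned object for recovery testing.
#'
#' @param config a [world_config()].
#' @return object of class `diet_world`: list with elements `config`,
#'   `regions` (country-region map), `surface` (per-factor truth
#'   parameters), `weights`, `covariates`.
#' @export
build_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  fx <- config$factors
  eff <- config$effects
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  countries <- data.table(
    country = sprintf("C%02d", seq_len(config$n_regions * config$countries_per_region)),
    region = rep(regions, each = config$countries_per_region)
  )
  ref_year <- mean(c(1990, 2018))
  mids <- age_bands()$age_mid
  basis <- age_spline_basis(mids)

  set.seed(derive_seed(config$seed, "surface"))
  surface <- list()
  for (i in seq_len(nrow(fx))) {
    f <- fx$factor[i]
    reg_eff <- stats::rnorm(length(regions), 0, eff$sd_region)
    Sig <- matrix(c(eff$sd_country^2,
                    eff$rho * eff$sd_country * eff$sd_slope,
                    eff$rho * eff$sd_country * eff$sd_slope,
                    eff$sd_slope^2), 2, 2)
    cs <- if (all(Sig == 0)) matrix(0, nrow(countries), 2) else
      MASS::mvrnorm(nrow(countries), c(0, eff$slope_mean), Sig)
    if (f == "energy") {
      ref <- reference_energy_table()$energy_kcal
      target <- log(ref) - mean(log(ref))
      age_curve <- as.vector(basis %*% qr.coef(qr(basis), target))
    } else {
      age_curve <- as.vector(basis %*% stats::rnorm(ncol(basis), 0, eff$age_sd))
      age_curve <- age_curve - mean(age_curve)
    }
    surface[[f]] <- list(
      factor = f, unit = fx$unit[i],
      global_logmean = log(fx$global_mean[i]),
      sigma_within = fx$sigma_within[i],
      region_effects = stats::setNames(reg_eff, regions),
      country_intercepts = stats::setNames(cs[, 1], countries$country),
      country_slopes = stats::setNames(cs[, 2], countries$country),
      rho = eff$rho,
      sex_female = stats::rnorm(1, eff$sex_mean, eff$sex_sd),
      edu_mid = stats::rnorm(1, eff$edu_mid_mean, eff$edu_mid_sd),
      edu_high = stats::rnorm(1, eff$edu_high_mean, eff$edu_high_sd),
      urban = stats::rnorm(1, eff$urban_mean, eff$urban_sd),
      age_curve = stats::setNames(age_curve, age_bands()$age_group)
    )
  }

  world <- structure(list(config = config, regions = countries,
                          surface = surface, ref_year = ref_year),
                     class = "diet_world")
  world$weights <- .build_weights(config, countries)
  world$covariates <- .build_covariates(world)
  .validate_surface(world)
  world
}

.build_weights <- function(config, countries) {
  set.seed(derive_seed(config$seed, "weights"))
  ab <- age_bands()
  base_pop <- exp(stats::rnorm(nrow(countries), log(5e6), 0.8))
  urban_share <- stats::runif(nrow(countries), 0.3, 0.8)
  edu_raw <- matrix(stats::runif(3 * nrow(countries), 0.5, 1.5), ncol = 3)
  edu_share <- edu_raw / rowSums(edu_raw)
  p_age <- exp(-0.015 * ab$age_mid)
  p_age <- p_age / sum(p_age)

  out <- vector("list", nrow(countries) * length(config$years))
  k <- 0L
  for (i in seq_len(nrow(countries))) {
    for (yr in config$years) {
      k <- k + 1L
      g <- stratum_grid(with_age_mid = FALSE)
      grow <- 1.01^(yr - 1990)
      ush <- min(urban_share[i] + 0.002 * (yr - 1990), 0.95)
      g[, persons := base_pop[i] * grow * 0.5 *
          p_age[match(age_group, ab$age_group)] *
          edu_share[i, match(education, EDU_LEVELS)] *
          ifelse(urbanicity == "urban", ush, 1 - ush)]
      g[, `:=`(country = countries$country[i], region = countries$region[i],
               year = yr)]
      out[[k]] <- g
    }
  }
  w <- rbindlist(out)
  setcolorder(w, c("region", "country", "year", "sex", "age_group",
                   "education", "urbanicity", "persons"))
  w[]
}

.build_covariates <- function(world) {
  config <- world$config
  set.seed(derive_seed(config$seed, "covariates"))
  grid <- CJ(country = world$regions$country, year = config$years,
             factor = config$factors$factor, sorted = FALSE)
  grid[, value := {
    s <- world$surface[[.BY$factor]]
    s$country_intercepts[country] +
      s$country_slopes[country] * (year - world$ref_year)
  }, by = factor]
  noise_sd <- config$effects$covariate_noise_sd
  if (noise_sd > 0) grid[, value := value + stats::rnorm(.N, 0, noise_sd)]
  grid[]
}

.validate_surface <- function(world) {
  tm <- true_stratum_means(world)
  bad <- tm[!is.finite(true_mean) | true_mean <= 0]
  if (nrow(bad)) {
    b <- bad[1]
    stop(sprintf(paste0("configuration implies non-positive mean for factor ",
                        "'%s' in %s/%d stratum (%s, %s, %s, %s)"),
                 b$factor, b$country, b$year, b$sex, b$age_group,
                 b$education, b$urbanicity))
  }
  invisible(world)
}

#' True stratum mean intakes of a synthetic world
#'
#' Evaluates the generative intake surface on the natural and log scale for
#' every requested country-year-stratum-factor.
#'
#' @param world a [build_world()] object.
#' @param countries,years,factors subsets to evaluate (default: all).
#' @return `data.table` with stratum descriptors, `factor`, `true_logmean`
#'   and `true_mean`.
#' @export
true_stratum_means <- function(world, countries = NULL, years = NULL,
                               factors = NULL) {
  stopifnot(inherits(world, "diet_world"))
  countries <- countries %||% world$regions$country
  years <- years %||% world$config$years
  factors <- factors %||% names(world$surface)
  bad <- setdiff(countries, world$regions$country)
  if (length(bad)) stop("unknown country: ", paste(bad, collapse = ", "))
  g <- stratum_grid(with_age_mid = FALSE)
  out <- CJ(country = countries, year = as.integer(years), factor = factors,
            sorted = FALSE)[, g[], by = .(country, year, factor)]
  out[, true_logmean := {
    s <- world$surface[[.BY$factor]]
    reg <- world$regions$region[match(country, world$regions$country)]
    s$global_logmean + s$region_effects[reg] +
      s$country_intercepts[country] +
      s$country_slopes[country] * (year - world$ref_year) +
      s$sex_female * (sex == "female") +
      s$edu_mid * (education == "6-<12y") +
      s$edu_high * (education == ">=12y") +
      s$urban * (urbanicity == "urban") +
      s$age_curve[age_group]
  }, by = factor]
  out[, true_mean := exp(true_logmean)]
  out[]
}
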