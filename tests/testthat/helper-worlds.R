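## Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## small two-region world used by most model tests
tiny_world <- function() {
  memo("tiny_world", build_world(world_config(
    n_regions = 2, countries_per_region = 2, years = c(1990, 2018),
    seed = 7
  )))
}

tiny_records <- function() {
  memo("tiny_records", {
    w <- tiny_world()
    simulate_surveys(w, biases = unbiased_method_biases(w$config$factors))
  })
}

tiny_fit <- function() {
  memo("tiny_fit", {
    w <- tiny_world()
    suppressWarnings(fit_intake_model(
      tiny_records()[factor %in% c("fruit", "energy")],
      model_spec(seed = 11), w$regions, w$covariates, w$weights
    ))
  })
}

## independent sort-based percentile oracle: linear interpolation between
## order statistics at plotting position k/(n+1)
sort_percentile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n + 1) * pp
    k <- floor(h)
    if (k < 1) return(xs[1])
    if (k >= n) return(xs[n])
    xs[k] + (h - k) * (xs[k + 1] - xs[k])
  }, numeric(1))
}

## constructs a posterior_intake with given per-stratum constant or supplied
## draw matrix, for scoring/aggregation tests
make_intake <- function(values, factors, units = NULL, country = "C01",
                        year = 2018, draws = NULL, sex = NULL) {
  g <- stratum_grid(with_age_mid = FALSE)
  if (!is.null(sex)) g <- g[g$sex %in% sex, ]
  n <- nrow(g)
  strata <- data.table::rbindlist(lapply(seq_along(factors), function(i) {
    data.table::data.table(country = country, year = year, g,
                           factor = factors[i],
                           unit = if (is.null(units)) "servings/day"
                                  else units[i])
  }))
  if (is.null(draws)) {
    draws <- matrix(rep(rep(values, each = n), 4000),
                    nrow = n * length(factors), ncol = 4000)
  }
  posterior_intake(strata, draws)
}

## equal weights for every stratum of the given country-years
flat_weights <- function(countries = "C01", years = 2018, region = "R01") {
  g <- stratum_grid(with_age_mid = FALSE)
  out <- data.table::CJ(country = countries, year = years, sorted = FALSE)
  out <- out[, g[], by = .(country, year)]
  out[, persons := 1]
  out[, region := region]
  out[]
}

## one-stratum posterior_intake holding given per-factor constant values
single_stratum_intake <- function(values, units) {
  g <- stratum_grid(with_age_mid = FALSE)[sex == "male"][1]
  strata <- data.table::rbindlist(lapply(names(values), function(f) {
    data.table::data.table(country = "C01", year = 2018, g, factor = f,
                           unit = units[[f]])
  }))
  posterior_intake(strata, matrix(rep(unlist(values), 4000),
                                  nrow = length(values)))
}

## stratum-median population for quantile cutpoints, from world ground truth
truth_median_population <- function(world) {
  tm <- true_stratum_means(world, years = 2018)
  tm[, .(country, year, sex, age_group, education, urbanicity, factor,
         median = true_mean)]
}

pattern_world <- function() {
  memo("pattern_world", build_world(world_config(
    n_regions = 2, countries_per_region = 2, years = c(1990, 2018),
    factors = pattern_factors(), seed = 31
  )))
}
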