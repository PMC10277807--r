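## Survey simulation: noisy stratum-level observations of the true intake
## surface. Observed means are sample means of n log-normal individual draws
## around the (method-biased) cell mean; non-representative surveys and the
## coarser instruments carry an extra between-survey noise term, which is the
## overdispersion the intake model has to absorb.

#' Default multiplicative assessment-method biases
#'
#' Factor-specific multiplicative biases by assessment method relative to the
#' 24-hour recall reference. The magnitudes of real instrument biases are not
#' established; these defaults are placeholders with the household-derived
#' methods (DHS, HBS) furthest from 1.
#'
#' @param factors character vector of factor names (or a factor table).
#' @return matrix `factors x methods` of multiplicative biases.
#' @export
default_method_biases <- function(factors = default_factors()) {
  if (is.data.frame(factors)) factors <- factors$factor
  b <- matrix(rep(c(1.0, 0.95, 0.90, 0.85), each = length(factors)),
              nrow = length(factors),
              dimnames = list(factors, METHOD_LEVELS))
  b
}

#' Bias-free method matrix (all ones)
#' @rdname default_method_biases
#' @export
unbiased_method_biases <- function(factors = default_factors()) {
  b <- default_method_biases(factors)
  b[] <- 1
  b
}

## between-survey log-SD by method (placeholders; DHS/HBS noisier)
default_method_noise <- function() {
  c("24hr_recall" = 0, "FFQ" = 0.03, "DHS" = 0.08, "HBS" = 0.10)
}

#' Default survey design for a world
#'
#' One nationally representative 24-hour-recall survey with full
#' stratification per country-year, plus, per country, a non-representative
#' education-collapsed FFQ in the final year, and one DHS and one HBS survey
#' (both non-representative, collapsed) to exercise every method type, both
#' representativeness values and the collapsed-stratum path.
#'
#' @param world a [build_world()] object.
#' @param n_per_stratum participants sampled per stratum cell.
#' @return `data.table` design with one row per survey: `country`, `year`,
#'   `method`, `representative`, `n_per_stratum`, `collapse` (one of
#'   `"none"`, `"education"`, `"urbanicity"`, `"education+urbanicity"`).
#' @export
default_survey_design <- function(world, n_per_stratum = 50L) {
  stopifnot(inherits(world, "diet_world"))
  yrs <- world$config$years
  cc <- world$regions$country
  core <- CJ(country = cc, year = yrs, sorted = FALSE)
  core[, `:=`(method = "24hr_recall", representative = TRUE,
              n_per_stratum = n_per_stratum, collapse = "none")]
  ffq <- data.table(country = cc, year = max(yrs), method = "FFQ",
                    representative = FALSE, n_per_stratum = 2L * n_per_stratum,
                    collapse = "education")
  extra <- data.table(
    country = cc[c(1L, min(2L, length(cc)))],
    year = yrs[min(2L, length(yrs))],
    method = c("DHS", "HBS"), representative = FALSE,
    n_per_stratum = 2L * n_per_stratum,
    collapse = c("education", "education+urbanicity")
  )
  rbind(core, ffq, extra)
}

#' Simulate survey records from a world's true intake surface
#'
#' For each survey and factor, cell-level true means are the
#' population-weighted averages of the constituent stratum means (collapsed
#' dimensions averaged out), multiplied by the method's factor-specific bias
#' and a survey-level log-normal noise term (method noise, plus
#' `nonrep_sd` when not representative). Observed mean/SD are the sample
#' moments of `n` log-normal individual draws with the factor's
#' within-population log-SD.
#'
#' @param world a [build_world()] object.
#' @param design survey design table, see [default_survey_design()].
#' @param biases factor-by-method multiplicative bias matrix.
#' @param method_noise named per-method between-survey log-SD.
#' @param nonrep_sd extra between-survey log-SD for non-representative
#'   surveys.
#' @param factors factors to observe (default: all in the world).
#' @param seed integer seed (default derived from the world's master seed).
#' @return `data.table` of survey records: survey metadata, stratum
#'   descriptors (`NA` on collapsed dimensions, with a `collapsed` column
#'   naming them), `factor`, `unit`, `observed_mean`, `observed_sd`, `n`.
#' @export
simulate_surveys <- function(world, design = default_survey_design(world),
                             biases = default_method_biases(world$config$factors),
                             method_noise = default_method_noise(),
                             nonrep_sd = 0.12,
                             factors = NULL,
                             seed = NULL) {
  stopifnot(inherits(world, "diet_world"))
  design <- as.data.table(design)
  need <- c("country", "year", "method", "representative", "n_per_stratum",
            "collapse")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  bad <- design[!country %in% world$regions$country |
                !year %in% world$config$years]
  if (nrow(bad)) {
    stop(sprintf("design references unknown country/year: %s/%d",
                 bad$country[1], bad$year[1]))
  }
  if (!all(design$method %in% METHOD_LEVELS)) {
    stop("unknown assessment method in design")
  }
  factors <- factors %||% names(world$surface)
  stopifnot(all(factors %in% rownames(biases)))
  set.seed(seed %||% derive_seed(world$config$seed, "surveys"))

  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i]
    collapsed_dims <- if (d$collapse == "none") character(0) else
      strsplit(d$collapse, "+", fixed = TRUE)[[1]]
    tm <- true_stratum_means(world, countries = d$country, years = d$year,
                             factors = factors)
    w <- world$weights[country == d$country & year == d$year,
                       .(sex, age_group, education, urbanicity, persons)]
    tm <- merge(tm, w, by = c("sex", "age_group", "education", "urbanicity"),
                sort = FALSE)
    for (dim in collapsed_dims) tm[, (dim) := NA_character_]
    keycols <- c("sex", "age_group", "education", "urbanicity")
    cells <- tm[, .(true_mean = sum(true_mean * persons) / sum(persons)),
                by = c(keycols, "factor")]
    cells[, `:=`(survey_id = sprintf("S%03d", i), country = d$country,
                 year = d$year, method = d$method,
                 representative = d$representative,
                 collapsed = paste(collapsed_dims, collapse = "+"),
                 n = d$n_per_stratum)]
    ## survey-level multiplicative noise, one draw per factor
    extra_sd <- method_noise[[d$method]] +
      if (!d$representative) nonrep_sd else 0
    sfac <- stats::setNames(exp(stats::rnorm(length(factors), 0, extra_sd)),
                            factors)
    cells[, cell_mean := true_mean * biases[factor, unique(method)] *
            sfac[factor], by = factor]
    ## sample moments of n log-normal individuals per cell
    cells[, c("observed_mean", "observed_sd") := {
      sw <- world$surface[[.BY$factor]]$sigma_within
      nn <- n[1]
      m <- matrix(stats::rlnorm(nn * .N,
                                meanlog = rep(log(cell_mean) - sw^2 / 2, each = nn),
                                sdlog = sw),
                  nrow = nn)
      list(colMeans(m), apply(m, 2, stats::sd))
    }, by = factor]
    cells[, unit := world$config$factors$unit[
      match(factor, world$config$factors$factor)]]
    out[[i]] <- cells[, .(survey_id, country, year, method, representative,
                          sex, age_group, education, urbanicity, collapsed,
                          factor, unit, observed_mean, observed_sd, n)]
  }
  rbindlist(out)[]
}
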