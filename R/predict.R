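## Posterior stratum predictions: 264 strata per country-year-factor, each
## carried as 4,000 natural-scale posterior draws.

#' Posterior intake container
#'
#' Holds stratum descriptors and an aligned draws matrix (one row per
#' stratum-factor, `4000` columns). Draw column `d` indexes the same joint
#' posterior sample in every row, which is the contract that makes draw-wise
#' differencing downstream valid.
#'
#' @param strata `data.table` with columns `country`, `year`, `sex`,
#'   `age_group`, `education`, `urbanicity`, `factor`, `unit`.
#' @param draws numeric matrix, `nrow(strata)` x 4000, non-negative (model
#'   predictions are strictly positive by construction; zero is admitted so
#'   boundary intakes such as no sugar-sweetened beverages can be scored).
#' @param standardized logical flag: energy-standardized or raw.
#' @return object of class `posterior_intake`.
#' @export
posterior_intake <- function(strata, draws, standardized = FALSE) {
  strata <- as.data.table(strata)
  stopifnot(is.matrix(draws), nrow(draws) == nrow(strata))
  assert_draw_count(ncol(draws), "posterior_intake")
  if (any(draws < 0)) stop("posterior intake draws must be non-negative")
  structure(list(strata = strata, draws = draws,
                 standardized = isTRUE(standardized)),
            class = "posterior_intake")
}

#' @export
print.posterior_intake <- function(x, ...) {
  cat("<posterior_intake>", nrow(x$strata), "stratum-factor rows x",
      ncol(x$draws), "draws;",
      if (x$standardized) "energy-standardized" else "natural units", "\n")
  invisible(x)
}

#' Summarize posterior intakes (median and 95% UI per stratum)
#'
#' @param object a [posterior_intake()].
#' @param ... unused.
#' @return `data.table`: stratum descriptors plus `median`, `ui_low`,
#'   `ui_high`.
#' @export
summary.posterior_intake <- function(object, ...) {
  q <- .row_quantiles(object$draws)
  out <- copy(object$strata)
  out[, `:=`(median = q[, 1], ui_low = q[, 2], ui_high = q[, 3])]
  out[]
}

#' Predict posterior intake draws for all 264 strata
#'
#' For every requested country-year and fitted factor, emits exactly 264
#' strata with 4,000 natural-scale posterior draws each (exponentiated
#' linear-predictor draws at the reference assessment method). Strata never
#' directly observed are predicted through the hierarchical structure. A
#' target country absent from the fitted region map falls back to its
#' region's effects plus a country effect drawn from the posterior
#' country-SD, with a warning; such targets must carry a `region` column.
#'
#' @param fit an [fit_intake_model()] result.
#' @param targets `data.table` of `country`, `year` (optional `region` for
#'   out-of-map countries).
#' @param factors factors to predict (default: all fitted).
#' @return a [posterior_intake()].
#' @export
predict_strata <- function(fit, targets, factors = NULL) {
  stopifnot(inherits(fit, "intake_fit"))
  targets <- unique(as.data.table(targets))
  factors <- factors %||% names(fit$fits)
  spec <- fit$spec
  grid <- stratum_grid()
  strata_list <- list()
  draw_list <- list()
  k <- 0L
  for (f in factors) {
    ff <- fit$fits[[f]]
    if (is.null(ff) || !identical(ff$status, "ok")) {
      stop("factor '", f, "' has no fitted estimate (status: ",
           ff$status %||% "absent", ")")
    }
    des <- ff$design
    for (i in seq_len(nrow(targets))) {
      ct <- targets$country[i]; yr <- targets$year[i]
      known <- ct %in% des$cty_levels
      if (!known) {
        if (!"region" %in% names(targets) || is.na(targets$region[i])) {
          stop("country '", ct, "' absent from model; targets must supply ",
               "its region for the hierarchical fallback")
        }
        if (!targets$region[i] %in% des$reg_levels) {
          stop("region '", targets$region[i], "' unknown to the model")
        }
        warning("country '", ct, "' not in the fitted model; ",
                "falling back to region-level effects", call. = FALSE)
      }
      dt <- copy(grid)
      dt[, method := NA_character_]
      if (spec$use_covariate) {
        cv <- fit$covariates[country == ct & year == yr & factor == f, value]
        if (length(cv) != 1L) {
          if (known) {
            stop(sprintf("covariate missing for %s/%d/%s", ct, yr, f))
          }
          cv <- 0  # out-of-map fallback: region-level prediction only
        }
        dt[, covariate := cv]
      }
      X <- .fixed_design(dt, spec$use_covariate)
      reg <- if (known) {
        fit$regions$region[match(ct, fit$regions$country)]
      } else targets$region[i]
      Zr <- outer(rep(reg, nrow(dt)), des$reg_levels, `==`) * 1
      Zc <- matrix(0, nrow(dt), des$n_country)
      if (known) Zc[, match(ct, des$cty_levels)] <- 1
      Mp <- cbind(X, Zr, Zc)
      mu <- Mp %*% t(ff$draws)          # 264 x 4000, log scale
      if (!known) {
        set.seed(derive_seed(spec$seed, paste0("fallback|", ct, "|", f)))
        u <- stats::rnorm(ncol(mu), 0, ff$scale_draws[, "sigma_country"])
        mu <- sweep(mu, 2L, u, `+`)
      }
      k <- k + 1L
      st <- copy(grid)[, `:=`(country = ct, year = yr, factor = f,
                              unit = ff$unit %||% NA_character_)]
      st[, age_mid := NULL]
      strata_list[[k]] <- st
      draw_list[[k]] <- exp(mu)
    }
  }
  strata <- rbindlist(strata_list)
  setcolorder(strata, c("country", "year", "sex", "age_group", "education",
                        "urbanicity", "factor", "unit"))
  posterior_intake(strata, do.call(rbind, draw_list))
}
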