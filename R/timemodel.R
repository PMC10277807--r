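## Second-stage varying-slopes model for time trends. Country-year log-mean
## intakes (from the first-stage posterior) are regressed on centred calendar
## year with country-specific intercepts and slopes that are partially pooled
## across countries through a bivariate normal with estimated
## intercept-slope correlation; an optional availability covariate enters as
## a shared fixed effect. Gibbs sampling with conjugate normal /
## inverse-Wishart updates and a Metropolis step for the residual SD.

#' Time model specification
#'
#' @param chains,warmup,draws_per_chain MCMC layout; retained total must be
#'   4,000.
#' @param mean_sd prior SD of the normal prior on the population intercept,
#'   slope and covariate coefficient.
#' @param iw_df,iw_scale inverse-Wishart prior (degrees of freedom and scale
#'   diagonal, intercept then slope) on the country intercept-slope
#'   covariance.
#' @param sigma_scale half-normal prior scale of the residual SD.
#' @param mh_step Metropolis step for `log(sigma)`.
#' @param seed integer seed.
#' @return object of class `time_model_spec`.
#' @export
time_model_spec <- function(chains = 4L, warmup = 500L,
                            draws_per_chain = 1000L, mean_sd = 10,
                            iw_df = 4, iw_scale = c(0.25, 0.001),
                            sigma_scale = 0.5, mh_step = 0.3, seed = 1L) {
  if (chains * draws_per_chain != N_DRAWS) {
    stop(sprintf("chains * draws_per_chain must equal %d retained draws",
                 N_DRAWS))
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws_per_chain = as.integer(draws_per_chain),
                 mean_sd = mean_sd, iw_df = iw_df, iw_scale = iw_scale,
                 sigma_scale = sigma_scale, mh_step = mh_step,
                 seed = as.integer(seed)),
            class = "time_model_spec")
}

## reduce a posterior_intake (single factor) to country-year log-mean series
.country_year_series <- function(pred) {
  fcts <- unique(pred$strata$factor)
  if (length(fcts) != 1L) {
    stop("supply a single-factor posterior_intake (subset first); found: ",
         paste(fcts, collapse = ", "))
  }
  lg <- log(pred$draws)
  idx <- pred$strata[, .(country, year)]
  key <- paste(idx$country, idx$year)
  ## per-draw country-year mean over strata, then moments over draws
  out <- rbindlist(lapply(split(seq_len(nrow(idx)), key), function(rows) {
    m <- colMeans(lg[rows, , drop = FALSE])
    data.table(country = idx$country[rows[1]], year = idx$year[rows[1]],
               logmean = mean(m), se = stats::sd(m))
  }))
  out[se < 1e-6, se := 1e-6]
  out[]
}

#' Fit the varying-slopes time model
#'
#' @param x either a single-factor [posterior_intake()] or a `data.table`
#'   with columns `country`, `year`, `logmean`, `se`.
#' @param covariates optional `data.table` (`country`, `year`, `value`);
#'   countries whose series does not cover all model years fall back to
#'   first-stage estimates (they are excluded from the fit, with a message).
#' @param spec a [time_model_spec()].
#' @param ref_year year at which intercepts are anchored (default: midpoint
#'   of the observed years).
#' @return object of class `time_fit` with 4,000 posterior draws of country
#'   intercepts and slopes, their population means, covariance, correlation
#'   (`rho`, in \[-1, 1\]), covariate coefficient and residual SD.
#' @export
fit_time_model <- function(x, covariates = NULL, spec = time_model_spec(),
                           ref_year = NULL) {
  dat <- if (inherits(x, "posterior_intake")) .country_year_series(x)
         else as.data.table(x)
  stopifnot(all(c("country", "year", "logmean", "se") %in% names(dat)))
  excluded <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.table(covariates)
    yrs <- sort(unique(dat$year))
    ok_c <- covariates[, .(full = all(yrs %in% year)), by = country][full == TRUE, country]
    excluded <- setdiff(unique(dat$country), ok_c)
    if (length(excluded)) {
      message("countries without complete covariate series fall back to ",
              "first-stage estimates: ", paste(excluded, collapse = ", "))
      dat <- dat[!country %in% excluded]
    }
    dat <- merge(dat, covariates[, .(country, year, xcov = value)],
                 by = c("country", "year"), sort = FALSE)
  } else {
    dat[, xcov := 0]
  }
  ref_year <- ref_year %||% mean(range(dat$year))
  dat[, t := year - ref_year]
  ctys <- sort(unique(dat$country))
  C <- length(ctys)
  if (C < 2L) stop("time model needs at least two countries")
  use_cov <- !is.null(covariates)

  nkeep <- spec$draws_per_chain
  dims <- c(nkeep, C, spec$chains)
  A <- array(NA_real_, dims); Bm <- array(NA_real_, dims)
  TH0 <- array(NA_real_, c(nkeep, 2L, spec$chains))
  RHO <- array(NA_real_, c(nkeep, spec$chains))
  GAM <- array(NA_real_, c(nkeep, spec$chains))
  SIG <- array(NA_real_, c(nkeep, spec$chains))
  SIGMAT <- array(NA_real_, c(nkeep, 3L, spec$chains))

  split_dat <- split(dat, dat$country)[ctys]
  P0 <- diag(2) / spec$mean_sd^2
  S0 <- diag(spec$iw_scale)

  for (ch in seq_len(spec$chains)) {
    set.seed(derive_seed(spec$seed, paste0("time|", ch)))
    th <- matrix(0, C, 2)
    th0 <- c(mean(dat$logmean), 0)
    Sig <- diag(c(0.1, 0.001))
    gam <- 0
    lsig <- log(0.05)
    for (it in seq_len(spec$warmup + nkeep)) {
      se2 <- exp(2 * lsig)
      Sinv <- solve(Sig)
      ## country intercept/slope blocks
      for (ci in seq_len(C)) {
        d <- split_dat[[ci]]
        vv <- d$se^2 + se2
        W <- cbind(1, d$t)
        r <- d$logmean - gam * d$xcov
        Qc <- crossprod(W / sqrt(vv)) + Sinv
        rhs <- crossprod(W, r / vv) + Sinv %*% th0
        Rc <- chol(Qc)
        th[ci, ] <- backsolve(Rc, forwardsolve(t(Rc), rhs)) +
          backsolve(Rc, stats::rnorm(2))
      }
      ## population mean
      Q0 <- C * Sinv + P0
      R0 <- chol(Q0)
      rhs0 <- Sinv %*% colSums(th)
      th0 <- as.vector(backsolve(R0, forwardsolve(t(R0), rhs0)) +
                         backsolve(R0, stats::rnorm(2)))
      ## covariance (inverse-Wishart, conjugate)
      dev <- sweep(th, 2L, th0)
      SS <- S0 + crossprod(dev)
      Wdraw <- stats::rWishart(1L, spec$iw_df + C, solve(SS))[, , 1]
      Sig <- solve(Wdraw)
      ## covariate coefficient
      if (use_cov) {
        fit_c <- th[match(dat$country, ctys), 1] +
          th[match(dat$country, ctys), 2] * dat$t
        vv <- dat$se^2 + se2
        prec <- sum(dat$xcov^2 / vv) + 1 / spec$mean_sd^2
        mean_g <- sum(dat$xcov * (dat$logmean - fit_c) / vv) / prec
        gam <- stats::rnorm(1, mean_g, sqrt(1 / prec))
      }
      ## residual SD (Metropolis on log scale)
      fit_all <- th[match(dat$country, ctys), 1] +
        th[match(dat$country, ctys), 2] * dat$t + gam * dat$xcov
      lp_sig <- function(l) {
        s2 <- exp(2 * l)
        vv <- dat$se^2 + s2
        -0.5 * sum(log(vv) + (dat$logmean - fit_all)^2 / vv) -
          s2 / (2 * spec$sigma_scale^2) + l
      }
      prop <- lsig + stats::rnorm(1, 0, spec$mh_step)
      if (log(stats::runif(1)) < lp_sig(prop) - lp_sig(lsig)) lsig <- prop
      if (it > spec$warmup) {
        k <- it - spec$warmup
        A[k, , ch] <- th[, 1]; Bm[k, , ch] <- th[, 2]
        TH0[k, , ch] <- th0
        RHO[k, ch] <- Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2])
        GAM[k, ch] <- gam
        SIG[k, ch] <- exp(lsig)
        SIGMAT[k, , ch] <- c(Sig[1, 1], Sig[2, 2], Sig[1, 2])
      }
    }
  }
  flat <- function(a) if (length(dim(a)) == 3L)
    do.call(rbind, lapply(seq_len(dim(a)[3]), function(ch) a[, , ch]))
  else as.vector(a)
  a_d <- flat(A); b_d <- flat(Bm)
  colnames(a_d) <- colnames(b_d) <- ctys
  structure(list(spec = spec, countries = ctys, ref_year = ref_year,
                 data = dat, excluded = excluded, use_covariate = use_cov,
                 intercepts = a_d, slopes = b_d, pop_mean = flat(TH0),
                 rho = flat(RHO), gamma = flat(GAM), sigma = flat(SIG),
                 cov_elements = flat(SIGMAT)),
            class = "time_fit")
}

#' @export
print.time_fit <- function(x, ...) {
  cat("<time_fit>", length(x$countries), "countries; mean slope",
      signif(mean(x$pop_mean[, 2]), 3), "per year; rho",
      signif(mean(x$rho), 3), "\n")
  invisible(x)
}

#' Replace first-stage trends with time-model trends
#'
#' Adjusts a single-factor [posterior_intake()] draw-wise: for each
#' country-year and draw, the first-stage country-year mean log intake is
#' replaced by the time model's fitted value, preserving all within-country
#' stratum contrasts and the draw alignment. Countries excluded from the
#' time model (incomplete covariate series, or absent) keep their
#' first-stage draws.
#'
#' @param pred a single-factor [posterior_intake()].
#' @param tfit a [fit_time_model()] result.
#' @return adjusted [posterior_intake()].
#' @export
apply_time_adjustment <- function(pred, tfit) {
  stopifnot(inherits(pred, "posterior_intake"), inherits(tfit, "time_fit"))
  invisible(.country_year_series(pred))  # validates single factor
  lg <- log(pred$draws)
  idx <- pred$strata[, .(country, year)]
  skipped <- character(0)
  for (ct in unique(idx$country)) {
    if (!ct %in% tfit$countries) {
      skipped <- c(skipped, ct)
      next
    }
    for (yr in unique(idx$year[idx$country == ct])) {
      rows <- which(idx$country == ct & idx$year == yr)
      m <- colMeans(lg[rows, , drop = FALSE])
      xc <- if (tfit$use_covariate) {
        tfit$data[country == ct & year == yr, xcov][1]
      } else 0
      fitted <- tfit$intercepts[, ct] + tfit$slopes[, ct] * (yr - tfit$ref_year) +
        tfit$gamma * xc
      lg[rows, ] <- sweep(lg[rows, , drop = FALSE], 2L, fitted - m, `+`)
    }
  }
  if (length(skipped)) {
    message("kept first-stage estimates for: ", paste(skipped, collapse = ", "))
  }
  posterior_intake(pred$strata, exp(lg), standardized = pred$standardized)
}
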