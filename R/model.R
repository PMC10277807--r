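## Hierarchical Bayesian model for stratum-level log-mean intakes.
##
## Observation model, per survey record i of one dietary factor:
##   log(observed_mean_i) + v_i/2 ~ N(mu_i + eta_{s(i)}, v_i)
##   mu_i = x_i' beta + region(i) + country(i)
##   v_i  = observed_sd_i^2 / (n_i * observed_mean_i^2)   (delta method;
##          the +v_i/2 term removes the second-order log-transform bias)
##   eta_s ~ N(0, tau0^2 + omega^2 * flagged_s)   (study-level effect)
## where flagged surveys are those that are not representative or not fully
## stratified; omega is the overdispersion excess of the study-level
## variance for such surveys. Fixed effects x: intercept, sex, education
## (2), urbanicity, natural cubic spline of age-band midpoint,
## assessment-method indicators (24h recall as reference) and the
## country-year availability covariate. Region and country intercepts are
## mean-zero normal random effects with half-normal priors on their SDs.
## Records with collapsed strata enter as population-weighted averages of
## the constituent strata's linear predictors.
##
## The sampler is a blocked Gibbs: all location effects are drawn jointly
## from their multivariate-normal full conditional (observation variances
## are known), study effects have conjugate univariate normal conditionals,
## and the four scale parameters (region SD, country SD, study SD,
## overdispersion excess SD) are updated by random-walk Metropolis on the
## log scale.

#' Intake model specification
#'
#' @param chains,warmup,draws_per_chain MCMC layout. The retained total
#'   `chains * draws_per_chain` must equal 4,000, the draw count carried by
#'   every downstream stage.
#' @param beta_sd prior SD of the weakly-informative normal prior on fixed
#'   effects (log scale).
#' @param sigma_region_scale,sigma_country_scale half-normal prior scales of
#'   the region and country random-effect SDs.
#' @param tau_scale half-normal prior scale of the baseline study-level SD.
#' @param od_scale half-normal prior scale of the overdispersion excess SD
#'   added (in variance) to the study-level term of surveys that are not
#'   representative or not fully stratified.
#' @param use_covariate include the country-year availability covariate as a
#'   fixed effect.
#' @param min_obs_var floor on the observation-level variance (log scale).
#' @param mh_step random-walk Metropolis step (log scale) for the scale
#'   parameters.
#' @param rhat_limit split-R-hat threshold above which non-convergence is
#'   flagged with a warning.
#' @param seed integer seed; per-factor, per-chain streams are derived.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(chains = 4L, warmup = 1000L, draws_per_chain = 1000L,
                       beta_sd = 10, sigma_region_scale = 1,
                       sigma_country_scale = 1, tau_scale = 0.3,
                       od_scale = 0.5, use_covariate = TRUE,
                       min_obs_var = 1e-8, mh_step = 0.3,
                       rhat_limit = 1.05, seed = 1L) {
  if (chains * draws_per_chain != N_DRAWS) {
    stop(sprintf("chains * draws_per_chain must equal %d retained draws",
                 N_DRAWS))
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws_per_chain = as.integer(draws_per_chain),
                 beta_sd = beta_sd, sigma_region_scale = sigma_region_scale,
                 sigma_country_scale = sigma_country_scale,
                 tau_scale = tau_scale, od_scale = od_scale,
                 use_covariate = isTRUE(use_covariate),
                 min_obs_var = min_obs_var, mh_step = mh_step,
                 rhat_limit = rhat_limit, seed = as.integer(seed)),
            class = "model_spec")
}

## fixed-effect design matrix for fully specified strata rows
## (sex, age_mid, education, urbanicity, method or NA, covariate value)
.fixed_design <- function(dt, use_covariate) {
  B <- age_spline_basis(dt$age_mid)
  X <- cbind(
    intercept = 1,
    sex_female = as.numeric(dt$sex == "female"),
    edu_mid = as.numeric(dt$education == "6-<12y"),
    edu_high = as.numeric(dt$education == ">=12y"),
    urban = as.numeric(dt$urbanicity == "urban"),
    B
  )
  colnames(X)[6:(5 + ncol(B))] <- paste0("age", seq_len(ncol(B)))
  for (m in METHOD_LEVELS[-1]) {
    X <- cbind(X, as.numeric(!is.na(dt$method) & dt$method == m))
    colnames(X)[ncol(X)] <- paste0("m_", m)
  }
  if (use_covariate) {
    X <- cbind(X, covariate = dt$covariate)
  }
  X
}

## full design (fixed + region + country indicator columns); records with NA
## stratum dimensions are expanded over the collapsed levels and averaged
## with population weights (equal weights if none supplied)
.record_design <- function(recs, regions, covariates, weights, use_covariate,
                           factor_name) {
  recs <- copy(recs)
  recs[, .row := .I]
  full <- recs[, {
    edu <- if (is.na(education)) EDU_LEVELS else education
    urb <- if (is.na(urbanicity)) URB_LEVELS else urbanicity
    CJ(education = edu, urbanicity = urb)
  }, by = .(.row, survey_id, country, year, method, sex, age_group)]
  ab <- age_bands()
  full[, age_mid := ab$age_mid[match(age_group, ab$age_group)]]
  if (!is.null(weights)) {
    full <- merge(full,
                  weights[, .(country, year, sex, age_group, education,
                              urbanicity, persons)],
                  by = c("country", "year", "sex", "age_group", "education",
                         "urbanicity"), all.x = TRUE, sort = FALSE)
    full[is.na(persons), persons := 1]
  } else {
    full[, persons := 1]
  }
  if (use_covariate) {
    full <- merge(full, covariates[factor == factor_name,
                                   .(country, year, covariate = value)],
                  by = c("country", "year"), all.x = TRUE, sort = FALSE)
    if (anyNA(full$covariate)) {
      stop("missing covariate value for some country-years of factor ",
           factor_name)
    }
  }
  setorder(full, .row)
  X <- .fixed_design(full, use_covariate)
  reg_levels <- sort(unique(regions$region))
  cty_levels <- sort(unique(regions$country))
  reg_of <- regions$region[match(full$country, regions$country)]
  Zr <- outer(reg_of, reg_levels, `==`) * 1
  Zc <- outer(full$country, cty_levels, `==`) * 1
  colnames(Zr) <- paste0("r_", reg_levels)
  colnames(Zc) <- paste0("c_", cty_levels)
  M <- cbind(X, Zr, Zc)
  ## weighted average of constituent rows per record (log-scale linkage)
  wsum <- rowsum(full$persons, full$.row)
  Mw <- rowsum(M * full$persons, full$.row) / as.vector(wsum)
  list(M = Mw,
       n_fixed = ncol(X), n_region = length(reg_levels),
       n_country = length(cty_levels),
       reg_levels = reg_levels, cty_levels = cty_levels)
}

## split-R-hat and a simple initial-monotone-sequence effective sample size
.split_rhat <- function(a) {  # a: iterations x chains
  n <- nrow(a) %/% 2L
  s <- cbind(a[seq_len(n), , drop = FALSE],
             a[n + seq_len(n), , drop = FALSE])
  m <- ncol(s)
  mu <- colMeans(s)
  B <- n * stats::var(mu)
  W <- mean(apply(s, 2, stats::var))
  if (W < 1e-300) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) < 1e-300) return(n)
  ac <- stats::acf(x, lag.max = min(100L, n - 1L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' Fit the hierarchical intake model to survey records
#'
#' Fits one model per dietary factor present in `records` (a factor with no
#' records yields an explicit `"no_data"` entry, never a silent estimate).
#' Monitors split-R-hat on every parameter and warns when any exceeds the
#' spec's limit.
#'
#' @param records survey records (as from [simulate_surveys()] or
#'   [read_surveys()]).
#' @param spec a [model_spec()].
#' @param regions country-to-region membership table (`country`, `region`);
#'   must cover every country in `records`.
#' @param covariates country-year covariate table (`country`, `year`,
#'   `factor`, `value`); required when `spec$use_covariate`.
#' @param weights population weights used to link collapsed-stratum records
#'   to their constituent strata (equal weights if `NULL`).
#' @param factors subset of factors to fit (default: all in `records`).
#' @return object of class `intake_fit`.
#' @export
fit_intake_model <- function(records, spec = model_spec(), regions,
                             covariates = NULL, weights = NULL,
                             factors = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  records <- copy(as.data.table(records))
  regions <- as.data.table(regions)
  if (!"collapsed" %in% names(records)) {
    records[, collapsed := fifelse(is.na(education) | is.na(urbanicity),
                                   "some", "")]
  }
  missing_reg <- setdiff(unique(records$country), regions$country)
  if (length(missing_reg)) {
    stop("region membership unknown for country: ",
         paste(missing_reg, collapse = ", "))
  }
  if (spec$use_covariate && is.null(covariates)) {
    stop("spec includes the availability covariate but none was supplied")
  }
  if (!is.null(covariates)) covariates <- as.data.table(covariates)
  if (!is.null(weights)) weights <- as.data.table(weights)
  factors <- factors %||% unique(records$factor)

  fits <- list()
  units <- list()
  for (f in factors) {
    recs <- records[factor == f]
    if (nrow(recs) == 0L) {
      fits[[f]] <- list(status = "no_data")
      next
    }
    units[[f]] <- recs$unit[1] %||% NA_character_
    des <- .record_design(recs, regions, covariates, weights,
                          spec$use_covariate, f)
    v <- pmax(recs$observed_sd^2 / (recs$n * recs$observed_mean^2),
              spec$min_obs_var)
    ## pool observation variances within survey: records of one survey share
    ## n and the within-population CV, and per-record estimated variances
    ## would bias inverse-variance weights (low sample means come with low
    ## sample SDs in skewed intake data)
    v <- stats::ave(v, recs$survey_id)
    ## second-order delta method: E[log(xbar)] = log(mu) - Var(xbar)/(2 mu^2)
    y <- log(recs$observed_mean) + v / 2
    flagged <- !recs$representative | !is.na(recs$collapsed) &
      nzchar(recs$collapsed)
    fits[[f]] <- c(.gibbs_fit(y, v, des$M, flagged, recs$survey_id, des,
                              spec, f),
                   list(status = "ok", unit = units[[f]], design = des))
  }
  structure(list(spec = spec, regions = regions, covariates = covariates,
                 weights = weights, fits = fits),
            class = "intake_fit")
}

.gibbs_fit <- function(y, v, M, flagged, survey_id, des, spec, factor_name) {
  p <- ncol(M)
  surveys <- unique(survey_id)
  ns <- length(surveys)
  sidx <- match(survey_id, surveys)
  sflag <- as.logical(rowsum(as.numeric(flagged), sidx) > 0)
  ## augment the design with survey indicator columns: location effects and
  ## study effects are drawn as one Gaussian block, which decorrelates the
  ## method coefficients from the study effects of flagged surveys
  Z <- matrix(0, nrow(M), ns)
  Z[cbind(seq_len(nrow(M)), sidx)] <- 1
  Maug <- cbind(M, Z)
  paug <- p + ns
  A <- crossprod(Maug / sqrt(v))
  r <- as.vector(crossprod(Maug, y / v))
  reg_idx <- des$n_fixed + seq_len(des$n_region)
  cty_idx <- des$n_fixed + des$n_region + seq_len(des$n_country)
  eta_idx <- p + seq_len(ns)

  nkeep <- spec$draws_per_chain
  B <- array(NA_real_, c(nkeep, p, spec$chains))
  S <- array(NA_real_, c(nkeep, 4L, spec$chains))
  lp_scale <- function(lsig, eff, hn_scale) {
    sig <- exp(lsig)
    -length(eff) * lsig - sum(eff^2) / (2 * sig^2) -
      sig^2 / (2 * hn_scale^2) + lsig
  }
  for (ch in seq_len(spec$chains)) {
    set.seed(derive_seed(spec$seed, paste0("fit|", factor_name, "|", ch)))
    lsr <- log(abs(stats::rnorm(1, 0, 0.3)) + 0.05)
    lsc <- log(abs(stats::rnorm(1, 0, 0.3)) + 0.05)
    ltau <- log(abs(stats::rnorm(1, 0, 0.05)) + 0.01)
    lom <- log(abs(stats::rnorm(1, 0, 0.1)) + 0.02)
    for (it in seq_len(spec$warmup + nkeep)) {
      sr <- exp(lsr); sc <- exp(lsc)
      tau2 <- exp(2 * ltau); om2 <- exp(2 * lom)
      svar <- tau2 + om2 * sflag
      prior_prec <- c(rep(1 / spec$beta_sd^2, des$n_fixed),
                      rep(1 / sr^2, des$n_region),
                      rep(1 / sc^2, des$n_country),
                      1 / svar)
      Q <- A
      diag(Q) <- diag(Q) + prior_prec
      R <- chol(Q)
      mu <- backsolve(R, forwardsolve(t(R), r))
      ball <- mu + backsolve(R, stats::rnorm(paug))
      b <- ball[seq_len(p)]
      eta <- ball[eta_idx]
      ## scale parameters: a few random-walk sub-steps each per scan
      lp_study <- function(lt, lo) {
        t2 <- exp(2 * lt); o2 <- exp(2 * lo)
        sv <- t2 + o2 * sflag
        -0.5 * sum(log(sv) + eta^2 / sv) -
          t2 / (2 * spec$tau_scale^2) - o2 / (2 * spec$od_scale^2) +
          lt + lo
      }
      for (sub in seq_len(3L)) {
        prop <- lsr + stats::rnorm(1, 0, spec$mh_step)
        if (log(stats::runif(1)) < lp_scale(prop, b[reg_idx], spec$sigma_region_scale) -
              lp_scale(lsr, b[reg_idx], spec$sigma_region_scale)) lsr <- prop
        prop <- lsc + stats::rnorm(1, 0, spec$mh_step)
        if (log(stats::runif(1)) < lp_scale(prop, b[cty_idx], spec$sigma_country_scale) -
              lp_scale(lsc, b[cty_idx], spec$sigma_country_scale)) lsc <- prop
        prop <- ltau + stats::rnorm(1, 0, spec$mh_step)
        if (log(stats::runif(1)) < lp_study(prop, lom) - lp_study(ltau, lom)) {
          ltau <- prop
        }
        prop <- lom + stats::rnorm(1, 0, spec$mh_step)
        if (log(stats::runif(1)) < lp_study(ltau, prop) - lp_study(ltau, lom)) {
          lom <- prop
        }
      }
      if (it > spec$warmup) {
        k <- it - spec$warmup
        B[k, , ch] <- b
        S[k, , ch] <- c(exp(lsr), exp(lsc), exp(ltau), exp(lom))
      }
    }
  }
  par_names <- colnames(M)
  draws <- do.call(rbind, lapply(seq_len(spec$chains), function(ch) B[, , ch]))
  colnames(draws) <- par_names
  sdraws <- do.call(rbind, lapply(seq_len(spec$chains), function(ch) S[, , ch]))
  colnames(sdraws) <- c("sigma_region", "sigma_country", "tau_study",
                        "od_excess")
  rhat <- c(vapply(seq_len(p), function(j) .split_rhat(B[, j, ]), 0),
            vapply(1:4, function(j) .split_rhat(S[, j, ]), 0))
  ess <- c(vapply(seq_len(p), function(j) .ess(as.vector(B[, j, ])), 0),
           vapply(1:4, function(j) .ess(as.vector(S[, j, ])), 0))
  diag_dt <- data.table(param = c(par_names, colnames(sdraws)),
                        rhat = rhat, ess = ess)
  if (any(diag_dt$rhat > spec$rhat_limit, na.rm = TRUE)) {
    warning(sprintf("factor %s: split-R-hat above %.2f for: %s",
                    factor_name, spec$rhat_limit,
                    paste(diag_dt[rhat > spec$rhat_limit, param],
                          collapse = ", ")), call. = FALSE)
  }
  list(draws = draws, scale_draws = sdraws, diagnostics = diag_dt,
       n_records = length(y))
}

#' @export
print.intake_fit <- function(x, ...) {
  ok <- names(Filter(function(f) identical(f$status, "ok"), x$fits))
  nd <- setdiff(names(x$fits), ok)
  cat("<intake_fit>", length(ok), "factor(s) fitted,",
      length(nd), "without data\n")
  for (f in ok) {
    d <- x$fits[[f]]$diagnostics
    cat(sprintf("  %-20s records %4d  max R-hat %.3f\n", f,
                x$fits[[f]]$n_records, max(d$rhat, na.rm = TRUE)))
  }
  invisible(x)
}
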