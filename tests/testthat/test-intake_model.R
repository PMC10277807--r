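## records for a single country/stratum with known mean, used for the
## conjugate-limit checks
flat_records <- function(n_surveys = 30L, mean_log = log(5), sd_obs = 0.1,
                         seed = 4, observed_sd = 2, n = 400L) {
  set.seed(seed)
  data.table::data.table(
    survey_id = sprintf("X%03d", seq_len(n_surveys)),
    country = "C01", year = 2018, method = "24hr_recall",
    representative = TRUE, sex = "male", age_group = "30-34",
    education = "<6y", urbanicity = "rural", collapsed = "",
    factor = "fruit", unit = "servings/day",
    observed_mean = exp(rnorm(n_surveys, mean_log, sd_obs)),
    observed_sd = observed_sd, n = n
  )
}

one_region <- data.table::data.table(country = "C01", region = "R01")

test_that("flat single-stratum posterior matches the sample log-mean", {
  recs <- flat_records()
  fit <- suppressWarnings(
    fit_intake_model(recs, model_spec(use_covariate = FALSE, seed = 2),
                     one_region)
  )
  pred <- predict_strata(fit, data.table::data.table(country = "C01",
                                                     year = 2018))
  lg <- log(pred$draws[pred$strata$sex == "male" &
                         pred$strata$age_group == "30-34" &
                         pred$strata$education == "<6y" &
                         pred$strata$urbanicity == "rural", ])
  v <- recs$observed_sd^2 / (recs$n * recs$observed_mean^2)
  y <- log(recs$observed_mean) + v / 2
  mc_se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(lg) - mean(y)), 2 * mc_se)
})

test_that("posterior summaries agree with an independent MCMC engine", {
  ## same likelihood and priors expressed in JAGS, run on the identical
  ## design matrix; posterior means of stratum log-intakes must agree
  library(rjags)
  w <- tiny_world()
  recs <- tiny_records()[factor == "fruit" &
                           age_group %in% c("5-9", "30-34", "60-64") &
                           (is.na(education) | education == "<6y") &
                           (is.na(urbanicity) | urbanicity == "urban")]
  spec <- model_spec(seed = 3)
  fit <- suppressWarnings(
    fit_intake_model(recs, spec, w$regions, w$covariates, w$weights)
  )
  ff <- fit$fits$fruit
  M <- ff$design$M
  v <- pmax(recs$observed_sd^2 / (recs$n * recs$observed_mean^2),
            spec$min_obs_var)
  v <- ave(v, recs$survey_id)
  y <- log(recs$observed_mean) + v / 2
  sid <- match(recs$survey_id, unique(recs$survey_id))
  fl <- as.numeric(tapply(!recs$representative | nzchar(recs$collapsed),
                          sid, any)[as.character(seq_len(max(sid)))])
  pf <- ff$design$n_fixed
  nr <- ff$design$n_region
  nc <- ff$design$n_country
  jm <- "model {
    for (i in 1:N) {
      y[i] ~ dnorm(inprod(M[i,], b) + eta[s[i]], 1 / v[i])
    }
    for (j in 1:pf) { b[j] ~ dnorm(0, 0.01) }
    for (j in (pf+1):(pf+nr)) { b[j] ~ dnorm(0, 1 / (sr * sr)) }
    for (j in (pf+nr+1):(pf+nr+nc)) { b[j] ~ dnorm(0, 1 / (sc * sc)) }
    for (k in 1:S) { eta[k] ~ dnorm(0, 1 / (tau*tau + om*om*fl[k])) }
    sr ~ dnorm(0, 1) T(0,)
    sc ~ dnorm(0, 1) T(0,)
    tau ~ dnorm(0, 1 / 0.09) T(0,)
    om ~ dnorm(0, 1 / 0.25) T(0,)
  }"
  jags <- jags.model(textConnection(jm),
                     data = list(N = nrow(M), M = M, y = y, v = v, s = sid,
                                 S = max(sid), fl = fl, pf = pf, nr = nr,
                                 nc = nc),
                     n.chains = 2, quiet = TRUE, inits = list(
                       list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 1),
                       list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 2)))
  update(jags, 1500)
  samp <- coda.samples(jags, "b", n.iter = 3000)
  bj <- do.call(rbind, lapply(samp, as.matrix))
  ## compare posterior mean linear predictors for a handful of strata
  tgt <- stratum_grid()[age_group %in% c("5-9", "30-34", "60-64") &
                          education == "<6y" & urbanicity == "urban"]
  tgt[, `:=`(method = NA_character_,
             covariate = w$covariates[country == "C01" & year == 2018 &
                                        factor == "fruit", value])]
  X <- dietquality:::.fixed_design(tgt, TRUE)
  Xa <- cbind(X, outer(rep("R01", nrow(X)), ff$design$reg_levels, `==`) * 1,
              outer(rep("C01", nrow(X)), ff$design$cty_levels, `==`) * 1)
  mine <- as.vector(Xa %*% colMeans(ff$draws))
  theirs <- as.vector(Xa %*% colMeans(bj))
  ## both are finite MCMC runs with slow-mixing scale hyperparameters;
  ## 0.02 on the log scale (~2% intake) is well inside the posterior SD
  expect_lt(max(abs(mine - theirs)), 0.02)
  mine_sd <- apply(Xa %*% t(ff$draws), 1, sd)
  theirs_sd <- apply(Xa %*% t(bj), 1, sd)
  expect_true(all(mine_sd / theirs_sd > 0.7 & mine_sd / theirs_sd < 1.4))
})

test_that("draw summaries follow the documented percentile convention", {
  stub <- (1:4000) / 100
  s <- draw_summary(stub)
  o <- sort_percentile_oracle(sample(stub), c(0.5, 0.025, 0.975))
  expect_identical(unname(s), o)
  expect_equal(unname(s["median"]), 20.005)
  expect_equal(unname(s["ui_low"]), 1.00025)
  expect_equal(unname(s["ui_high"]), 39.00975)
  ## property: agreement with the sort oracle on random draws, exactly
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(4000)
    expect_equal(unname(draw_summary(x)),
                 sort_percentile_oracle(x, c(0.5, 0.025, 0.975)),
                 tolerance = 1e-15)
  }
})

test_that("predictions cover all 264 strata with 4000 positive draws", {
  fit <- tiny_fit()
  tg <- data.table::data.table(country = c("C01", "C03"), year = 2018)
  pred <- predict_strata(fit, tg, factors = "fruit")
  cnt <- pred$strata[, .N, by = .(country, year, factor)]
  expect_true(all(cnt$N == 264L))
  expect_equal(ncol(pred$draws), 4000L)
  expect_true(all(pred$draws > 0))
  s <- summary(pred)
  expect_true(all(s$ui_low <= s$median & s$median <= s$ui_high))
})

test_that("a degenerate posterior yields identical draws and zero-width UI", {
  fit <- tiny_fit()
  fit$fits$fruit$draws <-
    matrix(colMeans(fit$fits$fruit$draws), 4000,
           ncol(fit$fits$fruit$draws),
           byrow = TRUE, dimnames = list(NULL,
                                         colnames(fit$fits$fruit$draws)))
  pred <- predict_strata(fit, data.table::data.table(country = "C01",
                                                     year = 2018),
                         factors = "fruit")
  expect_equal(apply(pred$draws, 1, function(r) max(r) - min(r)),
               rep(0, 264))
  s <- summary(pred)
  expect_equal(s$ui_high - s$ui_low, rep(0, 264))
})

test_that("adding data at a stratum does not inflate its posterior variance", {
  w <- tiny_world()
  base <- tiny_records()[factor == "fruit"]
  extra <- flat_records(n_surveys = 30L, sd_obs = 0.02,
                        observed_sd = 0.5, n = 2000L,
                        mean_log = log(true_stratum_means(
                          w, "C01", 2018, "fruit")[sex == "male" &
                              age_group == "30-34" & education == "<6y" &
                              urbanicity == "rural", true_mean]))
  fit1 <- suppressWarnings(fit_intake_model(base, model_spec(seed = 9),
                                            w$regions, w$covariates,
                                            w$weights))
  fit2 <- suppressWarnings(fit_intake_model(rbind(base, extra),
                                            model_spec(seed = 9),
                                            w$regions, w$covariates,
                                            w$weights))
  get_var <- function(fit) {
    pred <- predict_strata(fit, data.table::data.table(country = "C01",
                                                       year = 2018),
                           factors = "fruit")
    i <- which(pred$strata$sex == "male" & pred$strata$age_group == "30-34" &
                 pred$strata$education == "<6y" &
                 pred$strata$urbanicity == "rural")
    var(log(pred$draws[i, ]))
  }
  expect_lt(get_var(fit2), get_var(fit1) * 1.10)
})

test_that("a country with no data inherits the region-level prediction", {
  w <- tiny_world()
  recs <- tiny_records()[factor == "fruit" & country != "C02"]
  fit <- suppressWarnings(fit_intake_model(recs, model_spec(seed = 12),
                                           w$regions, w$covariates,
                                           w$weights))
  pred <- predict_strata(fit, data.table::data.table(
    country = c("C01", "C02"), year = 2018), factors = "fruit")
  lg <- log(pred$draws)
  ## C02 (no data, same region R01 as C01) must carry extra country-level
  ## spread around the region mean rather than collapse to C01
  v1 <- mean(apply(lg[pred$strata$country == "C01", ], 1, var))
  v2 <- mean(apply(lg[pred$strata$country == "C02", ], 1, var))
  expect_gt(v2, v1)
  ## its country effect is the prior given sigma_country: centred at zero
  ce <- fit$fits$fruit$draws[, "c_C02"]
  expect_lt(abs(mean(ce)) / sd(ce), 0.2)
  sc <- fit$fits$fruit$scale_draws[, "sigma_country"]
  expect_equal(sd(ce) / sqrt(mean(sc^2)), 1, tolerance = 0.25)
  ## a country absent from the region map needs its region, and warns
  expect_error(predict_strata(fit, data.table::data.table(
    country = "C99", year = 2018), factors = "fruit"), "region")
  expect_warning(p99 <- predict_strata(fit, data.table::data.table(
    country = "C99", year = 2018, region = "R01"), factors = "fruit"),
    "falling back")
  expect_equal(nrow(p99$strata), 264L)
})

test_that("empty factors and non-convergence are reported, never silent", {
  w <- tiny_world()
  recs <- tiny_records()[factor == "fruit"]
  fit <- suppressWarnings(
    fit_intake_model(recs, model_spec(seed = 2), w$regions, w$covariates,
                     w$weights, factors = c("fruit", "sodium"))
  )
  expect_identical(fit$fits$sodium$status, "no_data")
  expect_error(predict_strata(fit, data.table::data.table(country = "C01",
                                                          year = 2018),
                              factors = "sodium"), "no fitted estimate")
  ## an absurdly strict R-hat limit must trigger the non-convergence flag
  expect_warning(
    fit_intake_model(flat_records(n_surveys = 8L),
                     model_spec(use_covariate = FALSE, rhat_limit = 1.0000001,
                                seed = 5),
                     one_region),
    "split-R-hat")
})
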