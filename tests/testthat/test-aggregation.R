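## brute-force draw-by-draw oracle built independently of the package's
## vectorized path
oracle_weighted_mean <- function(draws, w) {
  vapply(seq_len(ncol(draws)), function(d) {
    sum(draws[, d] * w) / sum(w)
  }, numeric(1))
}

make_score <- function(draws, g = NULL, year = 2018, country = "C01",
                       pattern = "AHEI") {
  if (is.null(g)) g <- stratum_grid(with_age_mid = FALSE)[seq_len(nrow(draws))]
  structure(list(
    strata = data.table::data.table(country = country, year = year, g,
                                    pattern = pattern),
    draws = draws, components = list(),
    definition = score_definition(pattern, list())),
    class = "stratum_score")
}

test_that("weighted aggregation of constants is the weighted mean, UI width 0", {
  g <- stratum_grid(with_age_mid = FALSE)[1:2]
  sc <- make_score(matrix(c(40, 20), 2, 4000))
  w <- flat_weights()
  w[paste(sex, age_group, education, urbanicity) %in%
      paste(g$sex, g$age_group, g$education, g$urbanicity),
    persons := c(0.75, 0.25)]
  est <- aggregate_scores(sc, w, scope = "global")
  expect_equal(est$median, 35)
  expect_equal(est$ui_low, 35)
  expect_equal(est$ui_high, 35)
})

test_that("single-stratum aggregate equals the stratum's own summary", {
  set.seed(2)
  d <- matrix(rnorm(4000, 50, 5), 1, 4000)
  sc <- make_score(d)
  est <- aggregate_scores(sc, flat_weights(), scope = "country")
  s <- draw_summary(d[1, ])
  expect_equal(est$median, unname(s["median"]))
  expect_equal(est$ui_low, unname(s["ui_low"]))
  expect_equal(est$ui_high, unname(s["ui_high"]))
})

test_that("aggregation matches the brute-force oracle on random instances", {
  set.seed(31)
  for (rep_i in 1:3) {
    n <- 50L
    g <- stratum_grid(with_age_mid = FALSE)[sample(264, n)]
    draws <- matrix(rnorm(n * 4000, 40, 10), n, 4000)
    sc <- make_score(draws, g)
    w <- flat_weights()
    w <- merge(w, data.table::data.table(g, p2 = runif(n, 0.1, 5)),
               by = c("sex", "age_group", "education", "urbanicity"),
               all.x = TRUE)
    w[!is.na(p2), persons := p2]
    est <- aggregate_scores(sc, w, scope = "global", return_draws = TRUE)
    agg <- attr(est, "draws")[[1]]
    wv <- w[paste(sex, age_group, education, urbanicity) %in%
              paste(g$sex, g$age_group, g$education, g$urbanicity)]
    wv <- wv[match(paste(g$sex, g$age_group, g$education, g$urbanicity),
                   paste(sex, age_group, education, urbanicity)), persons]
    expect_equal(agg, oracle_weighted_mean(draws, wv), tolerance = 1e-12)
    o <- sort_percentile_oracle(agg, c(0.5, 0.025, 0.975))
    expect_equal(c(est$median, est$ui_low, est$ui_high), o,
                 tolerance = 1e-12)
  }
})

test_that("aggregates are invariant to weight rescaling and hierarchically consistent", {
  set.seed(8)
  yrs <- 2018
  g <- stratum_grid(with_age_mid = FALSE)
  countries <- c("C01", "C02", "C03")
  regions <- c("R01", "R01", "R02")
  sc_strata <- data.table::rbindlist(lapply(countries, function(cc) {
    data.table::data.table(country = cc, year = yrs, g, pattern = "X")
  }))
  draws <- matrix(rnorm(nrow(sc_strata) * 4000, 30, 8), nrow(sc_strata))
  sc <- structure(list(strata = sc_strata, draws = draws,
                       components = list(),
                       definition = score_definition("X", list())),
                  class = "stratum_score")
  w <- data.table::rbindlist(lapply(seq_along(countries), function(i) {
    out <- data.table::data.table(country = countries[i], year = yrs, g,
                                  persons = runif(264, 0.5, 3))
    out[, region := regions[i]]
    out
  }))
  glob <- aggregate_scores(sc, w, scope = "global", return_draws = TRUE)
  w2 <- data.table::copy(w)[, persons := persons * 7.3]
  glob2 <- aggregate_scores(sc, w2, scope = "global", return_draws = TRUE)
  expect_equal(attr(glob, "draws")[[1]], attr(glob2, "draws")[[1]],
               tolerance = 1e-12)
  ## global equals the population-weighted mean of regional aggregates,
  ## draw by draw, exactly
  reg <- aggregate_scores(sc, w, scope = "region", return_draws = TRUE)
  regw <- w[, .(persons = sum(persons)), by = region][order(region)]
  rd <- attr(reg, "draws")
  rebuilt <- (rd[[1]] * regw$persons[1] + rd[[2]] * regw$persons[2]) /
    sum(regw$persons)
  expect_equal(rebuilt, attr(glob, "draws")[[1]], tolerance = 1e-12)
})

test_that("group contrasts match the pairwise oracle and are antisymmetric", {
  set.seed(13)
  g <- stratum_grid(with_age_mid = FALSE)
  draws <- matrix(rnorm(264 * 4000, 40, 6), 264, 4000)
  sc <- make_score(draws, g)
  w <- flat_weights()
  w[, persons := runif(.N, 0.2, 2)]
  est <- contrast_groups(sc, w, "education", scope = "global",
                         return_draws = TRUE)
  d <- attr(est, "draws")[[1]]
  ## oracle: match (sex, age, urbanicity) cells, diff draws, weight by
  ## summed persons
  hi <- which(g$education == ">=12y")
  lo <- which(g$education == "<6y")
  key <- paste(g$sex, g$age_group, g$urbanicity)
  lo <- lo[match(key[hi], key[lo])]
  wv <- w[match(paste(g$sex, g$age_group, g$education, g$urbanicity),
                paste(sex, age_group, education, urbanicity)), persons]
  o <- oracle_weighted_mean(draws[hi, ] - draws[lo, ], wv[hi] + wv[lo])
  expect_equal(d, o, tolerance = 1e-12)
  ## swapping the levels negates the estimate draw-wise
  est_r <- contrast_groups(sc, w, "education", levels = c("<6y", ">=12y"),
                           scope = "global", return_draws = TRUE)
  expect_equal(attr(est_r, "draws")[[1]], -d, tolerance = 1e-12)
  ## a uniform +3 shift is recovered exactly with zero UI width
  draws2 <- draws
  draws2[hi, ] <- draws2[lo, ] + 3
  est3 <- contrast_groups(make_score(draws2, g), w, "education")
  expect_equal(est3$median, 3)
  expect_equal(est3$ui_high - est3$ui_low, 0)
  ## identical groups give exactly zero
  draws2[hi, ] <- draws2[lo, ]
  est0 <- contrast_groups(make_score(draws2, g), w, "education")
  expect_equal(est0$median, 0)
})

test_that("time changes are 2018-standardized, draw-wise, oracle-exact", {
  set.seed(17)
  g <- stratum_grid(with_age_mid = FALSE)
  strata <- data.table::rbindlist(lapply(c(1990, 2018), function(yr) {
    data.table::data.table(country = "C01", year = yr, g, pattern = "X")
  }))
  d90 <- matrix(rnorm(264 * 4000, 38, 5), 264)
  d18 <- matrix(rnorm(264 * 4000, 40, 5), 264)
  sc <- structure(list(strata = strata, draws = rbind(d90, d18),
                       components = list(),
                       definition = score_definition("X", list())),
                  class = "stratum_score")
  w <- data.table::rbindlist(lapply(c(1990, 2018), function(yr) {
    out <- data.table::data.table(country = "C01", year = yr, g)
    out[, persons := if (yr == 1990) runif(264, 1, 2) else runif(264, 1, 2)]
    out
  }))
  est <- change_over_time(sc, w, scope = "global", return_draws = TRUE)
  w18 <- w[year == 2018]
  wv <- w18[match(paste(g$sex, g$age_group, g$education, g$urbanicity),
                  paste(sex, age_group, education, urbanicity)), persons]
  o <- oracle_weighted_mean(d18 - d90, wv)
  expect_equal(attr(est, "draws")[[1]], o, tolerance = 1e-12)
  ## constant +1.5 shift is recovered regardless of weights
  sc2 <- sc
  sc2$draws <- rbind(d90, d90 + 1.5)
  est2 <- change_over_time(sc2, w)
  expect_equal(est2$median, 1.5)
  expect_equal(est2$ui_high - est2$ui_low, 0)
  ## identical scores across years give exactly zero change
  sc3 <- sc
  sc3$draws <- rbind(d90, d90)
  expect_equal(change_over_time(sc3, w)$median, 0)
  ## demographic drift alone is removed by 2018 standardization, while a
  ## naive crude-mean comparison would report spurious change
  w_shift <- data.table::copy(w)
  w_shift[year == 1990, persons := rev(persons)]
  est4 <- change_over_time(sc3, w_shift)
  expect_equal(est4$median, 0)
  crude90 <- oracle_weighted_mean(d90, w_shift[year == 1990,
    persons][match(paste(g$sex, g$age_group, g$education, g$urbanicity),
                   paste(w_shift[year == 1990, sex],
                         w_shift[year == 1990, age_group],
                         w_shift[year == 1990, education],
                         w_shift[year == 1990, urbanicity]))])
  crude18 <- oracle_weighted_mean(d90, wv)
  expect_gt(max(abs(crude18 - crude90)), 0.01)
})

test_that("score correlations follow rank invariance and the rank oracle", {
  set.seed(23)
  n <- 200L
  g <- stratum_grid(with_age_mid = FALSE)[rep(1:264, length.out = n)]
  g <- unique(data.table::data.table(g,
    country = rep(sprintf("C%02d", 1:4), each = 50)))[1:n]
  dA <- matrix(rnorm(n * 4000, 40, 8), n)
  mkp <- function(d, pat) {
    structure(list(strata = data.table::data.table(
      country = g$country, year = 2018,
      g[, .(sex, age_group, education, urbanicity)], pattern = pat),
      draws = d, components = list(),
      definition = score_definition(pat, list())),
      class = "stratum_score")
  }
  ## monotone transform: rho exactly 1; negation: exactly -1
  r <- score_correlations(list(mkp(dA, "A"), mkp(exp(dA / 10), "B"),
                               mkp(-dA, "C")))
  expect_equal(r["A", "B"], 1)
  expect_equal(r["A", "C"], -1)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))
  ## random scores match a rank-then-Pearson oracle
  dB <- matrix(rnorm(n * 4000, 25, 4), n)
  r2 <- score_correlations(list(mkp(dA, "A"), mkp(dB, "B")))
  mA <- apply(dA, 1, median)
  mB <- apply(dB, 1, median)
  expect_equal(r2["A", "B"], cor(rank(mA), rank(mB)), tolerance = 1e-12)
  ## fewer than 3 strata is undefined
  g2 <- stratum_grid(with_age_mid = FALSE)[1:2]
  expect_error(score_correlations(list(make_score(dA[1:2, ], g2, pattern = "A"),
                                       make_score(dB[1:2, ], g2, pattern = "B"))),
               "at least 3")
})
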