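## Population-weighted aggregation of draw-level stratum scores to country,
## regional and global estimates, subgroup contrasts and 1990->2018 changes.
## All differences are formed draw-wise at the stratum level before
## summarizing, so the 95% UIs reflect the correlated uncertainty within
## each joint posterior draw.

.filter_rows <- function(dt, filter) {
  keep <- rep(TRUE, nrow(dt))
  for (nm in names(filter)) {
    val <- filter[[nm]]
    keep <- keep & switch(nm,
      sex = dt$sex %in% val,
      education = dt$education %in% val,
      urbanicity = dt$urbanicity %in% val,
      age_group = dt$age_group %in% val,
      age_class = age_class(dt$age_group) %in% val,
      year = dt$year %in% val,
      country = dt$country %in% val,
      region = dt$region %in% val,
      stop("unknown filter dimension: ", nm)
    )
  }
  keep
}

.join_weights <- function(strata, weights) {
  weights <- as.data.table(weights)
  cols <- c("country", "year", "sex", "age_group", "education", "urbanicity")
  out <- merge(copy(strata)[, .idx := .I],
               weights[, c(cols, "persons",
                           intersect("region", names(weights))), with = FALSE],
               by = cols, all.x = TRUE, sort = FALSE)
  if (anyNA(out$persons)) {
    stop("population weights do not cover every included stratum")
  }
  setorder(out, .idx)
  out
}

.group_cols <- function(scope) {
  switch(scope,
    global = c("pattern", "year"),
    region = c("pattern", "region", "year"),
    country = c("pattern", "country", "year"),
    stop("scope must be one of global/region/country")
  )
}

.summarize_groups <- function(dt, draws, scope, return_draws) {
  gc <- .group_cols(scope)
  if (scope == "region" && !"region" %in% names(dt)) {
    stop("region scope needs a 'region' column in the weights")
  }
  groups <- split(seq_len(nrow(dt)), dt[, gc, with = FALSE], drop = TRUE)
  res <- vector("list", length(groups))
  gdraws <- if (return_draws) vector("list", length(groups)) else NULL
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    w <- dt$persons[rows]
    if (sum(w) <= 0) stop("filter selects zero population")
    agg <- as.vector(crossprod(draws[rows, , drop = FALSE], w)) / sum(w)
    s <- draw_summary(agg)
    res[[i]] <- cbind(dt[rows[1], gc, with = FALSE],
                      data.table(median = s[1], ui_low = s[2],
                                 ui_high = s[3], n_strata = length(rows)))
    if (return_draws) gdraws[[i]] <- agg
  }
  out <- rbindlist(res)
  if (return_draws) {
    names(gdraws) <- names(groups)
    setattr(out, "draws", gdraws)
  }
  out[]
}

#' Population-weighted aggregate scores
#'
#' Per posterior draw, the weighted mean of the included strata's scores;
#' summarized by the median and 95% UI over the 4,000 aggregated draws.
#' Weights are renormalized within the filter, so the result is invariant to
#' weight rescaling.
#'
#' @param scores a [score_strata()] result.
#' @param weights population weights (with a `region` column for regional
#'   scope; [build_world()] weights carry one).
#' @param scope `"global"`, `"region"` or `"country"`.
#' @param filter named list restricting the population, e.g.
#'   `list(age_class = "children", sex = "female", year = 2018)`.
#' @param return_draws attach the aggregated draw vectors as attribute
#'   `"draws"` (used by verification code).
#' @return `data.table` with one row per scope group: `pattern`, scope
#'   columns, `median`, `ui_low`, `ui_high`, `n_strata`.
#' @export
aggregate_scores <- function(scores, weights, scope = "global",
                             filter = list(), return_draws = FALSE) {
  stopifnot(inherits(scores, "stratum_score"))
  assert_draw_count(ncol(scores$draws), "aggregate_scores")
  dt <- .join_weights(scores$strata, weights)
  keep <- .filter_rows(dt, filter)
  if (!any(keep)) stop("filter selects no strata")
  .summarize_groups(dt[keep], scores$draws[dt$.idx[keep], , drop = FALSE],
                    scope, return_draws)
}

#' Draw-wise subgroup contrasts
#'
#' Forms the difference between two levels of a demographic dimension at the
#' matched-stratum level, per draw, then aggregates the differences with
#' population weights (the summed persons of each matched pair,
#' renormalized). The education contrast compares high (>=12y) with low
#' (<6y) attainment and drops the middle level entirely; unmatched strata
#' are excluded with a message. Swapping `levels` negates the estimate
#' draw-wise.
#'
#' @param scores a [score_strata()] result.
#' @param weights population weights.
#' @param dimension `"sex"`, `"education"`, `"urbanicity"` or `"age_class"`.
#' @param levels length-2 character: the level reported minus the reference
#'   level. Defaults: female-male, >=12y minus <6y, urban-rural,
#'   adults-children.
#' @param scope,filter,return_draws as in [aggregate_scores()].
#' @return `data.table` of contrast estimates (median, 95% UI).
#' @export
contrast_groups <- function(scores, weights, dimension,
                            levels = NULL, scope = "global",
                            filter = list(), return_draws = FALSE) {
  stopifnot(inherits(scores, "stratum_score"))
  assert_draw_count(ncol(scores$draws), "contrast_groups")
  levels <- levels %||% switch(dimension,
    sex = c("female", "male"),
    education = c(">=12y", "<6y"),
    urbanicity = c("urban", "rural"),
    age_class = c("adults", "children"),
    stop("dimension must be sex/education/urbanicity/age_class")
  )
  stopifnot(length(levels) == 2L)
  dt <- .join_weights(scores$strata, weights)
  keep <- .filter_rows(dt, filter)
  dt <- dt[keep]
  dim_val <- if (dimension == "age_class") age_class(dt$age_group)
             else dt[[dimension]]
  match_cols <- setdiff(c("country", "year", "sex", "age_group", "education",
                          "urbanicity"),
                        if (dimension == "age_class") c("age_group")
                        else dimension)
  mk <- do.call(paste, c(dt[, match_cols, with = FALSE], sep = "|"))
  i1 <- which(dim_val == levels[1])
  i2 <- which(dim_val == levels[2])
  if (!length(i1) || !length(i2)) stop("a contrast level selects no strata")
  if (dimension == "age_class") {
    ## age bands differ between the classes, so no one-to-one stratum pairs
    ## exist: aggregate each class per draw within the scope group, then
    ## difference the aggregated draws
    gc <- .group_cols(scope)
    if (scope == "region" && !"region" %in% names(dt)) {
      stop("region scope needs a 'region' column in the weights")
    }
    groups <- split(seq_len(nrow(dt)), dt[, gc, with = FALSE], drop = TRUE)
    res <- vector("list", length(groups))
    gdraws <- if (return_draws) vector("list", length(groups)) else NULL
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      r1 <- rows[dim_val[rows] == levels[1]]
      r2 <- rows[dim_val[rows] == levels[2]]
      if (!length(r1) || !length(r2)) {
        stop("a contrast level selects no strata in some scope group")
      }
      wm <- function(rr) {
        as.vector(crossprod(scores$draws[dt$.idx[rr], , drop = FALSE],
                            dt$persons[rr])) / sum(dt$persons[rr])
      }
      agg <- wm(r1) - wm(r2)
      s <- draw_summary(agg)
      res[[g]] <- cbind(dt[rows[1], gc, with = FALSE],
                        data.table(median = s[1], ui_low = s[2],
                                   ui_high = s[3],
                                   n_strata = length(r1) + length(r2)))
      if (return_draws) gdraws[[g]] <- agg
    }
    out <- rbindlist(res)
    if (return_draws) {
      names(gdraws) <- names(groups)
      setattr(out, "draws", gdraws)
    }
    return(out[])
  }
  m <- match(mk[i1], mk[i2])
  unmatched <- sum(is.na(m))
  if (unmatched > 0L) {
    message(unmatched, " stratum pair(s) unmatched across levels; excluded")
  }
  ok <- !is.na(m)
  i1 <- i1[ok]; i2 <- i2[m[ok]]
  rows1 <- dt$.idx[i1]; rows2 <- dt$.idx[i2]
  ddraws <- scores$draws[rows1, , drop = FALSE] -
    scores$draws[rows2, , drop = FALSE]
  pair_dt <- dt[i1]
  pair_dt$persons <- dt$persons[i1] + dt$persons[i2]
  .summarize_groups(pair_dt, ddraws, scope, return_draws)
}

#' Draw-wise change between two years, standardized to end-year population
#'
#' Per matched stratum and draw, the difference `year2 - year1`, aggregated
#' with the `year2` population weights only, so demographic drift between
#' the years does not masquerade as dietary change. Both years must have
#' been scored with the identical cutpoint set.
#'
#' @param scores a [score_strata()] result covering both years.
#' @param weights population weights (must cover `year2`).
#' @param years length-2 integer, baseline then end year (default
#'   `c(1990, 2018)`).
#' @param scope,filter,return_draws as in [aggregate_scores()].
#' @return `data.table` of change estimates; the `year` column reports the
#'   end year.
#' @export
change_over_time <- function(scores, weights, years = c(1990L, 2018L),
                             scope = "global", filter = list(),
                             return_draws = FALSE) {
  stopifnot(inherits(scores, "stratum_score"), length(years) == 2L)
  assert_draw_count(ncol(scores$draws), "change_over_time")
  st <- scores$strata
  for (yr in years) {
    if (!yr %in% st$year) stop("year ", yr, " missing from scores")
  }
  dt <- .join_weights(st, weights)
  keep <- .filter_rows(dt, filter)
  dt <- dt[keep]
  mk <- paste(dt$country, dt$sex, dt$age_group, dt$education, dt$urbanicity,
              sep = "|")
  i1 <- which(dt$year == years[1])
  i2 <- which(dt$year == years[2])
  m <- match(mk[i2], mk[i1])
  if (anyNA(m)) {
    message(sum(is.na(m)), " stratum/strata of ", years[2],
            " unmatched in ", years[1], "; excluded")
  }
  ok <- !is.na(m)
  i2 <- i2[ok]; i1 <- i1[m[ok]]
  ddraws <- scores$draws[dt$.idx[i2], , drop = FALSE] -
    scores$draws[dt$.idx[i1], , drop = FALSE]
  pair_dt <- dt[i2]  # end-year weights and descriptors
  .summarize_groups(pair_dt, ddraws, scope, return_draws)
}

#' Spearman correlations between diet-pattern scores
#'
#' Rank correlation across strata of the stratum-level median scores of each
#' pattern pair in the given year (optionally per draw, averaged).
#'
#' @param scores_list list of [score_strata()] results (one per pattern),
#'   scored on the same strata.
#' @param year analysis year.
#' @param level `"median"` (correlate stratum median scores; default) or
#'   `"draws"` (mean of per-draw correlations).
#' @return symmetric correlation matrix with unit diagonal, one row/column
#'   per pattern.
#' @export
score_correlations <- function(scores_list, year = 2018, level = "median") {
  stopifnot(length(scores_list) >= 2L)
  pats <- vapply(scores_list, function(s) s$definition$name, "")
  keys <- lapply(scores_list, function(s) {
    st <- s$strata
    paste(st$country, st$year, stratum_key(st))[st$year == year]
  })
  common <- Reduce(intersect, keys)
  if (length(common) < 3L) {
    stop("need at least 3 common strata to correlate scores")
  }
  mats <- lapply(scores_list, function(s) {
    st <- s$strata
    k <- paste(st$country, st$year, stratum_key(st))
    s$draws[match(common, k), , drop = FALSE]
  })
  n <- length(scores_list)
  rho <- diag(1, n)
  dimnames(rho) <- list(pats, pats)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- if (level == "median") {
        stats::cor(apply(mats[[i]], 1, stats::median),
                   apply(mats[[j]], 1, stats::median), method = "spearman")
      } else {
        mean(vapply(seq_len(ncol(mats[[i]])), function(d) {
          stats::cor(mats[[i]][, d], mats[[j]][, d], method = "spearman")
        }, 0))
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  rho
}
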