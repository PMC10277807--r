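## Diet-pattern scoring. Patterns are declarative: a list of components,
## each naming a dietary factor, a direction (healthy/unhealthy) and a
## scoring rule. Three rules exist:
##   cutpoint_linear -- 0..10 points, linear between a worst and an optimal
##                      intake (mirrored for unhealthy components);
##   quintile        -- 1..5 points by sex-specific population-weighted
##                      quintiles of the 2018 stratum median intakes
##                      (reversed for unhealthy components);
##   median_binary   -- 0/1 by the sex-specific population-weighted median.
## Quantile cutpoints are computed once, from the 2018 distribution, and the
## identical cutpoint set is reused for every other year. Ties at a quantile
## boundary take the lower point value.

#' Declare a diet-pattern definition
#'
#' @param name pattern name.
#' @param components list of component lists with elements `factor`,
#'   `direction` (`"healthy"` or `"unhealthy"`), `rule` (`"cutpoint_linear"`,
#'   `"quintile"` or `"median_binary"`) and, for `cutpoint_linear`, numeric
#'   `worst` and `optimal` intakes.
#' @param rescale_mult multiplier applied to the component sum (AHEI uses
#'   100/90; DASH and MED use 1).
#' @return object of class `score_definition`.
#' @export
score_definition <- function(name, components, rescale_mult = 1) {
  for (cmp in components) {
    stopifnot(is.character(cmp$factor),
              cmp$direction %in% c("healthy", "unhealthy"),
              cmp$rule %in% c("cutpoint_linear", "quintile", "median_binary"))
    if (cmp$rule == "cutpoint_linear") {
      if (is.null(cmp$worst) || is.null(cmp$optimal) ||
          cmp$worst == cmp$optimal) {
        stop("cutpoint_linear component '", cmp$factor,
             "' needs distinct worst/optimal cutpoints")
      }
    }
  }
  if (anyDuplicated(vapply(components, `[[`, "", "factor"))) {
    stop("duplicate component factor in pattern '", name, "'")
  }
  structure(list(name = name, components = components,
                 rescale_mult = rescale_mult),
            class = "score_definition")
}

.cmp <- function(factor, direction, rule, worst = NULL, optimal = NULL) {
  list(factor = factor, direction = direction, rule = rule,
       worst = worst, optimal = optimal)
}

#' Default AHEI definition (nine components, 0-100)
#'
#' Fixed-cutpoint components following the published AHEI-2010 intake
#' cutpoints for the nine scored components (alcohol and trans fat are not
#' part of the pattern here); each component scores 0-10 and the 0-90 sum is
#' rescaled by 100/90 to the 0-100 range. Sodium uses linear scoring between
#' editable bounds rather than cohort deciles (decile scoring is
#' cohort-relative); all cutpoints are data, editable via
#' [write_score_definition()].
#'
#' @return a [score_definition()].
#' @export
ahei_definition <- function() {
  score_definition("AHEI", list(
    .cmp("fruit", "healthy", "cutpoint_linear", worst = 0, optimal = 4),
    .cmp("vegetables", "healthy", "cutpoint_linear", worst = 0, optimal = 5),
    .cmp("whole_grains", "healthy", "cutpoint_linear", worst = 0, optimal = 75),
    .cmp("ssb", "unhealthy", "cutpoint_linear", worst = 1, optimal = 0),
    .cmp("legumes_nuts", "healthy", "cutpoint_linear", worst = 0, optimal = 1),
    .cmp("red_processed_meat", "unhealthy", "cutpoint_linear",
         worst = 1.5, optimal = 0),
    .cmp("seafood_omega3", "healthy", "cutpoint_linear",
         worst = 0, optimal = 250),
    .cmp("pufa", "healthy", "cutpoint_linear", worst = 2, optimal = 10),
    .cmp("sodium", "unhealthy", "cutpoint_linear",
         worst = 5500, optimal = 1500)
  ), rescale_mult = 100 / 90)
}

#' Default DASH definition (eight components, 8-40)
#'
#' Eight-component quintile-scored form (fruits, vegetables, nuts/legumes,
#' whole grains, low-fat dairy, sodium, red/processed meat, SSBs); healthy
#' components earn 1-5 points by ascending sex-specific quintile, unhealthy
#' components the reverse.
#'
#' @return a [score_definition()].
#' @export
dash_definition <- function() {
  score_definition("DASH", list(
    .cmp("fruit", "healthy", "quintile"),
    .cmp("vegetables", "healthy", "quintile"),
    .cmp("legumes_nuts", "healthy", "quintile"),
    .cmp("whole_grains", "healthy", "quintile"),
    .cmp("low_fat_dairy", "healthy", "quintile"),
    .cmp("sodium", "unhealthy", "quintile"),
    .cmp("red_processed_meat", "unhealthy", "quintile"),
    .cmp("ssb", "unhealthy", "quintile")
  ))
}

#' Default MED definition (eight components, 0-8)
#'
#' Median-binary components (vegetables, legumes/nuts, fruit, whole grains,
#' fish, MUFA:SFA ratio, with meat and dairy reversed); alcohol is not part
#' of the pattern here. One point on the favourable side of the sex-specific
#' median.
#'
#' @return a [score_definition()].
#' @export
med_definition <- function() {
  score_definition("MED", list(
    .cmp("vegetables", "healthy", "median_binary"),
    .cmp("legumes_nuts", "healthy", "median_binary"),
    .cmp("fruit", "healthy", "median_binary"),
    .cmp("whole_grains", "healthy", "median_binary"),
    .cmp("fish", "healthy", "median_binary"),
    .cmp("mufa_sfa_ratio", "healthy", "median_binary"),
    .cmp("red_processed_meat", "unhealthy", "median_binary"),
    .cmp("dairy", "unhealthy", "median_binary")
  ))
}

#' Linear cutpoint component score
#'
#' Healthy direction: 0 points at or below `worst`, 10 at or above
#' `optimal`, linear in between. Unhealthy direction mirrored: 10 at or
#' below `optimal`, 0 at or above `worst`. Always clamped to \[0, 10\].
#'
#' @param intake non-negative intake (vector or matrix).
#' @param rule component list with `direction`, `worst`, `optimal`.
#' @return score(s) in \[0, 10\], same shape as `intake`.
#' @export
score_component_linear <- function(intake, rule) {
  if (any(intake < 0)) stop("negative intake passed to component scoring")
  frac <- (intake - rule$worst) / (rule$optimal - rule$worst)
  10 * pmin(pmax(frac, 0), 1)
}

#' Compute sex-specific quantile cutpoints from the 2018 distribution
#'
#' For every quintile or median-binary component of `definition`, computes
#' the population-weighted quantiles (20/40/60/80th for quintile rules, the
#' median for binary rules) of the stratum-level median intakes of
#' `ref_year`, pooled across all countries within sex. The returned cutpoint
#' set is frozen: scoring any other year reuses it unchanged.
#'
#' @param intakes a (standardized) [posterior_intake()], or a `data.table`
#'   of stratum medians with columns `country`, `year`, `sex`, `age_group`,
#'   `education`, `urbanicity`, `factor`, `median`.
#' @param weights population weights (`country`, `year`, stratum columns,
#'   `persons`).
#' @param definition a [score_definition()].
#' @param ref_year reference year of the distribution (2018).
#' @return `data.table` of class `cutpoint_set`: `pattern`, `factor`,
#'   `sex`, `year`, `prob`, `value` (boundaries strictly increasing within a
#'   component unless the distribution is degenerate, which warns).
#' @export
compute_cutpoints <- function(intakes, weights, definition, ref_year = 2018) {
  stopifnot(inherits(definition, "score_definition"))
  med <- if (inherits(intakes, "posterior_intake")) {
    summary(intakes)[, .(country, year, sex, age_group, education,
                         urbanicity, factor, median)]
  } else {
    as.data.table(intakes)
  }
  med <- med[year == ref_year]
  if (nrow(med) == 0L) stop("no strata for reference year ", ref_year)
  weights <- as.data.table(weights)
  med <- merge(med, weights[, .(country, year, sex, age_group, education,
                                urbanicity, persons)],
               by = c("country", "year", "sex", "age_group", "education",
                      "urbanicity"), all.x = TRUE, sort = FALSE)
  if (anyNA(med$persons)) stop("population weights missing for some strata")
  out <- list()
  for (cmp in definition$components) {
    if (!cmp$rule %in% c("quintile", "median_binary")) next
    probs <- if (cmp$rule == "quintile") c(0.2, 0.4, 0.6, 0.8) else 0.5
    d <- med[factor == cmp$factor]
    if (nrow(d) == 0L) stop("no intake rows for component factor '",
                            cmp$factor, "'")
    for (sx in SEX_LEVELS) {
      ds <- d[sex == sx]
      q <- weighted_quantile(ds$median, ds$persons, probs)
      if (anyDuplicated(q)) {
        warning("degenerate intake distribution for ", cmp$factor, " (",
                sx, "): tied quantile boundaries; ties take the lower point",
                call. = FALSE)
      }
      out[[length(out) + 1L]] <- data.table(
        pattern = definition$name, factor = cmp$factor, sex = sx,
        year = ref_year, prob = probs, value = q)
    }
  }
  cp <- rbindlist(out)
  setattr(cp, "class", c("cutpoint_set", class(cp)))
  cp[]
}

#' Score strata draw-wise against a pattern definition
#'
#' Computes component and total pattern scores for every stratum and every
#' posterior draw. Strata missing any component factor are not scored for
#' the pattern (reported via a message). Totals are the component sums times
#' the pattern's rescale multiplier; component draw-level scores are
#' retained for component-level results.
#'
#' @param intakes a (standardized) [posterior_intake()] containing all
#'   component factors.
#' @param definition a [score_definition()].
#' @param cutpoints a `cutpoint_set` from [compute_cutpoints()]; required
#'   when the definition has quintile or median-binary components.
#' @return object of class `stratum_score`: `strata` (descriptors +
#'   `pattern`), `draws` (total score matrix), `components` (named list of
#'   component score matrices).
#' @export
score_strata <- function(intakes, definition, cutpoints = NULL) {
  stopifnot(inherits(intakes, "posterior_intake"),
            inherits(definition, "score_definition"))
  needs_cp <- any(vapply(definition$components,
                         function(c) c$rule != "cutpoint_linear", TRUE))
  if (needs_cp && is.null(cutpoints)) {
    stop("pattern '", definition$name,
         "' has quantile-based components; supply cutpoints from ",
         "compute_cutpoints()")
  }
  st <- intakes$strata
  fct_names <- vapply(definition$components, `[[`, "", "factor")
  missing_f <- setdiff(fct_names, unique(st$factor))
  if (length(missing_f)) {
    stop("pattern '", definition$name, "' cannot be scored: factor(s) ",
         paste(missing_f, collapse = ", "), " absent from intakes")
  }
  key_all <- paste(st$country, st$year, stratum_key(st))
  base_keys <- Reduce(intersect,
                      lapply(fct_names, function(f) key_all[st$factor == f]))
  n_drop <- length(unique(key_all)) - length(base_keys)
  if (n_drop > 0L) {
    message(n_drop, " stratum/strata lack some component factor and are ",
            "not scored for ", definition$name)
  }
  if (length(base_keys) == 0L) stop("no stratum has all component factors")
  base_rows <- match(base_keys, key_all)  # representative rows for descriptors
  base <- st[base_rows, .(country, year, sex, age_group, education,
                          urbanicity)]
  comp_scores <- list()
  for (cmp in definition$components) {
    rows <- which(st$factor == cmp$factor)
    idx <- rows[match(base_keys, key_all[rows])]
    V <- intakes$draws[idx, , drop = FALSE]
    S <- switch(cmp$rule,
      cutpoint_linear = score_component_linear(V, cmp),
      quintile = .score_quintile(V, base$sex, cmp, cutpoints,
                                 definition$name),
      median_binary = .score_median_binary(V, base$sex, cmp, cutpoints,
                                           definition$name)
    )
    comp_scores[[cmp$factor]] <- S
  }
  total <- Reduce(`+`, comp_scores) * definition$rescale_mult
  strata <- copy(base)[, pattern := definition$name]
  structure(list(strata = strata, draws = total, components = comp_scores,
                 definition = definition, cutpoints = cutpoints),
            class = "stratum_score")
}

.lookup_cp <- function(cutpoints, pattern, fct, sx) {
  cp <- cutpoints[cutpoints$pattern == pattern & cutpoints$factor == fct &
                    cutpoints$sex == sx, ]
  if (nrow(cp) == 0L) {
    stop("no cutpoints for ", pattern, "/", fct, "/", sx)
  }
  cp$value[order(cp$prob)]
}

.score_quintile <- function(V, sex, cmp, cutpoints, pattern) {
  S <- matrix(0, nrow(V), ncol(V))
  for (sx in unique(sex)) {
    b <- .lookup_cp(cutpoints, pattern, cmp$factor, sx)
    rows <- which(sex == sx)
    Vs <- V[rows, , drop = FALSE]
    if (cmp$direction == "healthy") {
      pts <- 1 + (Vs > b[1]) + (Vs > b[2]) + (Vs > b[3]) + (Vs > b[4])
    } else {
      pts <- 5 - ((Vs >= b[1]) + (Vs >= b[2]) + (Vs >= b[3]) + (Vs >= b[4]))
    }
    S[rows, ] <- pts
  }
  S
}

.score_median_binary <- function(V, sex, cmp, cutpoints, pattern) {
  S <- matrix(0, nrow(V), ncol(V))
  for (sx in unique(sex)) {
    m <- .lookup_cp(cutpoints, pattern, cmp$factor, sx)
    rows <- which(sex == sx)
    Vs <- V[rows, , drop = FALSE]
    S[rows, ] <- if (cmp$direction == "healthy") (Vs > m) * 1 else (Vs < m) * 1
  }
  S
}

#' @export
print.stratum_score <- function(x, ...) {
  cat("<stratum_score>", x$definition$name, "-", nrow(x$strata),
      "strata x", ncol(x$draws), "draws\n")
  invisible(x)
}

#' Summarize stratum scores (median and 95% UI per stratum)
#'
#' @param object a [score_strata()] result.
#' @param ... unused.
#' @return `data.table` of stratum descriptors plus `median`, `ui_low`,
#'   `ui_high`.
#' @export
summary.stratum_score <- function(object, ...) {
  q <- .row_quantiles(object$draws)
  out <- copy(object$strata)
  out[, `:=`(median = q[, 1], ui_low = q[, 2], ui_high = q[, 3])]
  out[]
}
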