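## Demographic stratification: 2 sexes x 22 age bands x 3 education levels
## x 2 urbanicity levels = 264 joint strata per country-year.

SEX_LEVELS <- c("male", "female")
EDU_LEVELS <- c("<6y", "6-<12y", ">=12y")
URB_LEVELS <- c("urban", "rural")
METHOD_LEVELS <- c("24hr_recall", "FFQ", "DHS", "HBS")

#' Age bands of the demographic stratification
#'
#' The 22 ordered age bands used throughout: `<1`, `1-2`, `3-4`, `5-9`, then
#' five-year bands from `10-14` to `90-94`, and `95+`. Bands are disjoint and
#' exhaustive over age 0 upwards. Midpoints are used as the age coordinate of
#' the model's smooth age effect.
#'
#' @return `data.table` with columns `age_group` (ordered character codes),
#'   `age_low`, `age_high` (band edges in years; `Inf` for the open band) and
#'   `age_mid` (band midpoint; 97.5 for `95+`).
#' @export
age_bands <- function() {
  lows  <- c(0, 1, 3, 5, seq(10, 95, by = 5))
  highs <- c(1, 3, 5, 10, seq(15, 95, by = 5), Inf)
  labs  <- c("<1", "1-2", "3-4", "5-9",
             paste(seq(10, 90, by = 5), seq(14, 94, by = 5), sep = "-"),
             "95+")
  mids  <- ifelse(is.finite(highs), (lows + highs) / 2, 97.5)
  data.table(age_group = labs, age_low = lows, age_high = highs,
             age_mid = mids)
}

#' Enumerate the 264 demographic strata
#'
#' @param with_age_mid attach the age-band midpoint column.
#' @return `data.table` with one row per joint stratum (sex, age_group,
#'   education, urbanicity); 264 rows.
#' @export
stratum_grid <- function(with_age_mid = TRUE) {
  ab <- age_bands()
  g <- CJ(sex = SEX_LEVELS, age_group = ab$age_group,
          education = EDU_LEVELS, urbanicity = URB_LEVELS, sorted = FALSE)
  if (with_age_mid) g <- merge(g, ab[, .(age_group, age_mid)],
                               by = "age_group", sort = FALSE)
  setcolorder(g, c("sex", "age_group", "education", "urbanicity"))
  setorder(g, sex, age_group, education, urbanicity)
  g[]
}

#' Age-class membership (children vs adults)
#'
#' Children are ages 19 and below (bands `<1` through `15-19`); adults are 20
#' and above.
#'
#' @param age_group character vector of age-band codes.
#' @return character vector `"children"`/`"adults"`.
#' @export
age_class <- function(age_group) {
  ab <- age_bands()
  kid_bands <- ab[age_low < 20, age_group]
  bad <- setdiff(unique(age_group), ab$age_group)
  if (length(bad)) stop("unknown age band(s): ", paste(bad, collapse = ", "))
  ifelse(age_group %in% kid_bands, "children", "adults")
}

## canonical stratum key string, used for row alignment
stratum_key <- function(dt) {
  paste(dt$sex, dt$age_group, dt$education, dt$urbanicity, sep = "|")
}
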