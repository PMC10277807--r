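## Energy standardization: rescale intake draws to a common 2,000 kcal/day
## basis (density method, applied draw by draw) so the diet-quality scores
## reflect dietary composition rather than quantity.

#' Standardize posterior intakes to 2,000 kcal/day
#'
#' Each absolute-unit factor draw is multiplied, draw-wise, by
#' `target / energy_draw` of its own stratum, so uncertainty in energy
#' propagates into the standardized intakes. The energy factor itself maps
#' exactly to `target`; energy-relative units (`% energy`, `ratio`) are left
#' unchanged. Strata with no energy draws are excluded from the result with
#' a message — they are never silently scored.
#'
#' @param intakes a [posterior_intake()] including the `energy` factor.
#' @param target target energy basis in kcal/day.
#' @param energy_factor name of the energy factor.
#' @return a [posterior_intake()] flagged `standardized`.
#' @export
standardize_to_2000 <- function(intakes, target = 2000,
                                energy_factor = "energy") {
  stopifnot(inherits(intakes, "posterior_intake"), target > 0)
  st <- intakes$strata
  if (!energy_factor %in% st$factor) {
    stop("no '", energy_factor, "' rows found; energy draws are required ",
         "for standardization")
  }
  key <- paste(st$country, st$year, stratum_key(st))
  en_rows <- which(st$factor == energy_factor)
  en_of <- match(key, key[en_rows])
  missing <- is.na(en_of)
  if (any(missing)) {
    drop_strata <- unique(key[missing])
    message(length(drop_strata),
            " stratum/strata lack energy draws and are excluded ",
            "from standardization")
  }
  keep <- which(!missing)
  draws <- intakes$draws[keep, , drop = FALSE]
  st2 <- st[keep]
  escale <- target / intakes$draws[en_rows[en_of[keep]], , drop = FALSE]
  relative <- st2$unit %in% c("% energy", "ratio")
  is_energy <- st2$factor == energy_factor
  scale_rows <- !relative & !is_energy
  draws[scale_rows, ] <- draws[scale_rows, , drop = FALSE] *
    escale[scale_rows, , drop = FALSE]
  draws[is_energy, ] <- target
  posterior_intake(st2, draws, standardized = TRUE)
}
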