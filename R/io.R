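## Plain-text interchange: CSV tables with JSON sidecars carrying run
## metadata (schema version, seed, config hash, package version) sufficient
## to regenerate the artifact. UTF-8, '.' decimal; values written with 17
## significant digits so numeric round-trips are exact.

SCHEMA_VERSION <- "1.0"

## polynomial rolling hash over the deparsed object (config fingerprint)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, type, extra = list()) {
  meta <- c(list(schema_version = SCHEMA_VERSION, type = type,
                 package = "dietquality",
                 package_version = as.character(utils::packageVersion("dietquality")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(meta)
}

.read_sidecar <- function(path, expected_type) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION)) {
    stop(sprintf("schema version mismatch: file %s, supported %s",
                 meta$schema_version %||% "<none>", SCHEMA_VERSION))
  }
  if (!is.null(expected_type) && !identical(meta$type, expected_type)) {
    stop(sprintf("expected a %s file, found %s", expected_type,
                 meta$type %||% "<unknown>"))
  }
  meta
}

.num17 <- function(x) sprintf("%.17g", x)

#' Write and read survey records
#'
#' CSV with one row per survey-stratum-factor observation. Reading validates
#' every row (known method and demographic codes, positive mean,
#' non-negative SD, `n >= 1`) and raises a hard error naming the offending
#' rows; an empty file yields an empty table with a warning.
#'
#' @param records survey record table.
#' @param path CSV path (a `.json` sidecar is written alongside).
#' @param seed optional seed recorded in the sidecar.
#' @return `write_surveys`: the path, invisibly. `read_surveys`: validated
#'   `data.table` of records.
#' @export
write_surveys <- function(records, path, seed = NULL) {
  records <- as.data.table(records)
  out <- copy(records)
  for (cl in c("observed_mean", "observed_sd")) {
    out[[cl]] <- .num17(out[[cl]])
  }
  fwrite(out, path)
  .write_sidecar(path, "surveys",
                 list(n_records = nrow(records), seed = seed,
                      config_hash = .config_hash(names(records))))
  invisible(path)
}

#' @rdname write_surveys
#' @export
read_surveys <- function(path) {
  dt <- fread(path, colClasses = list(character = c("sex", "age_group",
                                                    "education",
                                                    "urbanicity")))
  if (nrow(dt) == 0L) {
    warning("survey file ", path, " is empty")
    return(dt)
  }
  need <- c("survey_id", "country", "year", "method", "representative",
            "sex", "age_group", "education", "urbanicity", "factor",
            "observed_mean", "observed_sd", "n")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("survey file missing columns: ",
                         paste(miss, collapse = ", "))
  for (cl in c("sex", "age_group", "education", "urbanicity")) {
    dt[get(cl) == "", (cl) := NA_character_]
  }
  probs <- character(0)
  bad_rows <- function(cond, what) {
    if (any(cond)) probs <<- c(probs, sprintf("%s on row(s) %s", what,
                                              paste(which(cond),
                                                    collapse = ", ")))
  }
  bad_rows(!dt$method %in% METHOD_LEVELS, "unknown method code")
  bad_rows(!is.na(dt$education) & !dt$education %in% EDU_LEVELS,
           "unknown education code")
  bad_rows(!is.na(dt$sex) & !dt$sex %in% SEX_LEVELS, "unknown sex code")
  bad_rows(!is.na(dt$urbanicity) & !dt$urbanicity %in% URB_LEVELS,
           "unknown urbanicity code")
  bad_rows(!is.na(dt$age_group) & !dt$age_group %in% age_bands()$age_group,
           "unknown age band")
  bad_rows(!(dt$observed_mean > 0), "non-positive observed mean")
  bad_rows(dt$observed_sd < 0, "negative observed SD")
  bad_rows(dt$n < 1, "sample size below 1")
  if (length(probs)) {
    stop("invalid survey records: ", paste(probs, collapse = "; "))
  }
  dt[]
}

#' Write and read posterior estimates (intakes or scores)
#'
#' Long-format CSV (stratum descriptors, `factor` or `pattern`, `draw_id`,
#' `value`) with a JSON sidecar. The round trip is lossless and preserves
#' draw order (required for draw-wise differencing); reading enforces the
#' 4,000-draw contract and the schema version.
#'
#' @param x a [posterior_intake()] or [score_strata()] result.
#' @param path CSV path.
#' @param seed optional seed recorded in the sidecar.
#' @return `write_estimates`: the path, invisibly; `read_estimates`: the
#'   reconstructed object (component-level score draws are not serialized).
#' @export
write_estimates <- function(x, path, seed = NULL) {
  if (inherits(x, "posterior_intake")) {
    st <- copy(x$strata)[, .rid := .I]
    long <- st[, .(.rid = rep(.rid, each = ncol(x$draws)))]
    long <- cbind(st[long$.rid, !".rid"],
                  data.table(draw_id = rep(seq_len(ncol(x$draws)),
                                           nrow(st)),
                             value = .num17(as.vector(t(x$draws)))))
    fwrite(long, path)
    .write_sidecar(path, "posterior_intake",
                   list(n_strata = nrow(st), n_draws = ncol(x$draws),
                        standardized = x$standardized, seed = seed,
                        config_hash = .config_hash(x$strata)))
  } else if (inherits(x, "stratum_score")) {
    st <- copy(x$strata)[, .rid := .I]
    long <- st[, .(.rid = rep(.rid, each = ncol(x$draws)))]
    long <- cbind(st[long$.rid, !".rid"],
                  data.table(draw_id = rep(seq_len(ncol(x$draws)),
                                           nrow(st)),
                             value = .num17(as.vector(t(x$draws)))))
    fwrite(long, path)
    .write_sidecar(path, "stratum_score",
                   list(n_strata = nrow(st), n_draws = ncol(x$draws),
                        pattern = x$definition$name, seed = seed,
                        config_hash = .config_hash(x$strata)))
  } else {
    stop("x must be a posterior_intake or stratum_score")
  }
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  meta <- .read_sidecar(path, expected_type = NULL)
  if (!meta$type %in% c("posterior_intake", "stratum_score")) {
    stop("unsupported estimate type: ", meta$type)
  }
  dt <- fread(path)
  id_cols <- setdiff(names(dt), c("draw_id", "value"))
  dt[, .key := do.call(paste, c(.SD, sep = "|")), .SDcols = id_cols]
  counts <- dt[, .N, by = .key]
  if (any(counts$N != N_DRAWS)) {
    stop(sprintf("draw count %d found where %d required (truncated file?)",
                 counts[N != N_DRAWS, N][1], N_DRAWS))
  }
  setorder(dt, .key, draw_id)
  keys <- unique(dt$.key)
  draws <- matrix(dt$value, nrow = length(keys), ncol = N_DRAWS, byrow = TRUE)
  st <- unique(dt[, c(id_cols, ".key"), with = FALSE])[match(keys, .key)]
  st[, .key := NULL]
  if (meta$type == "posterior_intake") {
    posterior_intake(st, draws, standardized = isTRUE(meta$standardized))
  } else {
    structure(list(strata = st, draws = draws, components = list(),
                   definition = score_definition(meta$pattern, list()),
                   cutpoints = NULL),
              class = "stratum_score")
  }
}

#' Write and read score definitions and cutpoint sets as YAML
#'
#' @param definition a [score_definition()]; `cutpoints` a `cutpoint_set`.
#' @param path YAML file path.
#' @return readers return the reconstructed object.
#' @export
write_score_definition <- function(definition, path) {
  stopifnot(inherits(definition, "score_definition"))
  yaml::write_yaml(list(name = definition$name,
                        rescale_mult = definition$rescale_mult,
                        components = definition$components), path)
  invisible(path)
}

#' @rdname write_score_definition
#' @export
read_score_definition <- function(path) {
  y <- yaml::read_yaml(path)
  comps <- lapply(y$components, function(cmp) {
    .cmp(cmp$factor, cmp$direction, cmp$rule, cmp$worst, cmp$optimal)
  })
  score_definition(y$name, comps, rescale_mult = y$rescale_mult %||% 1)
}

#' @rdname write_score_definition
#' @param cutpoints a `cutpoint_set` from [compute_cutpoints()].
#' @export
write_cutpoints <- function(cutpoints, path) {
  yaml::write_yaml(lapply(seq_len(nrow(cutpoints)), function(i) {
    as.list(cutpoints[i])
  }), path)
  invisible(path)
}

#' @rdname write_score_definition
#' @export
read_cutpoints <- function(path) {
  cp <- rbindlist(lapply(yaml::read_yaml(path), as.data.table))
  setattr(cp, "class", c("cutpoint_set", class(cp)))
  cp[]
}

#' Run configuration for a scripted pipeline
#'
#' Validates that every referenced input file exists before any stage runs.
#'
#' @param surveys,weights,covariates,definitions file paths (or `NULL` for
#'   stages that generate their inputs).
#' @param stages character vector of stage names to run.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return validated `run_config` list.
#' @export
run_config <- function(surveys = NULL, weights = NULL, covariates = NULL,
                       definitions = NULL,
                       stages = c("simulate", "fit", "standardize", "score",
                                  "aggregate"),
                       seed = 1L, out_dir = "results",
                       log_level = "info") {
  stopifnot(log_level %in% c("quiet", "info", "debug"))
  for (p in c(surveys, weights, covariates, definitions)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  structure(list(surveys = surveys, weights = weights,
                 covariates = covariates, definitions = definitions,
                 stages = stages, seed = as.integer(seed),
                 out_dir = out_dir, log_level = log_level),
            class = "run_config")
}
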