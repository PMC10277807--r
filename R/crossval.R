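## Five-fold cross-validation of the intake model: randomly omit 20% of the
## survey records, refit, and compare predicted versus observed intakes;
## repeated five times with fresh fold assignments.

#' Cross-validate the intake model
#'
#' Records are randomly partitioned into `folds` folds (each holding out
#' `holdout` of the data); each fold's records are predicted from a model
#' fitted to the remainder. The whole procedure is repeated `repeats` times.
#' A partition that removes every record of some country or factor from a
#' training set is reshuffled once, then raises an error. Held-out records
#' are predicted at their own stratum, assessment method and covariate
#' value, so the comparison is on the observed scale.
#'
#' @param records survey records.
#' @param spec a [model_spec()].
#' @param regions country-region map.
#' @param covariates,weights as in [fit_intake_model()].
#' @param folds,holdout,repeats protocol shape; `folds * holdout` must equal
#'   1 so the folds tile the data.
#' @param seed integer seed for fold assignment.
#' @return object of class `crossval_result`: `table` (one row per held-out
#'   record: `repeat_id`, `fold`, `factor`, observed and predicted means) and
#'   `summary` (per-repeat correlation and calibration slope of log observed
#'   on log predicted, plus overall values).
#' @export
cross_validate <- function(records, spec = model_spec(), regions,
                           covariates = NULL, weights = NULL,
                           folds = 5L, holdout = 0.20, repeats = 5L,
                           seed = 1L) {
  records <- copy(as.data.table(records))
  if (abs(folds * holdout - 1) > 1e-9) {
    stop("folds * holdout must equal 1 (e.g. 5 folds of 20%)")
  }
  records[, .cv_row := .I]
  rows <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("cv|", rep_i)))
    assign_folds <- function() {
      sample(rep_len(seq_len(folds), nrow(records)))
    }
    fold_of <- assign_folds()
    ok <- function(fo) {
      all(vapply(seq_len(folds), function(k) {
        tr <- records[fo != k]
        length(setdiff(unique(records$country), unique(tr$country))) == 0L &&
          length(setdiff(unique(records$factor), unique(tr$factor))) == 0L
      }, logical(1)))
    }
    if (!ok(fold_of)) {
      fold_of <- assign_folds()
      if (!ok(fold_of)) {
        stop("could not build folds retaining every country and factor; ",
             "too few records")
      }
    }
    preds <- vector("list", folds)
    for (k in seq_len(folds)) {
      train <- records[fold_of != k]
      test <- records[fold_of == k]
      fit <- fit_intake_model(train, spec, regions, covariates, weights)
      preds[[k]] <- .predict_records(fit, test)[, `:=`(fold = k,
                                                       repeat_id = rep_i)]
    }
    rows[[rep_i]] <- rbindlist(preds)
  }
  tab <- rbindlist(rows)
  per_rep <- tab[, .(correlation = stats::cor(log(observed_mean),
                                              log(predicted_mean)),
                     calibration_slope = .cal_slope(log(predicted_mean),
                                                    log(observed_mean))),
                 by = repeat_id]
  overall <- tab[, .(repeat_id = NA_integer_,
                     correlation = stats::cor(log(observed_mean),
                                              log(predicted_mean)),
                     calibration_slope = .cal_slope(log(predicted_mean),
                                                    log(observed_mean)))]
  structure(list(table = tab[], summary = rbind(per_rep, overall),
                 folds = folds, holdout = holdout, repeats = repeats),
            class = "crossval_result")
}

.cal_slope <- function(pred, obs) {
  if (stats::var(pred) < 1e-12) return(0)
  unname(stats::coef(stats::lm(obs ~ pred))[2])
}

## posterior-mean prediction of each record's observed value (its stratum
## linear predictor including method and overdispersion-free noise terms)
.predict_records <- function(fit, test) {
  out <- vector("list", length(unique(test$factor)))
  i <- 0L
  for (f in unique(test$factor)) {
    recs <- test[factor == f]
    ff <- fit$fits[[f]]
    if (is.null(ff) || !identical(ff$status, "ok")) {
      stop("factor '", f, "' missing from training fit")
    }
    des <- .record_design(recs, fit$regions, fit$covariates, fit$weights,
                          fit$spec$use_covariate, f)
    mu <- des$M %*% colMeans(ff$draws)
    i <- i + 1L
    out[[i]] <- data.table(.cv_row = recs$.cv_row, factor = f,
                           country = recs$country, year = recs$year,
                           observed_mean = recs$observed_mean,
                           predicted_mean = exp(as.vector(mu)))
  }
  rbindlist(out)
}

#' @export
print.crossval_result <- function(x, ...) {
  ov <- x$summary[is.na(repeat_id)]
  cat(sprintf("<crossval_result> %d folds x %d repeats (%.0f%% holdout)\n",
              x$folds, x$repeats, 100 * x$holdout))
  cat(sprintf("  overall r = %.3f, calibration slope = %.3f\n",
              ov$correlation, ov$calibration_slope))
  invisible(x)
}
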