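## data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", ".BY", ".I", ".N", ".SD", ".cv_row", ".idx", ".key", ".rid", ".row",
  "age_group", "age_low", "age_mid", "cell_mean", "collapsed", "country",
  "covariate", "draw_id", "education", "energy_kcal", "factor", "full",
  "median", "method", "n", "observed_mean", "observed_sd", "persons",
  "pattern", "predicted_mean", "prob", "region", "repeat_id",
  "representative", "rhat", "se", "sex", "survey_id", "t", "true_logmean",
  "true_mean", "ui_high", "ui_low", "unit", "urbanicity", "value", "xcov",
  "year", "param", "persons"
))
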