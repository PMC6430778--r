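# shared fixtures, all built in code

# one-row cohort record; stages given as named list/vector (t31.., t41..)
make_record <- function(sex = "M", ..., child_id = "C1",
                        dob = "2008-03-01", dor = "2015-09-01") {
  stages <- list(...)
  rec <- data.frame(child_id = child_id, sex = sex,
                    dob = as.Date(dob), dor = as.Date(dor))
  for (col in c(tooth_cols("left"), tooth_cols("right"))) {
    rec[[col]] <- if (col %in% names(stages)) stages[[col]] else NA_character_
  }
  rec
}

# record with every left tooth at one stage
uniform_record <- function(stage, sex = "M") {
  args <- as.list(stats::setNames(rep(stage, 7), tooth_cols("left")))
  do.call(make_record, c(list(sex = sex), args))
}

score_tab <- load_score_table()
conv_tab <- load_conversion_table()

# a tiny generator config for fast pipeline tests
small_config <- function(seed = 7) {
  gs <- data.frame(lower = c(4, 7, 4, 7), sex = c("M", "M", "F", "F"),
                   n = c(6, 6, 6, 6))
  bi <- data.frame(lower = gs$lower, sex = gs$sex, bias = c(0.3, 0.5, 0.2, 0.1))
  generator_config(group_sizes = gs, biases = bi, seed = seed)
}
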