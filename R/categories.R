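#' Category sets used throughout the pipeline
#'
#' Central definition of the categorical variables carried by survey and
#' donor records: the seven labour-force/condition groups, the four-level
#' labour force status used for matching, and the remaining nine matching
#' variables. The hours-worked bands partition 1 to 41+ hours per week;
#' non-employed records carry the sentinel band `"none"`.
#'
#' @return Named list of character vectors, one per categorical variable.
#' @export
category_sets <- function() {
  list(
    group = c("FT-no-condition", "PT-no-condition", "FT-diabetes",
              "PT-diabetes", "NILF-diabetes", "unemployed", "NILF-other"),
    lfs = c("FT", "PT", "unemployed", "NILF"),
    income_unit = c("couple-dependents", "couple-only", "lone-parent",
                    "lone-person"),
    income_quintile = as.character(1:5),
    age_pension = c("0", "1"),
    dsp = c("0", "1"),
    sex = c("male", "female"),
    age_group = c("45-49", "50-54", "55-59", "60-64"),
    hours_band = c("1-15", "16-24", "25-34", "35-40", "41+"),
    education = c("university", "non-university"),
    home_owner = c("0", "1")
  )
}

#' The five labour-force/condition groups reported in descriptive tables,
#' in their conventional printed order.
#' @export
analysis_groups <- function() {
  c("FT-no-condition", "PT-no-condition", "FT-diabetes",
    "PT-diabetes", "NILF-diabetes")
}

# Map a group label to its four-level labour force status.
group_to_lfs <- function(group) {
  map <- c("FT-no-condition" = "FT", "PT-no-condition" = "PT",
           "FT-diabetes" = "FT", "PT-diabetes" = "PT",
           "NILF-diabetes" = "NILF", "unemployed" = "unemployed",
           "NILF-other" = "NILF")
  unname(map[group])
}
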