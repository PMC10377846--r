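#' Schema for a synthetic sleep-clinic feature table
#'
#' Describes the columns of a generated dataset: names, numeric/nominal types,
#' level sets for nominal columns, and which columns play the demographic
#' roles (race, sex, age) used by the grouping stage.
#'
#' @param feature_names ordered character vector of identifiers
#' @param feature_types character vector, `"numeric"` or `"nominal"`, one per
#'   feature
#' @param nominal_levels named list of level vectors, one entry per nominal
#'   feature; every nominal feature needs at least two levels
#' @param demographic_roles named integer vector with entries `race`, `sex`
#'   and `age` giving the schema positions of those columns
#' @return an object of class `schema_spec`
#' @seealso [default_schema()] for the 31-column clinical default
#' @export
schema_spec <- function(feature_names, feature_types, nominal_levels,
                        demographic_roles) {
  stopifnot(length(feature_names) == length(feature_types))
  if (!all(feature_types %in% c("numeric", "nominal")))
    stop("feature_types must be 'numeric' or 'nominal'", call. = FALSE)
  if (anyDuplicated(feature_names))
    stop("feature names must be unique", call. = FALSE)
  nominal <- feature_names[feature_types == "nominal"]
  if (!setequal(names(nominal_levels), nominal))
    stop("nominal_levels must cover exactly the nominal features", call. = FALSE)
  if (any(vapply(nominal_levels, length, integer(1)) < 2))
    stop("every nominal feature needs >= 2 levels", call. = FALSE)
  roles <- c("race", "sex", "age")
  if (!setequal(names(demographic_roles), roles))
    stop("demographic_roles must name race, sex and age exactly once", call. = FALSE)
  demographic_roles <- vapply(demographic_roles[roles], as.integer, integer(1))
  if (any(demographic_roles < 1 | demographic_roles > length(feature_names)))
    stop("demographic role positions out of range", call. = FALSE)
  if (feature_types[demographic_roles[["age"]]] != "numeric")
    stop("the age column must be numeric", call. = FALSE)
  for (r in c("race", "sex"))
    if (feature_types[demographic_roles[[r]]] != "nominal")
      stop("the ", r, " column must be nominal", call. = FALSE)
  structure(
    list(feature_names = feature_names, feature_types = feature_types,
         nominal_levels = nominal_levels, demographic_roles = demographic_roles),
    class = "schema_spec"
  )
}

#' Default 31-feature clinical schema
#'
#' The standard layout of a demographic/polysomnography summary table:
#' race, age and sex up front, anthropometrics (BMI, waist, hip, neck),
#' questionnaire scores (Epworth, Berlin, snoring, daytime sleepiness),
#' comorbidities (diabetes, hypertension, coronary disease, stroke), and
#' overnight-study summaries (total sleep time, sleep efficiency, the
#' REM/NREM/supine apnea-hypopnea indices, apnea and hypopnea indices,
#' arousal/awakening/limb-movement indices and oxygen-saturation summaries).
#' Internally columns are named `f1` to `f31`; display names are kept as an
#' attribute.
#'
#' @return a [schema_spec()]
#' @export
default_schema <- function() {
  display <- c(
    "Race", "Age", "Sex", "BMI", "Epworth", "Waist", "Hip", "RDI", "Neck",
    "M.Friedman", "Co-morbid", "Snoring", "Daytime sleepiness", "DM", "HTN",
    "CAD", "CVA", "TST", "Sleep Effic", "REM AHI", "NREM AHI", "Supine AHI",
    "Apnea Index", "Hypopnea Index", "Berlin Q", "Arousal Index",
    "Awakening Index", "PLM Index", "Mins SaO2", "Mins SaO2 Desats",
    "Lowest SaO2"
  )
  types <- rep("numeric", 31)
  nominal_idx <- c(1, 3, 4, 11, 12, 13, 14, 15, 16, 17, 25)
  types[nominal_idx] <- "nominal"
  names <- paste0("f", 1:31)
  levels <- list(
    f1 = c("Caucasian", "Hispanic"),
    f3 = c("Female", "Male"),
    f4 = c("Normal", "Overweight", "Obese"),
    f11 = c("No", "Yes"),
    f12 = c("No", "Yes"),
    f13 = c("No", "Yes"),
    f14 = c("No", "Yes"),
    f15 = c("No", "Yes"),
    f16 = c("No", "Yes"),
    f17 = c("No", "Yes"),
    f25 = c("LowRisk", "HighRisk")
  )
  sch <- schema_spec(names, types, levels,
                     c(race = 1L, sex = 3L, age = 2L))
  attr(sch, "display_names") <- display
  sch
}

#' Configuration of the synthetic-data generator
#'
#' Defaults reproduce the documented composition of the motivating clinical
#' sample: 274 patients, 125 positive for witnessed apnea, 151 Caucasian /
#' 123 Hispanic, 118 female / 156 male, age approximately normal around 50
#' years truncated to the observed 19-96 range. The class signal is planted
#' in the five severity features (RDI, the three positional/stage AHI
#' variants, and lowest oxygen saturation) as a standardized mean shift of
#' 1.5 between classes.
#'
#' @param n_samples number of rows
#' @param positive_fraction expected proportion of positive (apnea) labels
#' @param race_fraction expected proportion of the first race level
#' @param female_fraction expected proportion of the first sex level
#' @param age_mean,age_sd age distribution in years before truncation
#' @param age_bounds length-2 numeric, truncation bounds in years
#' @param planted_features integer indices of informative features; must not
#'   include the demographic role columns
#' @param effect_sizes standardized between-class mean shift per planted
#'   feature (same length as `planted_features`)
#' @param group_modulation optional list with elements `variable` (one of
#'   `"race"`, `"sex"`, `"age"`) and `multipliers`, a named numeric vector of
#'   per-group scalings of the effect sizes (names are the level names, or
#'   `"le"`/`"gt"` for age split at 50). Lets grouped analyses outperform
#'   pooled ones.
#' @param missing_rate proportion of feature cells masked at random in `[0,1)`
#' @param seed integer RNG seed; identical configurations generate identical
#'   tables
#' @return an object of class `generator_config`
#' @export
generator_config <- function(n_samples = 274,
                             positive_fraction = 125 / 274,
                             race_fraction = 151 / 274,
                             female_fraction = 118 / 274,
                             age_mean = 50, age_sd = 14,
                             age_bounds = c(19, 96),
                             planted_features = c(8L, 20L, 21L, 22L, 31L),
                             effect_sizes = rep(1.5, 5),
                             group_modulation = NULL,
                             missing_rate = 0,
                             seed = 1L) {
  stopifnot(n_samples >= 1)
  for (p in c("positive_fraction", "race_fraction", "female_fraction")) {
    v <- get(p)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("`%s` must lie strictly in (0,1)", p), call. = FALSE)
  }
  stop_if_not_proportion(missing_rate, "missing_rate", open_right = TRUE)
  if (length(effect_sizes) != length(planted_features))
    stop("effect_sizes must match planted_features in length", call. = FALSE)
  if (length(planted_features) == 0 && any(effect_sizes != 0))
    stop("nonzero effect with an empty planted set", call. = FALSE)
  stopifnot(length(age_bounds) == 2, age_bounds[1] < age_bounds[2], age_sd > 0)
  if (!is.null(group_modulation)) {
    stopifnot(is.list(group_modulation),
              group_modulation$variable %in% c("race", "sex", "age"),
              is.numeric(group_modulation$multipliers),
              !is.null(names(group_modulation$multipliers)))
  }
  structure(
    list(n_samples = as.integer(n_samples),
         positive_fraction = positive_fraction,
         race_fraction = race_fraction,
         female_fraction = female_fraction,
         age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
         planted_features = as.integer(planted_features),
         effect_sizes = as.double(effect_sizes),
         group_modulation = group_modulation,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# truncated normal sampler via inverse-CDF on the truncated interval
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a labeled synthetic clinical table
#'
#' Labels are Bernoulli draws at `positive_fraction`. Planted features carry a
#' class-conditional Gaussian signal: a latent standard normal is shifted by
#' plus/minus half the effect size according to the label, optionally scaled
#' per demographic group via `group_modulation`. Non-planted features are
#' class-independent noise. Nominal features are produced by thresholding
#' their latent Gaussian at equal-frequency cut points, which preserves the
#' class-conditional dependence of planted nominal columns. Age is truncated
#' normal within `age_bounds`. The result is deterministic given the seed.
#'
#' @param schema a [schema_spec()]; defaults to [default_schema()]
#' @param config a [generator_config()]
#' @return a [labeled_table()]
#' @export
generate_dataset <- function(schema = default_schema(),
                             config = generator_config()) {
  stopifnot(inherits(schema, "schema_spec"), inherits(config, "generator_config"))
  nfeat <- length(schema$feature_names)
  if (length(config$planted_features) &&
      (min(config$planted_features) < 1 || max(config$planted_features) > nfeat))
    stop("planted_features outside schema indices", call. = FALSE)
  if (any(config$planted_features %in% schema$demographic_roles))
    stop("demographic role columns cannot be planted", call. = FALSE)

  with_seed(config$seed, {
    n <- config$n_samples
    labels <- stats::rbinom(n, 1, config$positive_fraction)
    roles <- schema$demographic_roles
    race_lv <- schema$nominal_levels[[schema$feature_names[roles[["race"]]]]]
    sex_lv <- schema$nominal_levels[[schema$feature_names[roles[["sex"]]]]]
    race <- factor(ifelse(stats::runif(n) < config$race_fraction,
                          race_lv[1], race_lv[2]), levels = race_lv)
    sex <- factor(ifelse(stats::runif(n) < config$female_fraction,
                         sex_lv[1], sex_lv[2]), levels = sex_lv)
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_bounds[1], config$age_bounds[2])

    mod <- rep(1, n)
    gm <- config$group_modulation
    if (!is.null(gm)) {
      grp <- switch(gm$variable,
        race = as.character(race),
        sex = as.character(sex),
        age = ifelse(age <= 50, "le", "gt"))
      if (!all(unique(grp) %in% names(gm$multipliers)))
        stop("group_modulation multipliers must cover every group", call. = FALSE)
      mod <- as.double(gm$multipliers[grp])
    }

    eff <- numeric(nfeat)
    eff[config$planted_features] <- config$effect_sizes
    cols <- vector("list", nfeat)
    for (j in seq_len(nfeat)) {
      nm <- schema$feature_names[j]
      if (j == roles[["race"]]) { cols[[j]] <- race; next }
      if (j == roles[["sex"]]) { cols[[j]] <- sex; next }
      if (j == roles[["age"]]) { cols[[j]] <- age; next }
      z <- stats::rnorm(n) + (labels - 0.5) * eff[j] * mod
      if (schema$feature_types[j] == "nominal") {
        lv <- schema$nominal_levels[[nm]]
        cuts <- stats::qnorm(seq_len(length(lv) - 1) / length(lv))
        cols[[j]] <- factor(lv[findInterval(z, cuts) + 1L], levels = lv)
      } else {
        cols[[j]] <- z
      }
    }
    names(cols) <- schema$feature_names
    tab <- labeled_table(as.data.frame(cols, check.names = FALSE), labels)
    if (config$missing_rate > 0)
      tab <- inject_missing(tab, config$missing_rate,
                            seed = derive_seed(config$seed, 1L))
    tab
  })
}

#' Mask feature cells completely at random
#'
#' Each feature cell is independently replaced by `NA` with probability
#' `rate` (missing-completely-at-random); labels are never masked.
#'
#' @param table a [labeled_table()]
#' @param rate masking probability in `[0,1)`
#' @param seed integer seed; deterministic given the seed
#' @return a [labeled_table()] with the same types
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  stopifnot(inherits(table, "labeled_table"))
  stop_if_not_proportion(rate, "rate", open_right = TRUE)
  if (rate == 0) return(table)
  with_seed(seed, {
    n <- nrow(table$data)
    data <- table$data
    for (j in seq_along(data)) {
      hit <- stats::runif(n) < rate
      data[[j]][hit] <- NA
    }
    labeled_table(data, table$labels, table$types)
  })
}

#' Ground-truth planted-feature mask
#'
#' @param schema a [schema_spec()]
#' @param config a [generator_config()]
#' @return integer 0/1 vector with ones exactly at the planted features,
#'   named by feature
#' @export
planted_feature_mask <- function(schema = default_schema(),
                                 config = generator_config()) {
  mask <- integer(length(schema$feature_names))
  mask[config$planted_features] <- 1L
  stats::setNames(mask, schema$feature_names)
}
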