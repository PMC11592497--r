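# Synthetic cohort generation -------------------------------------------------
#
# The generator emulates a paediatric heart-surgery registry: four disease
# groups of very different severity, in-hospital death competing with
# discharge (which censors follow-up), a 72 h post-surgery laboratory series
# per analyte, and MCAR gaps in the raw anthropometric fields.

DISEASE_GROUPS <- c("UVHD I", "UVHD II", "BVHD cmplx.", "BVHD smpl.")
HISTORY_LEVELS <- c("none", "BVHD smpl.", "UVHD II/III", "BVHD cmplx.",
                    "UVHD Ib", "UVHD Ia")
HLM_LEVELS <- c("0 min", "1-<90 min", ">=90 min")
HYPOTHERMIA_LEVELS <- c(">32 C", "28-32 C", "<28 C")
LAB_ANALYTES <- c("creatinine", "urea", "crp", "leukocytes")

# Group-level simulation parameters. Medians / frequencies follow the cohort
# structure the package is designed around (group sizes 50/111/291/850,
# group mortality ~62/7.2/9.6/0.7 %, discharge medians 17/14/10/6 days).
group_params <- function() {
  data.frame(
    group = DISEASE_GROUPS,
    male_frac = c(0.600, 0.658, 0.643, 0.519),
    adm_age_median = c(0.5, 1097, 20, 169),
    adm_age_sdlog = c(2.2, 1.34, 2.5, 1.12),
    days_to_surg_median = c(6, 1, 3, 1),
    days_to_surg_sdlog = c(0.8, 0.35, 1.0, 0.35),
    weight_kg_median = c(3.30, 13, 3.96, 6.9),
    weight_sdlog = c(0.20, 0.57, 0.55, 0.48),
    height_median = c(51.5, 92, 54, 65),
    height_sdlog = c(0.06, 0.28, 0.22, 0.20),
    malformations = c(0.320, 0.198, 0.134, 0.104),
    chrom_alterations = c(0.060, 0.018, 0.089, 0.212),
    pulm_hypertension = c(0.000, 0.018, 0.014, 0.011),
    circulatory_arrest = c(0.45, 0.10, 0.22, 0.08),
    open_thorax = c(0.60, 0.08, 0.15, 0.03),
    hlm_p0 = c(0.00, 0.05, 0.08, 0.17),
    hlm_p1 = c(0.05, 0.15, 0.12, 0.18),
    hypo_p1 = c(0.05, 0.25, 0.15, 0.30),
    hypo_p2 = c(0.15, 0.40, 0.30, 0.40),
    prev_adm_mean = c(0.20, 1.60, 0.50, 0.15),
    stringsAsFactors = FALSE
  )
}

# Per-analyte lognormal settings: group-shifted patient-level means plus
# within-patient draw noise; `agg` is the engineered summary direction.
lab_params <- function() {
  list(
    creatinine = list(mean = c(0.52, 0.44, 0.47, 0.40),
                      sdlog_patient = 0.45, sdlog_draw = 0.12, agg = "max"),
    urea       = list(mean = c(36, 33, 34, 29),
                      sdlog_patient = 0.40, sdlog_draw = 0.15, agg = "max"),
    crp        = list(mean = c(55, 50, 52, 46),
                      sdlog_patient = 0.55, sdlog_draw = 0.25, agg = "max"),
    leukocytes = list(mean = c(10.2, 10.8, 10.8, 11.4),
                      sdlog_patient = 0.30, sdlog_draw = 0.12, agg = "min")
  )
}

# History-group sampling probabilities per current disease group (rows),
# over the five recordable past groups (columns).
history_probs <- function() {
  m <- rbind(
    "UVHD I"      = c(0.05, 0.05, 0.10, 0.30, 0.50),
    "UVHD II"     = c(0.05, 0.20, 0.15, 0.30, 0.30),
    "BVHD cmplx." = c(0.15, 0.10, 0.50, 0.12, 0.13),
    "BVHD smpl."  = c(0.55, 0.05, 0.25, 0.07, 0.08)
  )
  colnames(m) <- c("BVHD smpl.", "UVHD II/III", "BVHD cmplx.",
                   "UVHD Ib", "UVHD Ia")
  m
}

#' Specification of a synthetic cohort
#'
#' Bundles every tunable of the cohort generator: group sizes, planted
#' log-hazard effects, the Weibull death-time law (shared shape,
#' group-specific scale), the lognormal discharge law per group, and the
#' MCAR missingness rates applied to raw fields.
#'
#' Defaults reproduce the study conditions the package targets: group sizes
#' 50/111/291/850 with group-wise in-hospital mortality close to
#' 62 / 7.2 / 9.6 / 0.7 per cent, discharge medians 17/14/10/6 days, and
#' planted effects strongest on the post-surgery creatinine maximum,
#' followed by open thorax, circulatory arrest, and UVHD I membership.
#' The default baseline Weibull scales were calibrated once by Monte Carlo
#' against the mortality targets under the default effect sizes.
#'
#' @param group_sizes Named integer vector of patients per disease group.
#' @param beta Named numeric vector of log-hazard effects. Continuous
#'   predictors act per standard deviation (standardised internally);
#'   categorical effects use `"feature=level"` keys, with a bare binary
#'   (`no`/`yes`) feature name meaning its `yes` level.
#' @param baseline_scale_per_group Named positive Weibull scales (days) for
#'   the group baseline death-time distributions.
#' @param weibull_shape Shared positive Weibull shape of the death-time law.
#' @param discharge_lognormal_params_per_group Named list of `c(mu, sigma)`
#'   on the log-day scale for the discharge-time law per group.
#' @param missingness_rates Named rates in `[0, 1]` applied MCAR to raw
#'   fields by [inject_missingness()].
#' @param seed Integer seed making generation fully reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [inject_missingness()]
#' @export
#' @examples
#' spec <- cohort_spec(seed = 7)
#' table(generate_cohort(spec)$disease_group)
cohort_spec <- function(group_sizes = c("UVHD I" = 50L, "UVHD II" = 111L,
                                        "BVHD cmplx." = 291L,
                                        "BVHD smpl." = 850L),
                        beta = c("creatinine_max" = 0.9,
                                 "open_thorax" = 0.6,
                                 "circulatory_arrest" = 0.45,
                                 "disease_group=UVHD I" = 0.8),
                        baseline_scale_per_group = NULL,
                        weibull_shape = 1.2,
                        discharge_lognormal_params_per_group = list(
                          "UVHD I" = c(log(17), 1.10),
                          "UVHD II" = c(log(14), 0.99),
                          "BVHD cmplx." = c(log(10), 0.66),
                          "BVHD smpl." = c(log(6), 0.35)),
                        missingness_rates = c(weight = 0.0223,
                                              height = 0.0008),
                        seed = 1L) {
  if (is.null(baseline_scale_per_group)) {
    baseline_scale_per_group <- default_baseline_scales()
  }
  spec <- structure(
    list(group_sizes = group_sizes, beta = beta,
         baseline_scale_per_group = baseline_scale_per_group,
         weibull_shape = weibull_shape,
         discharge_lognormal_params_per_group =
           discharge_lognormal_params_per_group,
         missingness_rates = missingness_rates, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

# Baseline Weibull scales (days) calibrated by Monte Carlo so that, under the
# default planted effects and discharge laws, group mortality matches the
# 62 / 7.2 / 9.6 / 0.7 % targets.  See the methods vignette.
default_baseline_scales <- function() {
  c("UVHD I" = 60.5, "UVHD II" = 300.9, "BVHD cmplx." = 177.2,
    "BVHD smpl." = 615.4)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = ", "), "\n")
  cat("  planted effects:", paste(sprintf("%s=%.2f", names(x$beta), x$beta),
                                  collapse = ", "), "\n")
  cat("  weibull shape:", x$weibull_shape, " seed:", x$seed, "\n")
  invisible(x)
}

validate_cohort_spec <- function(spec) {
  gs <- spec$group_sizes
  if (is.null(names(gs)) || !setequal(names(gs), DISEASE_GROUPS)) {
    stop_field("group_sizes", "must be named with the four disease groups")
  }
  if (any(gs <= 0) || any(gs != round(gs))) {
    stop_field("group_sizes", "must be positive whole numbers")
  }
  sc <- spec$baseline_scale_per_group
  if (!setequal(names(sc), DISEASE_GROUPS) || any(!is.finite(sc)) ||
      any(sc <= 0)) {
    stop_field("baseline_scale_per_group",
               "must be positive and named per disease group")
  }
  assert_number(spec$weibull_shape, "weibull_shape", lower = 0,
                open_lower = TRUE)
  dl <- spec$discharge_lognormal_params_per_group
  if (!setequal(names(dl), DISEASE_GROUPS) ||
      !all(vapply(dl, function(p) length(p) == 2L && is.finite(p[1]) &&
                    is.finite(p[2]) && p[2] > 0, logical(1)))) {
    stop_field("discharge_lognormal_params_per_group",
               "must give finite (mu, sigma > 0) per disease group")
  }
  mr <- spec$missingness_rates
  if (length(mr) && (is.null(names(mr)) || any(mr < 0) || any(mr > 1))) {
    stop_field("missingness_rates", "must be named rates in [0, 1]")
  }
  if (!is.numeric(spec$beta) ||
      (length(spec$beta) && is.null(names(spec$beta)))) {
    stop_field("beta", "must be a named numeric vector")
  }
  assert_number(spec$seed, "seed", integer = TRUE)
  invisible(spec)
}

# Engineered-scale covariate value of a beta key, as an indicator column or
# the raw continuous column (standardised by the caller).
beta_column <- function(cohort, key, engineered) {
  if (grepl("=", key, fixed = TRUE)) {
    parts <- strsplit(key, "=", fixed = TRUE)[[1]]
    col <- engineered[[parts[1]]]
    if (is.null(col)) stop_field("beta", sprintf("unknown feature '%s'",
                                                 parts[1]))
    return(as.numeric(col == parts[2]))
  }
  col <- engineered[[key]]
  if (is.null(col)) stop_field("beta", sprintf("unknown feature '%s'", key))
  if (is.factor(col)) {
    if (!identical(levels(col), c("no", "yes"))) {
      stop_field("beta", sprintf(
        "categorical feature '%s' needs a 'feature=level' key", key))
    }
    return(as.numeric(col == "yes"))
  }
  v <- as.numeric(col)
  s <- sd(v)
  if (s > 0) (v - mean(v)) / s else v * 0
}

# Linear predictor (log-hazard) of the planted effects on the cohort.
planted_linear_predictor <- function(cohort, beta) {
  engineered <- engineer_features(cohort, require_outcome = FALSE)
  lp <- rep(0, nrow(cohort))
  for (key in names(beta)) {
    lp <- lp + beta[[key]] * beta_column(cohort, key, engineered)
  }
  lp
}

#' Generate a synthetic raw cohort
#'
#' Draws one patient record per requested patient. Death times come from a
#' group-baseline Weibull whose hazard is multiplied by `exp(beta * x)`;
#' discharge times come from the group lognormal law. The observed follow-up
#' is the minimum of the two, with `status = 1` (deceased) iff death occurs
#' on or before discharge and `status = 0` (censored, i.e. discharged alive)
#' otherwise. Generation is bit-reproducible given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per patient: demographics, surgery
#'   descriptors, per-analyte 72 h laboratory series (list columns
#'   `lab_<analyte>` of `(hour, value)` data frames), the hospitalisation
#'   history (`history_groups` list column), `followup_days`, and `status`
#'   (0 censored / 1 deceased). The latent death and discharge times are
#'   attached as attribute `"latent"` for diagnostics.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  gp <- group_params()
  sizes <- spec$group_sizes[DISEASE_GROUPS]
  n <- sum(sizes)
  grp_idx <- rep(seq_along(DISEASE_GROUPS), times = sizes)
  g <- gp[grp_idx, ]

  rmed <- function(median, sdlog) rlnorm(n, log(median), sdlog)
  yn <- function(p) factor(ifelse(runif(n) < p, "yes", "no"),
                           levels = c("no", "yes"))

  age_adm <- floor(rlnorm(n, log(g$adm_age_median + 1), g$adm_age_sdlog))
  days_to_surg <- round(rmed(g$days_to_surg_median, g$days_to_surg_sdlog))
  hlm_u <- runif(n)
  hlm <- factor(ifelse(hlm_u < g$hlm_p0, HLM_LEVELS[1],
                ifelse(hlm_u < g$hlm_p0 + g$hlm_p1, HLM_LEVELS[2],
                       HLM_LEVELS[3])), levels = HLM_LEVELS)
  hyp_u <- runif(n)
  hypo <- factor(ifelse(hyp_u < g$hypo_p1, HYPOTHERMIA_LEVELS[1],
                 ifelse(hyp_u < g$hypo_p1 + g$hypo_p2, HYPOTHERMIA_LEVELS[2],
                        HYPOTHERMIA_LEVELS[3])), levels = HYPOTHERMIA_LEVELS)
  clamp <- ifelse(hlm == HLM_LEVELS[1], 0,
                  round(rgamma(n, shape = 1.8, scale = 48)))

  n_prev <- rpois(n, g$prev_adm_mean)
  hp <- history_probs()
  history <- lapply(seq_len(n), function(i) {
    if (n_prev[i] == 0L) return(character(0))
    sample(colnames(hp), n_prev[i], replace = TRUE, prob = hp[grp_idx[i], ])
  })

  lp_par <- lab_params()
  labs <- lapply(lp_par, function(an) {
    latent <- an$mean[grp_idx] * exp(rnorm(n, 0, an$sdlog_patient))
    lapply(seq_len(n), function(i) {
      k <- sample(4:8, 1L)
      data.frame(hour = round(sort(runif(k, 0, 72)), 1),
                 value = round(latent[i] * exp(rnorm(k, 0, an$sdlog_draw)), 3))
    })
  })

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    sex = factor(ifelse(runif(n) < g$male_frac, "m", "w"),
                 levels = c("m", "w")),
    age_at_admission = age_adm,
    age_at_surgery = age_adm + days_to_surg,
    weight = round(1000 * rmed(g$weight_kg_median, g$weight_sdlog)),
    height = round(rmed(g$height_median, g$height_sdlog), 1),
    disease_group = factor(DISEASE_GROUPS[grp_idx], levels = DISEASE_GROUPS),
    n_previous_admissions = n_prev,
    malformations = yn(g$malformations),
    chrom_alterations = yn(g$chrom_alterations),
    pulm_hypertension = yn(g$pulm_hypertension),
    circulatory_arrest = yn(g$circulatory_arrest),
    open_thorax = yn(g$open_thorax),
    hlm_category = hlm,
    hypothermia_category = hypo,
    aortic_cross_clamp_time = clamp,
    days_admission_to_surgery = days_to_surg,
    stringsAsFactors = FALSE
  )
  cohort$history_groups <- history
  for (an in LAB_ANALYTES) cohort[[paste0("lab_", an)]] <- labs[[an]]

  lp <- planted_linear_predictor(cohort, spec$beta)
  shape <- spec$weibull_shape
  scale0 <- spec$baseline_scale_per_group[DISEASE_GROUPS][grp_idx]
  death <- rweibull(n, shape = shape, scale = scale0 * exp(-lp / shape))
  dl <- spec$discharge_lognormal_params_per_group
  mu <- vapply(dl[DISEASE_GROUPS], `[`, numeric(1), 1L)[grp_idx]
  sig <- vapply(dl[DISEASE_GROUPS], `[`, numeric(1), 2L)[grp_idx]
  discharge <- rlnorm(n, mu, sig)

  cohort$followup_days <- round(pmin(death, discharge), 2)
  cohort$status <- as.integer(death <= discharge)
  attr(cohort, "latent") <- data.frame(death_time = death,
                                       discharge_time = discharge)
  rownames(cohort) <- NULL
  cohort
}

#' Inject MCAR missingness into raw cohort fields
#'
#' Sets each targeted field to `NA` independently with its rate,
#' missing-completely-at-random, reproducibly given `seed`.
#'
#' @param cohort A raw cohort from [generate_cohort()].
#' @param rates Named rates in `[0, 1]`; names must be cohort columns.
#' @param seed Integer seed.
#' @return The cohort with missing markers inserted.
#' @export
inject_missingness <- function(cohort, rates, seed = 1L) {
  if (length(rates) == 0L) return(cohort)
  if (is.null(names(rates)) || any(rates < 0) || any(rates > 1)) {
    stop_field("rates", "must be named rates in [0, 1]")
  }
  unknown <- setdiff(names(rates), names(cohort))
  if (length(unknown)) {
    stop_field("rates", sprintf("unknown field(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  with_seed(seed, {
    for (field in names(rates)) {
      hit <- runif(nrow(cohort)) < rates[[field]]
      cohort[[field]][hit] <- NA
    }
  })
  cohort
}

#' Write / read a raw cohort as CSV
#'
#' List columns (history and the per-analyte laboratory series) are
#' serialised as JSON strings in dedicated columns, so the file is plain
#' rectangular CSV.
#'
#' @param cohort A raw cohort.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data frame with list columns and factors restored.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$history_groups <- vapply(
    cohort$history_groups,
    function(h) as.character(jsonlite::toJSON(h)), character(1))
  for (an in LAB_ANALYTES) {
    cn <- paste0("lab_", an)
    out[[cn]] <- vapply(cohort[[cn]], function(d) {
      as.character(jsonlite::toJSON(d, digits = NA))
    }, character(1))
  }
  attr(out, "latent") <- NULL
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$sex <- factor(raw$sex, levels = c("m", "w"))
  raw$disease_group <- factor(raw$disease_group, levels = DISEASE_GROUPS)
  for (col in c("malformations", "chrom_alterations", "pulm_hypertension",
                "circulatory_arrest", "open_thorax")) {
    raw[[col]] <- factor(raw[[col]], levels = c("no", "yes"))
  }
  raw$hlm_category <- factor(raw$hlm_category, levels = HLM_LEVELS)
  raw$hypothermia_category <- factor(raw$hypothermia_category,
                                     levels = HYPOTHERMIA_LEVELS)
  raw$history_groups <- lapply(raw$history_groups, function(s) {
    as.character(jsonlite::fromJSON(s))
  })
  for (an in LAB_ANALYTES) {
    cn <- paste0("lab_", an)
    raw[[cn]] <- lapply(raw[[cn]], function(s) {
      d <- jsonlite::fromJSON(s)
      data.frame(hour = as.numeric(d$hour), value = as.numeric(d$value))
    })
  }
  raw
}
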