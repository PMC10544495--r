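#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults encode
#' the study conditions the package emulates: 125 patients over 165 IVF
#' cycles, mean maternal age 38.9 y (range 30-45), a mean of 7.2 normally
#' fertilized zygotes per cycle, an age-dependent meiotic-error channel
#' (logit slope 0.261 per year) enriched on chromosomes 15, 16, 19, 21 and
#' 22, age-independent mitotic errors generated mechanically by abnormal
#' cleavage (26.0% abnormal first divisions, 9.7% abnormal second
#' divisions), trophectoderm biopsies of 5-10 cells, and a 3.2% sample QC
#' failure rate.
#'
#' Arrest-model coefficients are calibrated so that marginal arrest
#' frequencies reproduce roughly 0.16 for euploid embryos, ~0.36 for
#' meiotic-only embryos and 0.55-0.64 for mitotic-containing categories,
#' with roughly half of all zygotes reaching the blastocyst stage.
#'
#' @param ... Named overrides of any default listed below.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 1)
#' cfg$meiotic_age_slope
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_patients = 125L,
    extra_cycles_mean = 0.32,        # cycles per patient = 1 + Poisson(.)
    zygotes_per_cycle_mean = 7.2,
    maternal_age_mean = 38.9,
    maternal_age_sd = 3.5,
    maternal_age_min = 30,
    maternal_age_max = 45,
    # meiotic-error channel (whole-chromosome, present in every cell)
    meiotic_intercept = 1.15,        # logit of P(>=1 meiotic error) at mean age
    meiotic_age_slope = 0.261,       # logit units per year of maternal age
    meiotic_extra_mean = 0.6,        # extra affected chromosomes ~ Poisson(.)
    sex_error_rate = 0.03,           # meiotic sex-chromosome error probability
    chromosome_weights = local({
      w <- rep(1, 22)
      w[c(15, 16, 19, 21, 22)] <- 4  # acrocentric / small-chromosome excess
      w / sum(w)
    }),
    # cleavage / mitotic channel
    p_abnormal_first_division = 0.26,
    p_abnormal_second_division = 0.097,
    abnormal_pattern_weights = c(multipolar = 0.35, precocious = 0.11,
                                 reverse = 0.27, failed = 0.27),
    per_division_missegregation_rate = 0.0015,  # per chromosome per division
    per_division_segmental_rate = 0.0005,      # per arm per division
    mitotic_age_slope = 0.009,       # logit units per year on missegregation
    cell_division_prob = 0.82,       # per-cell division probability per
                                     # growth round (clone-proportion noise)
    polyploid_multipolar_prob = 0.9, # >=4N cells divide multipolar
    monosomy_fitness = 0.92,         # division-prob multiplier per monosomy
    nullisomy_fitness = 0.5,
    trisomy_fitness = 0.97,
    # arrest model (logit scale)
    arrest_intercept = stats::qlogis(0.16),
    arrest_per_chromosome = 0.75,
    arrest_abnormal_division = 1.0,
    patient_sd = 0.4,
    arrest_attrition = 0.45,          # per-cell death probability in arrested
                                     # embryos before whole-embryo sampling
    # morphology and biopsy
    grade_aneuploid_shift = 0.9,
    grade_per_chromosome_shift = 0.22,
    grade_cuts = c(-0.25, 0.75, 1.75),
    biopsy_cells_min = 5L,
    biopsy_cells_max = 10L,
    biopsy_day_probs_euploid  = c(`5` = 0.45, `6` = 0.45, `7` = 0.10),
    biopsy_day_probs_aneuploid = c(`5` = 0.30, `6` = 0.53, `7` = 0.17),
    # sequencing
    bin_size = 1e6,
    sequencing_depth = 100,          # mean reads per full-width bin (disomy)
    read_noise = 0.01,               # negative-binomial overdispersion
    qc_fail_rate = 0.032,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown config fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defaults[names(over)] <- over
  }
  validate_sim_config(structure(defaults, class = "sim_config"))
}

validate_sim_config <- function(config) {
  probs <- c("p_abnormal_first_division", "p_abnormal_second_division",
             "cell_division_prob", "arrest_attrition",
             "per_division_missegregation_rate", "per_division_segmental_rate",
             "qc_fail_rate", "sex_error_rate", "polyploid_multipolar_prob",
             "monosomy_fitness", "nullisomy_fitness", "trisomy_fitness")
  for (p in probs) {
    v <- config[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("config field `", p, "` must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  w <- config$chromosome_weights
  if (length(w) != 22L || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("`chromosome_weights` must be 22 nonnegative weights summing to 1",
         call. = FALSE)
  }
  if (config$sequencing_depth <= 0) stop("`sequencing_depth` must be > 0",
                                         call. = FALSE)
  if (config$read_noise < 0) stop("`read_noise` must be >= 0", call. = FALSE)
  if (config$biopsy_cells_min < 1 ||
      config$biopsy_cells_max < config$biopsy_cells_min) {
    stop("invalid biopsy cell-count range", call. = FALSE)
  }
  for (p in c("biopsy_day_probs_euploid", "biopsy_day_probs_aneuploid")) {
    v <- config[[p]]
    if (length(v) != 3L || any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop("`", p, "` must be 3 probabilities (days 5-7) summing to 1",
           call. = FALSE)
    }
  }
  if (config$maternal_age_min > config$maternal_age_max) {
    stop("maternal age range is empty", call. = FALSE)
  }
  config
}

#' Read or write a simulation configuration as YAML
#'
#' Field names in the YAML file mirror the [sim_config()] arguments. A file
#' missing keys is rejected with an error listing them (pass
#' `partial = TRUE` to fall back to defaults); unknown keys are always an
#' error.
#'
#' @param path Path to a YAML file.
#' @param partial Allow missing keys (defaults are substituted).
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path, partial = FALSE) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a YAML mapping",
                          call. = FALSE)
  if (!partial) {
    missing_keys <- setdiff(names(unclass(sim_config())), names(raw))
    if (length(missing_keys)) {
      stop("config is missing required keys: ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
  }
  for (nm in c("abnormal_pattern_weights", "biopsy_day_probs_euploid",
               "biopsy_day_probs_aneuploid", "chromosome_weights")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  }), path, precision = 15L)
  invisible(path)
}
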