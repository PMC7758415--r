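#' Configuration for the synthetic flavor-panel generator
#'
#' Bundles and validates every tunable of [generate_panel()]. Defaults
#' emulate the study conditions the pipeline is designed for: 71 accessions
#' split 8/11/15/37 over pink-cherry, red-cherry, pink-large and red-large
#' fruit types; 60 volatiles with log-normal concentration spread at
#' coefficients of variation between 0.3 and 2.5; linear calibration with
#' slopes spanning the reference table; olfactory thresholds spanning
#' 3.5--4e6 (10^-9 kg L^-1); a 50-panelist hedonic panel on a 0--8 scale.
#'
#' @param n_accessions Number of accessions (>= 2).
#' @param type_proportions Named fractions over the four fruit types,
#'   summing to 1.
#' @param n_volatiles Number of volatiles.
#' @param concentration_cv_range Range of per-volatile concentration CVs.
#' @param calibration_slope_range Range of calibration slopes; must not
#'   contain 0 (a zero slope is non-invertible).
#' @param calibration_intercept_range Range of calibration intercepts.
#' @param threshold_range Range of olfactory thresholds, 10^-9 kg L^-1
#'   (drawn log-uniformly).
#' @param mean_conc_range Range of per-volatile panel-mean concentrations,
#'   10^-9 kg L^-1 (drawn log-uniformly).
#' @param n_panelists Panel size per accession.
#' @param score_max Hedonic scale ceiling (scores live in `[0, score_max]`).
#' @param noise_sd Per-panelist score noise SD, score units.
#' @param area_noise_cv Multiplicative CV of the peak-area noise
#'   (0 = noise-free chromatography).
#' @param low_match_rate Fraction of peaks given failing match scores.
#' @param istd_conc Internal-standard working concentration, 10^-9 kg L^-1;
#'   the default corresponds to 1e-5 L of 3.284e-5 kg L^-1 3-nonanone
#'   spiked into ~0.005 kg of homogenate.
#' @param seed Root seed; stage-level sub-streams are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 71,
                       type_proportions = c(pink_cherry = 8, red_cherry = 11,
                                            pink_large = 15, red_large = 37) / 71,
                       n_volatiles = 60,
                       concentration_cv_range = c(0.3, 2.5),
                       calibration_slope_range = c(0.02, 4.85),
                       calibration_intercept_range = c(-0.2, 0.2),
                       threshold_range = c(3.5, 4e6),
                       mean_conc_range = c(7, 3100),
                       n_panelists = 50,
                       score_max = 8,
                       noise_sd = 1,
                       area_noise_cv = 0.01,
                       low_match_rate = 0,
                       istd_conc = 65.68,
                       seed = 1) {
  cfg <- list(
    n_accessions = n_accessions, type_proportions = type_proportions,
    n_volatiles = n_volatiles,
    concentration_cv_range = concentration_cv_range,
    calibration_slope_range = calibration_slope_range,
    calibration_intercept_range = calibration_intercept_range,
    threshold_range = threshold_range, mean_conc_range = mean_conc_range,
    n_panelists = n_panelists, score_max = score_max, noise_sd = noise_sd,
    area_noise_cv = area_noise_cv, low_match_rate = low_match_rate,
    istd_conc = istd_conc, seed = seed
  )
  if (n_accessions < 2) abort("`n_accessions` must be at least 2.")
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    abort("`type_proportions` must sum to 1.")
  }
  if (any(type_proportions < 0)) abort("`type_proportions` must be non-negative.")
  if (length(type_proportions) != 4L || is.null(names(type_proportions))) {
    abort("`type_proportions` must be a named vector over the four fruit types.")
  }
  if (n_volatiles < 1) abort("`n_volatiles` must be positive.")
  ranges <- cfg[grepl("_range$", names(cfg))]
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      abort(sprintf("`%s` must be an increasing pair.", nm))
    }
  }
  if (calibration_slope_range[1] <= 0 && calibration_slope_range[2] >= 0) {
    abort("`calibration_slope_range` contains 0: calibration would be non-invertible.")
  }
  if (concentration_cv_range[1] < 0) abort("CVs must be non-negative.")
  if (threshold_range[1] <= 0 || mean_conc_range[1] <= 0) {
    abort("Thresholds and mean concentrations must be positive.")
  }
  if (score_max <= 0) abort("`score_max` must be positive.")
  if (n_panelists < 1) abort("`n_panelists` must be at least 1.")
  if (noise_sd < 0 || area_noise_cv < 0) abort("Noise levels must be non-negative.")
  if (low_match_rate < 0 || low_match_rate > 1) {
    abort("`low_match_rate` must be in [0, 1].")
  }
  if (istd_conc <= 0) abort("`istd_conc` must be positive.")
  structure(cfg, class = "sim_config")
}

#' Generate an n-alkane calibration ladder
#'
#' One row per n-alkane from `c_min` to `c_max` carbons, with retention
#' times from a strictly increasing retention model. The default model is a
#' linear ramp placing C4--C26 across a realistic 3.5--36.5 min window.
#'
#' @param c_min,c_max Carbon-number range (`c_min < c_max`).
#' @param rt_model Function mapping carbon number to retention time
#'   (minutes); must be strictly increasing over the range.
#' @return A tibble with columns `carbon` and `rt`.
#' @export
#' @examples
#' generate_alkane_ladder(4, 26)
generate_alkane_ladder <- function(c_min = 4, c_max = 26, rt_model = NULL) {
  if (c_min >= c_max) abort("`c_min` must be strictly less than `c_max`.")
  rt_model <- rt_model %||% function(z) 1.5 * z - 2.5
  carbon <- seq.int(c_min, c_max)
  rt <- vapply(carbon, rt_model, numeric(1))
  if (any(diff(rt) <= 0)) {
    abort("`rt_model` must be strictly increasing in carbon number.")
  }
  tibble(carbon = carbon, rt = rt)
}

snap_quarter <- function(x) round_half_up(x * 4) / 4

stage_seed <- function(config, stage) {
  set.seed((config$seed %% 1e6) * 101L + stage)
}

counts_from_proportions <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

type_codes <- c(pink_cherry = "PC", red_cherry = "RC",
                pink_large = "PL", red_large = "RL")

lognormal_params <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

runif_log <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic flavor panel with known ground truth
#'
#' Forward-simulates everything the pipeline consumes -- a compound
#' reference with true calibrations and thresholds, per-accession true
#' volatile concentrations and taste compounds, GC-MS peak tables, a
#' calibration-standard series, and hedonic sensory scores -- so that every
#' downstream stage can be checked against the ground truth it was
#' generated from.
#'
#' The forward model is the exact inverse of the quantification path: the
#' true relative concentration is `slope * conc + intercept` and the peak
#' area is `rel * istd_area * sample_mass / istd_conc`, times multiplicative
#' log-normal noise of CV `area_noise_cv`; with zero noise, quantification
#' recovers the true concentrations exactly. Sensory scores are per-factor
#' truths (sweetness planted on fructose+glucose, sourness on total acid,
#' the remaining factors on an accession-level latent flavor scalar)
#' averaged over `n_panelists` noisy panelists, truncated to
#' `[0, score_max]` and snapped to the panel's quarter-point grid. All
#' randomness derives deterministically from `config$seed` through
#' stage-level sub-streams.
#'
#' @param config A [sim_config()].
#' @return A `flavor_panel` list: `config`, `ladder`, `ref` (synthetic
#'   compound reference: `compound_id`, `slope`, `intercept`, `threshold`,
#'   `description`, `category`, `rt`, `mean_conc`, `cv`), `ground_truth`
#'   (`concentrations` long tibble, `taste`, `sensory_truth`,
#'   `latent_flavor`), `profiles` (per-accession taste compounds, sensory
#'   scores and odor-category OAVs), `peaks` (long GC-MS peak table ready
#'   for [quantify_peaks()]) and `standards` (calibration series ready for
#'   [fit_calibration()]).
#' @export
generate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must come from sim_config().")
  }
  ladder <- generate_alkane_ladder()

  # stage 1: compound reference ------------------------------------------
  stage_seed(config, 1L)
  nv <- config$n_volatiles
  cat_words <- c(green = "green", floral = "floral", fruity = "fruity",
                 vegetable = "vegetable", fatty = "fatty", irritant = "smoky")
  category <- sample(names(cat_words), nv, replace = TRUE)
  ref <- tibble(
    compound_id = sprintf("SV%02d", seq_len(nv)),
    slope = runif(nv, config$calibration_slope_range[1],
                  config$calibration_slope_range[2]),
    intercept = runif(nv, config$calibration_intercept_range[1],
                      config$calibration_intercept_range[2]),
    threshold = runif_log(nv, config$threshold_range),
    mean_conc = runif_log(nv, config$mean_conc_range),
    cv = runif(nv, config$concentration_cv_range[1],
               config$concentration_cv_range[2]),
    category = category,
    description = unname(cat_words[category]),
    rt = sort(runif(nv, min(ladder$rt) + 0.5, max(ladder$rt) - 0.5))
  )

  # stage 2: true concentrations and taste compounds ---------------------
  stage_seed(config, 2L)
  counts <- counts_from_proportions(config$type_proportions, config$n_accessions)
  fruit_type <- rep(type_codes[names(config$type_proportions)], counts)
  accession <- paste0(fruit_type, unlist(lapply(counts, seq_len)))
  na <- config$n_accessions

  conc <- purrr::pmap(
    list(ref$compound_id, ref$mean_conc, ref$cv),
    function(id, mu, cv) {
      p <- lognormal_params(mu, cv)
      tibble(accession = accession, compound_id = id,
             concentration = rlnorm(na, p$meanlog, p$sdlog))
    }
  ) %>% list_rbind()
  # guarantee a positive forward signal so the calibration stays invertible
  conc <- conc %>%
    left_join(select(ref, "compound_id", "slope", "intercept"), by = "compound_id") %>%
    mutate(concentration = pmax(.data$concentration,
                                pmax(0, (0.01 - .data$intercept) / .data$slope))) %>%
    select("accession", "compound_id", "concentration")

  taste_means <- c(fructose = 1460, glucose = 910, citric_acid = 281, malic_acid = 159)
  taste_cvs <- c(fructose = 0.22, glucose = 0.25, citric_acid = 0.3, malic_acid = 0.35)
  taste <- tibble(accession = accession, fruit_type = unname(fruit_type))
  for (nm in names(taste_means)) {
    p <- lognormal_params(taste_means[[nm]], taste_cvs[[nm]])
    taste[[nm]] <- rlnorm(na, p$meanlog, p$sdlog)
  }

  # stage 3: sensory truth and panel scores ------------------------------
  stage_seed(config, 3L)
  zsc <- function(x) (x - mean(x)) / sd(x)
  latent <- rnorm(na)
  half <- config$score_max / 2
  truth <- tibble(
    accession = accession,
    sweetness = half + 1.0 * zsc(taste$fructose + taste$glucose),
    sourness = half + 0.8 * zsc(taste$citric_acid + taste$malic_acid),
    characteristic_flavor = half + 1 + 0.8 * latent,
    overall_acceptability = half + 1 + 0.7 * latent + 0.2 * rnorm(na)
  )
  score_cols <- setdiff(names(truth), "accession")
  scores <- truth
  for (nm in score_cols) {
    panel_noise <- matrix(rnorm(na * config$n_panelists, 0, config$noise_sd),
                          nrow = na)
    m <- truth[[nm]] + rowMeans(panel_noise)
    scores[[nm]] <- snap_quarter(pmin(pmax(m, 0), config$score_max))
  }
  scores$sweet_sour_ratio <- scores$sweetness / pmax(scores$sourness, 0.25)

  # stage 4: odor-category OAVs from the true concentrations -------------
  cat_oav <- conc %>%
    left_join(select(ref, "compound_id", "threshold", "description"), by = "compound_id") %>%
    mutate(oav = odor_activity_value(.data$concentration, .data$threshold)) %>%
    select("accession", "compound_id", "description", "oav") %>%
    odor_category_oav() %>%
    select("accession", "category", "category_oav") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "category_oav")

  profiles <- taste %>%
    left_join(scores, by = "accession") %>%
    left_join(cat_oav, by = "accession")

  # stage 5: GC-MS peak tables -------------------------------------------
  stage_seed(config, 5L)
  istd_area <- rlnorm(na, log(1e6), 0.05)
  run_meta <- tibble(
    accession = accession,
    sample_id = accession,
    sample_mass = 1,
    istd_area = istd_area,
    istd_conc = config$istd_conc
  )
  noise_sdlog <- sqrt(log(1 + config$area_noise_cv^2))
  peaks <- conc %>%
    left_join(select(ref, "compound_id", "slope", "intercept", "rt"), by = "compound_id") %>%
    left_join(run_meta, by = "accession") %>%
    mutate(
      rel_true = .data$slope * .data$concentration + .data$intercept,
      area = .data$rel_true * .data$istd_area * .data$sample_mass / .data$istd_conc *
        exp(rnorm(dplyr::n(), -noise_sdlog^2 / 2, noise_sdlog)),
      match_forward = round(runif(dplyr::n(), 820, 995)),
      match_reverse = round(runif(dplyr::n(), 820, 995))
    )
  if (config$low_match_rate > 0) {
    low <- runif(nrow(peaks)) < config$low_match_rate
    peaks$match_forward[low] <- round(runif(sum(low), 400, 800))
  }
  peaks <- select(peaks, "sample_id", "compound_id", "area", "rt",
                  "match_forward", "match_reverse",
                  "sample_mass", "istd_area", "istd_conc")

  # stage 6: calibration-standard series ---------------------------------
  stage_seed(config, 6L)
  levels_rel <- seq(0, 3, by = 0.5) / 3
  standards <- ref %>%
    select("compound_id", "slope", "intercept", "mean_conc") %>%
    tidyr::expand_grid(level = levels_rel) %>%
    mutate(
      true_conc = .data$level * 2 * .data$mean_conc,
      measured = (.data$slope * .data$true_conc + .data$intercept) *
        exp(rnorm(dplyr::n(), -noise_sdlog^2 / 2, noise_sdlog))
    ) %>%
    select("compound_id", "true_conc", "measured")

  structure(
    list(
      config = config,
      ladder = ladder,
      ref = select(ref, "compound_id", "slope", "intercept", "threshold",
                   "description", "category", "rt", "mean_conc", "cv"),
      ground_truth = list(
        concentrations = conc,
        taste = taste,
        sensory_truth = truth,
        latent_flavor = setNames(latent, accession)
      ),
      profiles = profiles,
      peaks = peaks,
      standards = standards
    ),
    class = "flavor_panel"
  )
}

#' @export
print.flavor_panel <- function(x, ...) {
  cat(sprintf(
    "<flavor_panel> %d accessions x %d volatiles (seed %d)\n",
    x$config$n_accessions, x$config$n_volatiles, x$config$seed
  ))
  cat(sprintf("  fruit types: %s\n",
              paste(sprintf("%s=%d", names(table(x$profiles$fruit_type)),
                            as.integer(table(x$profiles$fruit_type))), collapse = " ")))
  cat(sprintf("  peaks: %d rows; standards: %d rows\n",
              nrow(x$peaks), nrow(x$standards)))
  invisible(x)
}
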