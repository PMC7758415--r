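#' Kovats retention index against an n-alkane ladder
#'
#' Interpolates query retention times between the two bracketing n-alkanes
#' of a calibration ladder. In `"log"` mode (the classical isothermal form)
#' the index is
#' \deqn{RI = 100 z + 100 \frac{\log t_x - \log t_z}{\log t_{z+1} - \log t_z}}
#' and in `"linear"` mode (the usual choice for temperature-programmed runs)
#' the logarithms are replaced by raw retention times. A query equal to a
#' ladder alkane's own retention time scores exactly `100 * carbon`; a query
#' outside the ladder span is not extrapolated and returns `NA` with a
#' warning.
#'
#' @param rt Query retention time(s), minutes.
#' @param ladder A data frame with columns `carbon` (integer carbon numbers,
#'   strictly increasing) and `rt` (retention times, minutes, strictly
#'   increasing), e.g. from [generate_alkane_ladder()].
#' @param mode `"log"` (default) or `"linear"`.
#' @return A numeric vector of retention indices, one per query; strictly
#'   between `100 z` and `100 (z + 1)` for a bracketed query.
#' @export
#' @examples
#' ladder <- tibble::tibble(carbon = 10:11, rt = c(10, 12))
#' kovats_ri(11, ladder, mode = "linear") # 1050
kovats_ri <- function(rt, ladder, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  ladder <- validate_ladder(ladder)
  tz <- ladder$rt
  z <- ladder$carbon
  ri <- map_dbl(rt, function(t) {
    hit <- which(t == tz)
    if (length(hit) == 1L) {
      return(100 * z[hit])
    }
    lo <- findInterval(t, tz)
    if (lo < 1L || lo >= length(tz)) {
      return(NA_real_)
    }
    if (mode == "log") {
      frac <- (log(t) - log(tz[lo])) / (log(tz[lo + 1L]) - log(tz[lo]))
    } else {
      frac <- (t - tz[lo]) / (tz[lo + 1L] - tz[lo])
    }
    100 * z[lo] + 100 * frac
  })
  if (anyNA(ri[!is.na(rt)])) {
    warn(sprintf(
      "%d quer%s outside the alkane ladder span [%g, %g] min: no extrapolation, RI set to NA.",
      sum(is.na(ri) & !is.na(rt)),
      if (sum(is.na(ri) & !is.na(rt)) == 1L) "y is" else "ies are",
      min(tz), max(tz)
    ))
  }
  ri
}

validate_ladder <- function(ladder) {
  if (!is.data.frame(ladder) || !all(c("carbon", "rt") %in% names(ladder))) {
    abort("`ladder` must be a data frame with columns `carbon` and `rt`.")
  }
  ladder <- arrange(as_tibble(ladder), .data$carbon)
  if (nrow(ladder) < 2L) {
    abort("The alkane ladder needs at least two rungs.")
  }
  if (any(diff(ladder$carbon) <= 0)) {
    abort("Ladder carbon numbers must be strictly increasing.")
  }
  if (any(diff(ladder$rt) <= 0)) {
    abort("Ladder retention times must be strictly increasing with carbon number.")
  }
  ladder
}

#' Filter peak identifications on spectral match quality
#'
#' Retains a peak only if both its forward (positive) and reverse (negative)
#' library match scores strictly exceed `min_match` on the 0--1000 scale.
#' Peaks with missing match scores are rejected. The rejected peaks, each
#' with a reason, are attached as the `"rejected"` attribute of the result
#' (retrievable with [rejected_peaks()]).
#'
#' @param peaks A data frame of peaks with columns `match_forward` and
#'   `match_reverse` (plus any identification columns, carried through).
#' @param min_match Strict lower bound for both scores; default 800.
#' @return The retained rows of `peaks`, in their input order.
#' @export
filter_identifications <- function(peaks, min_match = 800) {
  peaks <- as_tibble(peaks)
  if (!all(c("match_forward", "match_reverse") %in% names(peaks))) {
    abort("`peaks` must have `match_forward` and `match_reverse` columns.")
  }
  fwd <- peaks$match_forward
  rev <- peaks$match_reverse
  if (any(c(fwd, rev) < 0 | c(fwd, rev) > 1000, na.rm = TRUE)) {
    abort("Match scores must lie in [0, 1000].")
  }
  reason <- dplyr::case_when(
    is.na(fwd) | is.na(rev) ~ "missing match score",
    fwd <= min_match & rev <= min_match ~
      sprintf("forward and reverse match <= %g", min_match),
    fwd <= min_match ~ sprintf("forward match <= %g", min_match),
    rev <= min_match ~ sprintf("reverse match <= %g", min_match),
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  out <- peaks[keep, , drop = FALSE]
  attr(out, "rejected") <- mutate(peaks[!keep, , drop = FALSE], reason = reason[!keep])
  out
}

#' Rejected peaks from an identification filter
#'
#' @param x The result of [filter_identifications()].
#' @return A tibble of rejected peaks with a `reason` column.
#' @export
rejected_peaks <- function(x) {
  attr(x, "rejected") %||% tibble()
}

#' Internal-standard relative concentration
#'
#' Converts a peak area to a concentration relative to the spiked internal
#' standard: `conc = area * istd_conc / (istd_area * sample_mass)`, in the
#' units of `istd_conc` (10^-9 kg L^-1 throughout this package). The
#' homogenate-mass convention is that 1 L of tomato homogenate weighs about
#' 1 kg, so `sample_mass` defaults to 1.
#'
#' @param area Peak area(s) of the analyte.
#' @param istd_area Peak area of the internal standard (> 0; a zero
#'   internal-standard area invalidates the whole run and is an error).
#' @param istd_conc Internal-standard concentration, 10^-9 kg L^-1.
#' @param sample_mass Sample mass, kg (> 0).
#' @return Relative concentration(s), 10^-9 kg L^-1.
#' @export
#' @examples
#' relative_concentration(2.5e6, 1e6, 65.68) # 164.2
relative_concentration <- function(area, istd_area, istd_conc, sample_mass = 1) {
  if (!is.numeric(istd_area) || length(istd_area) != 1L || !is.finite(istd_area) ||
      istd_area <= 0) {
    abort("`istd_area` must be a single positive number: a run without a valid internal-standard peak cannot be quantified.")
  }
  if (!is.numeric(sample_mass) || any(sample_mass <= 0)) {
    abort("`sample_mass` must be positive.")
  }
  area * istd_conc / (istd_area * sample_mass)
}

#' Correct a relative concentration through its calibration curve
#'
#' The calibration curve maps true concentration (x) to measured
#' internal-standard-relative concentration (y = a x + b); correction
#' inverts it, `x = (y - b) / a`. Negative corrected concentrations (small
#' signals combined with a negative intercept) are floored at zero; the
#' number of floored values is attached as attribute `"n_floored"` and
#' reported in a warning.
#'
#' @param rel_conc Measured relative concentration(s), 10^-9 kg L^-1.
#' @param slope,intercept Calibration-line coefficients; `slope` must be
#'   nonzero. Both are recycled against `rel_conc`.
#' @return Corrected concentration(s), 10^-9 kg L^-1, never negative.
#' @export
#' @examples
#' apply_calibration(242.739, slope = 2.433, intercept = -0.561) # 100
apply_calibration <- function(rel_conc, slope, intercept = 0) {
  if (any(!is.finite(slope)) || any(slope == 0)) {
    abort("Calibration slope must be finite and nonzero.")
  }
  x <- (rel_conc - intercept) / slope
  n_floored <- sum(x < 0, na.rm = TRUE)
  if (n_floored > 0) {
    warn(sprintf("%d corrected concentration%s below zero floored at 0.",
                 n_floored, if (n_floored == 1L) "" else "s"))
    x <- pmax(x, 0)
  }
  structure(x, n_floored = n_floored)
}

#' Fit a calibration curve to a standard series
#'
#' Ordinary least-squares fit of measured relative concentration on true
#' standard concentration over a dilution series. Series whose r^2 falls
#' below `r2_min` are flagged (all curves in the shipped reference have
#' r^2 >= 0.99).
#'
#' @param true_conc True standard concentrations (>= 3 distinct levels).
#' @param measured Measured relative concentrations, same length.
#' @param r2_min Flagging threshold for the coefficient of determination.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `flagged`.
#' @export
fit_calibration <- function(true_conc, measured, r2_min = 0.99) {
  if (length(true_conc) != length(measured)) {
    abort("`true_conc` and `measured` must have the same length.")
  }
  ok <- is.finite(true_conc) & is.finite(measured)
  true_conc <- true_conc[ok]
  measured <- measured[ok]
  if (length(unique(true_conc)) < 2L) {
    abort("All standard concentrations are identical: the calibration slope is undefined.")
  }
  if (length(unique(true_conc)) < 3L) {
    abort("A calibration series needs at least 3 distinct concentration levels.")
  }
  fit <- lm(measured ~ true_conc)
  ss_tot <- sum((measured - mean(measured))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  tibble(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    flagged = r2 < r2_min
  )
}

#' Quantify GC-MS peak tables into compound concentrations
#'
#' The full quantification path for one or more runs held in a long peak
#' table: identification filtering on match scores, Kovats retention-index
#' computation against the alkane ladder, internal-standard relative
#' quantification, and calibration-curve correction against the compound
#' reference. Runs are identified by `sample_id`; the sample-level scalars
#' (`sample_mass`, `istd_area`, `istd_conc`) are columns repeated within
#' each run.
#'
#' @param peaks A data frame with one row per detected peak and columns
#'   `sample_id`, `compound_id`, `area`, `rt`, `match_forward`,
#'   `match_reverse`, `sample_mass`, `istd_area`, `istd_conc`.
#' @param ref Compound reference with columns `compound_id`, `slope`,
#'   `intercept` (e.g. [volatile_table()] renamed, or the synthetic
#'   reference from [generate_panel()]).
#' @param ladder Optional alkane ladder for retention indices; `NULL` skips
#'   the RI column.
#' @param ri_mode Passed to [kovats_ri()].
#' @param min_match Passed to [filter_identifications()].
#' @return A tibble with one row per retained peak: `sample_id`,
#'   `compound_id`, `ri` (if a ladder was given), `rel_conc` and
#'   `concentration` (both 10^-9 kg L^-1). Rejected peaks are attached as
#'   the `"rejected"` attribute.
#' @export
quantify_peaks <- function(peaks, ref, ladder = NULL, ri_mode = c("log", "linear"),
                           min_match = 800) {
  ri_mode <- match.arg(ri_mode)
  peaks <- as_tibble(peaks)
  needed <- c("sample_id", "compound_id", "area", "rt",
              "sample_mass", "istd_area", "istd_conc")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols)) {
    abort(paste0("`peaks` is missing columns: ", toString(missing_cols)))
  }
  if (any(peaks$area <= 0, na.rm = TRUE)) {
    abort("Peak areas must be positive.")
  }
  kept <- filter_identifications(peaks, min_match = min_match)
  rejected <- rejected_peaks(kept)

  out <- kept %>%
    group_by(.data$sample_id) %>%
    group_modify(function(df, key) {
      df$rel_conc <- relative_concentration(
        df$area, df$istd_area[1L], df$istd_conc[1L], df$sample_mass[1L]
      )
      df
    }) %>%
    ungroup() %>%
    inner_join(select(as_tibble(ref), "compound_id", "slope", "intercept"),
               by = "compound_id")
  out$concentration <- as.numeric(apply_calibration(out$rel_conc, out$slope, out$intercept))
  if (!is.null(ladder)) {
    out$ri <- kovats_ri(out$rt, ladder, mode = ri_mode)
  }
  out <- select(out, "sample_id", "compound_id", any_of("ri"),
                "rel_conc", "concentration")
  attr(out, "rejected") <- rejected
  out
}
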