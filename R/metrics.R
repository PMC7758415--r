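#' Odor activity value
#'
#' The OAV of a volatile is its concentration divided by its human olfactory
#' detection threshold, both in the same units; OAV > 1 marks an odor-impact
#' compound. A missing threshold leaves the OAV undefined (`NA`), not zero:
#' undefined OAVs are excluded from every downstream aggregate.
#'
#' @param conc Concentration(s), 10^-9 kg L^-1.
#' @param threshold Olfactory threshold(s), 10^-9 kg L^-1; positive or `NA`.
#' @return Numeric OAV(s), `NA` where the threshold is absent.
#' @seealso [oav_report()] for the integer reporting form.
#' @export
#' @examples
#' odor_activity_value(1174.85, 45)
odor_activity_value <- function(conc, threshold) {
  if (any(threshold <= 0, na.rm = TRUE)) {
    abort("Olfactory thresholds must be positive (use NA for an absent threshold).")
  }
  conc / threshold
}

#' Reporting form of an odor activity value
#'
#' Rounds half-up to an integer; values that round to zero are reported as
#' `"<1"`, and undefined OAVs (absent threshold) as `NA`. This reproduces
#' the table convention in which e.g. 124.18/190 = 0.65 prints as 1 while
#' 108.26/250 = 0.43 prints as "<1". The raw float should be retained for
#' any arithmetic; this form is for display only.
#'
#' @param oav Numeric OAV(s), e.g. from [odor_activity_value()].
#' @return A character vector.
#' @export
#' @examples
#' oav_report(c(0.43, 0.65, 26.1, NA))
oav_report <- function(oav) {
  rounded <- round_half_up(oav)
  dplyr::case_when(
    is.na(oav) ~ NA_character_,
    rounded == 0 ~ "<1",
    TRUE ~ sprintf("%d", as.integer(rounded))
  )
}

#' Sugar-acid ratio of a taste profile
#'
#' `(fructose + glucose) / (citric + malic)`, the standard fruit-quality
#' ratio of total reducing sugars to total organic acids. Reported to two
#' decimals by default; pass `digits = NULL` for the unrounded value. A zero
#' total acid leaves the ratio undefined (`NA`, with a warning).
#'
#' @param fructose,glucose,citric,malic Concentrations, mg 100 g^-1.
#' @param digits Rounding for the reported ratio; `NULL` to skip.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' sugar_acid_ratio(1290.00, 838.50, 251.33, 144.17) # 5.38
sugar_acid_ratio <- function(fructose, glucose, citric, malic, digits = 2) {
  if (any(c(fructose, glucose, citric, malic) < 0, na.rm = TRUE)) {
    abort("Taste-compound concentrations must be non-negative.")
  }
  acid <- citric + malic
  ratio <- (fructose + glucose) / acid
  if (any(acid == 0, na.rm = TRUE)) {
    warn("Zero total acid: sugar-acid ratio undefined for those rows.")
    ratio[acid == 0] <- NA_real_
  }
  if (!is.null(digits)) ratio <- round_half_up(ratio, digits)
  ratio
}

#' Add taste metrics to an accession taste table
#'
#' Data-frame-first wrapper that appends the computed `sugar_acid_ratio`
#' column to a table of per-accession taste compounds.
#'
#' @param df A data frame with columns `fructose`, `glucose`, `citric_acid`,
#'   `malic_acid`.
#' @inheritParams sugar_acid_ratio
#' @return `df` with a `sugar_acid_ratio` column (replaced if present).
#' @export
taste_metrics <- function(df, digits = 2) {
  df %>%
    as_tibble() %>%
    mutate(sugar_acid_ratio = sugar_acid_ratio(
      .data$fructose, .data$glucose, .data$citric_acid, .data$malic_acid,
      digits = digits
    ))
}

#' Aggregate volatile concentrations by compound class
#'
#' Sums per-volatile mean concentrations within functional classes (or
#' metabolic-precursor classes) and counts the member compounds. Volatiles
#' with a missing class label are assigned `"other"` (functional) or
#' `"unknown"` (precursor) with a warning. The grand total across classes is
#' attached as attribute `"grand_total"`; by construction it equals the
#' direct sum of all member concentrations.
#'
#' @param ref A data frame with the class column and a concentration column.
#' @param by Class column: `"functional_class"` or `"precursor_class"`.
#' @param values Name of the concentration column; default `"mean_conc"`.
#' @return A tibble with columns `class`, `n_components`, `total_conc`,
#'   sorted by descending total.
#' @export
#' @examples
#' aggregate_by_class(volatile_table())
aggregate_by_class <- function(ref,
                               by = c("functional_class", "precursor_class"),
                               values = "mean_conc") {
  by <- match.arg(by)
  ref <- as_tibble(ref)
  if (!values %in% names(ref)) {
    abort(sprintf("Column `%s` not found.", values))
  }
  fallback <- if (by == "functional_class") "other" else "unknown"
  lab <- ref[[by]] %||% rep(NA_character_, nrow(ref))
  if (anyNA(lab)) {
    warn(sprintf("%d volatile(s) without a %s label assigned to \"%s\".",
                 sum(is.na(lab)), by, fallback))
    lab[is.na(lab)] <- fallback
  }
  out <- tibble(class = lab, conc = ref[[values]]) %>%
    group_by(.data$class) %>%
    summarise(n_components = dplyr::n(), total_conc = sum(.data$conc), .groups = "drop") %>%
    arrange(desc(.data$total_conc))
  attr(out, "grand_total") <- sum(out$total_conc)
  out
}

match_categories <- function(description, map) {
  patterns <- paste0("\\b", map$keyword, "\\b")
  map(description, function(d) {
    if (is.na(d) || !nzchar(d)) return(character())
    unique(map$category[stringr::str_detect(tolower(d), patterns)])
  })
}

#' Aggregate odor activity values into odor categories
#'
#' Bins each volatile into odor categories by matching its descriptor text
#' against a keyword map (default [default_category_map()]) and sums the
#' member OAVs per category. A volatile whose descriptors span several
#' categories contributes its full OAV to each (no splitting); undefined
#' OAVs are skipped; volatiles matching no keyword contribute to no category
#' and are reported in the `"unmapped"` attribute. Every category of the map
#' appears in the output, empty ones with a sum of 0.
#'
#' @param oavs A data frame with columns `compound_id`, `description`,
#'   `oav`, and optionally a grouping column `accession` (kept if present).
#' @param map A descriptor keyword map; see [default_category_map()].
#' @return A tibble with `accession` (if supplied), `category`,
#'   `category_oav` and `n_members` (members with a defined OAV).
#' @export
odor_category_oav <- function(oavs, map = default_category_map()) {
  oavs <- as_tibble(oavs)
  if (!all(c("compound_id", "description", "oav") %in% names(oavs))) {
    abort("`oavs` needs columns `compound_id`, `description` and `oav`.")
  }
  cats <- match_categories(oavs$description, map)
  unmapped <- unique(oavs$compound_id[lengths(cats) == 0L & nzchar(oavs$description %||% "")])
  if (length(unmapped)) {
    inform(sprintf("%d volatile(s) matched no odor-category keyword: %s",
                   length(unmapped), toString(unmapped)))
  }
  long <- oavs %>%
    mutate(category = cats) %>%
    tidyr::unnest_longer("category") %>%
    filter(!is.na(.data$oav))
  grouping <- intersect("accession", names(oavs))
  all_cats <- unique(map$category)
  skeleton <- if (length(grouping)) {
    tidyr::expand_grid(accession = unique(oavs$accession), category = all_cats)
  } else {
    tibble(category = all_cats)
  }
  out <- long %>%
    group_by(across(all_of(c(grouping, "category")))) %>%
    summarise(category_oav = sum(.data$oav), n_members = dplyr::n(), .groups = "drop") %>%
    right_join(skeleton, by = c(grouping, "category")) %>%
    mutate(
      category_oav = tidyr::replace_na(.data$category_oav, 0),
      n_members = tidyr::replace_na(.data$n_members, 0L),
      category = factor(.data$category, levels = all_cats)
    ) %>%
    arrange(across(all_of(c(grouping, "category"))))
  attr(out, "unmapped") <- unmapped
  out
}

#' Descriptive statistics: mean, SD and coefficient of variation
#'
#' Sample statistics (n - 1 denominator) with `cv = sd / mean`. The CV is
#' undefined (`NA`, with a warning) when the mean is zero.
#'
#' @param x A numeric vector with at least 2 finite values.
#' @return A one-row tibble: `n`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' descriptive_stats(c(1, 3))
descriptive_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    abort("Descriptive statistics need at least 2 finite values.")
  }
  m <- mean(x)
  s <- sd(x)
  cv <- if (m == 0) {
    warn("Mean is zero: CV undefined.")
    NA_real_
  } else {
    s / m
  }
  tibble(n = length(x), mean = m, sd = s, cv = cv)
}
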