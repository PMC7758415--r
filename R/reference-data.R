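#' Taste-compound reference panel (71 tomato accessions)
#'
#' Per-accession concentrations of the principal taste compounds of mature
#' tomato fruit -- soluble solids (%), fructose, glucose, citric acid and
#' malic acid (all mg 100 g^-1) -- together with the printed sugar-acid ratio
#' and the flavor class (I--IV) each accession was assigned after
#' multi-criteria ranking. The panel covers four fruit types: pink cherry
#' (PC), red cherry (RC), pink large-fruited (PL) and red large-fruited (RL).
#'
#' @return A tibble with 71 rows and columns `flavor_class`, `accession`,
#'   `fruit_type` (PC/RC/PL/RL, from the accession prefix), `evolution_type`,
#'   `soluble_solids`, `fructose`, `glucose`, `citric_acid`, `malic_acid`,
#'   `sugar_acid_ratio`.
#' @export
#' @examples
#' taste_table()
taste_table <- function() {
  path <- system.file("extdata", "taste_compounds.csv", package = "tomatoflavor")
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out %>%
    mutate(fruit_type = substr(.data$accession, 1, 2)) %>%
    relocate("fruit_type", .after = "accession")
}

#' Volatile-compound reference table (60 tomato volatiles)
#'
#' The per-volatile reference record used throughout quantification and
#' odor scoring: calibration curve (slope/intercept on axes x = true
#' concentration, y = internal-standard-relative concentration), regression
#' r^2, retention time (min) and WAX-column Kovats retention index, odor
#' descriptors, olfactory detection threshold (10^-9 kg L^-1; `NA` where no
#' threshold is tabulated), the panel-wide concentration range, mean and
#' coefficient of variation, the reported odor activity value
#' (`oav_printed`, `"<1"` below the reporting cutoff, `NA` where undefined),
#' whether the compound was detectable at the olfactometer port
#' (`gco_detected`), the functional class and a curated metabolic-precursor
#' class (lipid / carotenoid / Phe / Ile-Leu; the precursor labels are a
#' chemistry-based curation, not a printed column).
#'
#' @return A tibble with 60 rows, one per volatile.
#' @export
#' @examples
#' volatile_table() %>% dplyr::count(functional_class)
volatile_table <- function() {
  path <- system.file("extdata", "volatile_reference.csv", package = "tomatoflavor")
  readr::read_csv(
    path,
    col_types = readr::cols(
      threshold = readr::col_double(),
      oav_printed = readr::col_character(),
      gco_detected = readr::col_logical(),
      .default = readr::col_guess()
    ),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Default descriptor-to-odor-category keyword map
#'
#' Maps odor-descriptor keywords to the six odor categories used for
#' accession-level odor scoring: green, floral, fruity, vegetable, fatty and
#' irritant. The map is configuration, not ground truth: it is an editable
#' two-column table (`category`, `keyword`) and a volatile whose descriptors
#' span several categories contributes to each of them. Keywords are matched
#' as whole words, case-insensitively, against the free-text `description`
#' field of the volatile reference.
#'
#' @return A tibble with columns `category` and `keyword`.
#' @export
#' @examples
#' default_category_map() %>% dplyr::count(category)
default_category_map <- function() {
  path <- system.file("extdata", "odor_category_map.csv", package = "tomatoflavor")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

odor_categories <- c("green", "floral", "fruity", "vegetable", "fatty", "irritant")
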