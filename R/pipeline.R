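# Orchestration layer: simulate / quantify / evaluate steps over a fixed
# on-disk CSV dialect (UTF-8, comma, "." decimals, header row). Every table
# is written with a one-line provenance comment and read back with
# read_output_csv().

pf_version <- function() as.character(utils::packageVersion("tomatoflavor"))

config_hash <- function(config) rlang::hash(unclass(config))

#' Write / read a pipeline CSV with a provenance header
#'
#' Pipeline outputs carry a single comment line
#' `# tomatoflavor <version>; config <hash>` above the header row, so every
#' table records the tool version and the configuration that produced it.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param hash Configuration hash recorded in the header.
#' @return `path`, invisibly (for `write_output_csv`); a tibble (for
#'   `read_output_csv`).
#' @export
write_output_csv <- function(df, path, hash = "unhashed") {
  writeLines(sprintf("# tomatoflavor %s; config %s", pf_version(), hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_output_csv
#' @export
read_output_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Simulate a flavor panel to disk
#'
#' Runs [generate_panel()] and writes every table the downstream steps read
#' -- compound reference, alkane ladder, peak tables, accession profiles,
#' true concentrations, calibration standards -- plus a `manifest.json`
#' recording the seed and configuration hash. Rerunning with the same
#' configuration yields byte-identical tables.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `flavor_panel`, invisibly, with the written paths in the
#'   `"paths"` attribute.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create output dir `%s`.", out_dir))
  panel <- generate_panel(config)
  h <- config_hash(config)
  tables <- list(
    ref = panel$ref,
    alkane_ladder = panel$ladder,
    peaks = panel$peaks,
    profiles = panel$profiles,
    true_concentrations = panel$ground_truth$concentrations,
    standards = panel$standards
  )
  paths <- purrr::imap_chr(tables, function(df, nm) {
    write_output_csv(df, file.path(out_dir, paste0(nm, ".csv")), h)
  })
  manifest <- list(
    tool = "tomatoflavor", version = pf_version(),
    seed = config$seed, config_hash = h,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(sprintf("Simulated %d accessions x %d volatiles into %s",
                 config$n_accessions, config$n_volatiles, out_dir))
  invisible(structure(panel, paths = c(paths, manifest = file.path(out_dir, "manifest.json"))))
}

#' Quantify simulated or imported peak tables from disk
#'
#' Reads `peaks.csv`, `ref.csv` and `alkane_ladder.csv` from `in_dir` (the
#' layout [run_simulate()] writes), runs [quantify_peaks()], and writes
#' `concentrations.csv` plus `rejected_peaks.csv` (each rejected peak with
#' its reason). A run without a positive internal-standard area is a hard
#' error.
#'
#' @param in_dir Directory holding the input tables.
#' @param out_dir Output directory; defaults to `in_dir`.
#' @param ri_mode,min_match Passed to [quantify_peaks()].
#' @return The concentration tibble, invisibly.
#' @export
run_quantify <- function(in_dir, out_dir = in_dir, ri_mode = "log", min_match = 800) {
  peaks <- read_output_csv(file.path(in_dir, "peaks.csv"))
  ref <- read_output_csv(file.path(in_dir, "ref.csv"))
  ladder <- read_output_csv(file.path(in_dir, "alkane_ladder.csv"))
  conc <- quantify_peaks(peaks, ref, ladder, ri_mode = ri_mode, min_match = min_match)
  rej <- rejected_peaks(conc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_output_csv(conc, file.path(out_dir, "concentrations.csv"))
  write_output_csv(
    if (nrow(rej)) select(rej, "sample_id", "compound_id", "reason") else
      tibble(sample_id = character(), compound_id = character(), reason = character()),
    file.path(out_dir, "rejected_peaks.csv")
  )
  inform(sprintf("Quantified %d peaks (%d rejected) from %s",
                 nrow(conc), nrow(rej), in_dir))
  invisible(conc)
}

#' Evaluate flavor from quantified concentrations and sensory profiles
#'
#' The analysis back end of the pipeline: computes per-accession OAVs and
#' odor-category OAVs from the measured concentrations, per-compound panel
#' means (and functional/precursor-class aggregates when the reference
#' carries those labels), the three TOPSIS flavor scores with a class
#' partition, and the compound-by-sensory correlation table. All outputs
#' are written as provenance-stamped CSVs.
#'
#' @param in_dir Directory with `concentrations.csv` (from
#'   [run_quantify()]), `ref.csv` and `profiles.csv`.
#' @param out_dir Output directory; defaults to `in_dir`.
#' @param class_sizes Optional class sizes for [assign_classes()]; mutually
#'   exclusive with `class_breaks`. When neither is given, classes are cut
#'   at the quartiles of the overall closeness score.
#' @param class_breaks Optional cut points for [assign_classes()].
#' @param category_map Descriptor keyword map for [odor_category_oav()].
#' @return A list of tibbles: `oav`, `category_oav`, `mean_concentrations`,
#'   `aggregates` (possibly `NULL`), `evaluation`, `ranking`,
#'   `correlations`; invisibly.
#' @export
run_evaluate <- function(in_dir, out_dir = in_dir, class_sizes = NULL,
                         class_breaks = NULL, category_map = default_category_map()) {
  conc <- read_output_csv(file.path(in_dir, "concentrations.csv"))
  ref <- read_output_csv(file.path(in_dir, "ref.csv"))
  profiles <- read_output_csv(file.path(in_dir, "profiles.csv"))
  if (nrow(profiles) == 0L || nrow(conc) == 0L) {
    abort("Empty accession set: nothing to evaluate.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  oav <- conc %>%
    rename(accession = "sample_id") %>%
    inner_join(select(ref, "compound_id", "threshold", "description"),
               by = "compound_id") %>%
    mutate(
      oav = odor_activity_value(.data$concentration, .data$threshold),
      oav_reported = oav_report(.data$oav)
    ) %>%
    select("accession", "compound_id", "description", "concentration",
           "oav", "oav_reported")

  cat_oav <- odor_category_oav(oav, map = category_map) %>%
    select("accession", "category", "category_oav")
  cat_wide <- tidyr::pivot_wider(cat_oav, names_from = "category",
                                 values_from = "category_oav")

  mean_conc <- oav %>%
    group_by(.data$compound_id) %>%
    summarise(mean_conc = mean(.data$concentration), .groups = "drop")
  aggregates <- NULL
  if ("functional_class" %in% names(ref)) {
    aggregates <- mean_conc %>%
      left_join(select(ref, "compound_id", "functional_class"), by = "compound_id") %>%
      aggregate_by_class(by = "functional_class")
  }

  criteria <- profiles %>%
    inner_join(cat_wide, by = "accession", suffix = c(".panel", ""))
  evaluation <- evaluate_flavor(criteria)
  breaks <- class_breaks
  if (is.null(class_sizes) && is.null(class_breaks)) {
    breaks <- unname(stats::quantile(evaluation$c_overall, c(0.25, 0.5, 0.75)))
  }
  ranking <- evaluation %>%
    as_tibble() %>%
    mutate(
      class = assign_classes(.data$c_overall, sizes = class_sizes, breaks = breaks),
      rank = rank_desc_stable(.data$c_overall)
    ) %>%
    arrange(.data$rank)

  sens_cols <- intersect(
    c("sweetness", "sourness", "sweet_sour_ratio", "characteristic_flavor",
      "overall_acceptability"), names(profiles)
  )
  comp_wide <- oav %>%
    select("accession", "compound_id", "concentration") %>%
    tidyr::pivot_wider(names_from = "compound_id", values_from = "concentration")
  assoc_in <- evaluation %>%
    as_tibble() %>%
    select("accession", "c_overall", "c_taste", "c_odor") %>%
    left_join(select(profiles, "accession", all_of(sens_cols)), by = "accession") %>%
    inner_join(comp_wide, by = "accession")
  correlations <- correlation_table(
    select(assoc_in, -"accession", -"c_overall", -"c_taste", -"c_odor",
           -all_of(sens_cols)),
    select(assoc_in, "c_overall", "c_taste", "c_odor", all_of(sens_cols))
  )

  out <- list(oav = oav, category_oav = cat_oav, mean_concentrations = mean_conc,
              aggregates = aggregates, evaluation = evaluation,
              ranking = ranking, correlations = correlations)
  for (nm in c("oav", "category_oav", "mean_concentrations", "ranking", "correlations")) {
    write_output_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  if (!is.null(aggregates)) {
    write_output_csv(aggregates, file.path(out_dir, "aggregates.csv"))
  }
  inform(sprintf("Evaluated %d accessions; best overall: %s",
                 nrow(ranking), ranking$accession[1L]))
  invisible(out)
}

rank_desc_stable <- function(x) {
  rk <- integer(length(x))
  rk[order(-x, seq_along(x))] <- seq_along(x)
  rk
}
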