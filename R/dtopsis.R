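#' Z-score standardization of criteria columns
#'
#' Centers and scales each selected column to sample mean 0 and sample SD 1.
#' A constant (zero-SD) column cannot be scaled and maps to all zeros with a
#' warning; a column with fewer than 2 finite values is an error.
#'
#' @param df A data frame.
#' @param cols Columns to standardize (tidyselect); defaults to every
#'   numeric column.
#' @return `df` with the selected columns standardized.
#' @export
#' @examples
#' zscore_standardize(tibble::tibble(x = c(1, 2, 3)))
zscore_standardize <- function(df, cols = where(is.numeric)) {
  df <- as_tibble(df)
  mutate(df, across({{ cols }}, function(x) {
    if (sum(is.finite(x)) < 2L) {
      abort("Cannot standardize a column with fewer than 2 finite values.")
    }
    s <- sd(x)
    if (s == 0) {
      warn("Zero-SD column standardized to all zeros.")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }))
}

#' TOPSIS ranking by closeness to the ideal solution
#'
#' Ranks alternatives by their weighted distance to the ideal and anti-ideal
#' criterion vectors. For each criterion j the ideal value \eqn{X^+_j} is
#' the column maximum for a benefit criterion and the column minimum for a
#' cost criterion (the anti-ideal \eqn{X^-_j} is the opposite), and each
#' alternative i scores
#' \deqn{S_i^\pm = \sqrt{\sum_j w_j^2 (R_{ij} - X^\pm_j)^2}, \qquad
#'       C_i = S_i^- / (S_i^+ + S_i^-)}
#' with \eqn{C_i \in [0, 1]} and \eqn{C_i = 1} exactly when the alternative
#' attains the ideal on every criterion. Cost criteria are handled through
#' the ideal/anti-ideal selection, never by sign-flipping the data. The
#' matrix is used as supplied: standardize first (see
#' [zscore_standardize()]) if the criteria are on incommensurate scales.
#'
#' @param df A data frame holding the decision matrix, one row per
#'   alternative.
#' @param directions Named character vector mapping criterion columns of
#'   `df` to `"benefit"` or `"cost"`.
#' @param weights Non-negative criterion weights, same order as
#'   `directions`; normalized internally to sum to 1. Default uniform.
#' @param id Optional name of an identifier column of `df` used to label
#'   alternatives (default: row number).
#' @return A `topsis_result` tibble with columns `alternative`, `s_plus`,
#'   `s_minus`, `closeness`, `closeness_z` (Z-scored closeness) and `rank`
#'   (1 = closest to ideal; ties broken by input order). The ideal and
#'   anti-ideal vectors, weights and directions are carried as attributes.
#' @export
#' @examples
#' m <- tibble::tibble(sweet = c(1, 0), sour = c(0, 1))
#' topsis(m, c(sweet = "benefit", sour = "cost"))
topsis <- function(df, directions, weights = NULL, id = NULL) {
  df <- as_tibble(df)
  crit <- names(directions)
  if (is.null(crit) || !all(nzchar(crit))) {
    abort("`directions` must be a named vector of \"benefit\"/\"cost\".")
  }
  if (!all(directions %in% c("benefit", "cost"))) {
    abort("Each direction must be \"benefit\" or \"cost\".")
  }
  missing_cols <- setdiff(crit, names(df))
  if (length(missing_cols)) {
    abort(paste0("Criterion column(s) not in `df`: ", toString(missing_cols)))
  }
  if (nrow(df) < 2L) {
    abort("A decision matrix needs at least 2 alternatives.")
  }
  R <- as.matrix(df[crit])
  if (!is.numeric(R) || anyNA(R)) {
    abort("Criterion columns must be numeric with no missing cells.")
  }
  k <- length(crit)
  weights <- weights %||% rep(1, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) == 0) {
    abort("`weights` must be non-negative, one per criterion, not all zero.")
  }
  w <- weights / sum(weights)

  benefit <- directions == "benefit"
  col_max <- apply(R, 2L, max)
  col_min <- apply(R, 2L, min)
  ideal <- ifelse(benefit, col_max, col_min)
  anti <- ifelse(benefit, col_min, col_max)

  w2 <- matrix(w^2, nrow(R), k, byrow = TRUE)
  s_plus <- sqrt(rowSums(w2 * sweep(R, 2L, ideal)^2))
  s_minus <- sqrt(rowSums(w2 * sweep(R, 2L, anti)^2))
  denom <- s_plus + s_minus
  if (any(denom == 0)) {
    abort("All alternatives are identical on every criterion: closeness is undefined.")
  }
  closeness <- s_minus / denom

  alternative <- if (!is.null(id)) df[[id]] else seq_len(nrow(df))
  rk <- integer(nrow(df))
  rk[order(-closeness, seq_along(closeness))] <- seq_along(closeness)
  cz <- if (sd(closeness) == 0) rep(0, length(closeness)) else
    (closeness - mean(closeness)) / sd(closeness)

  out <- tibble(
    alternative = alternative,
    s_plus = s_plus,
    s_minus = s_minus,
    closeness = closeness,
    closeness_z = cz,
    rank = rk
  )
  structure(out,
    ideal = setNames(ideal, crit),
    anti_ideal = setNames(anti, crit),
    weights = setNames(w, crit),
    directions = directions,
    class = c("topsis_result", class(out))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn topsis Return the per-alternative results as a plain tibble.
#' @param x A `topsis_result`.
#' @param ... Unused.
#' @method tidy topsis_result
#' @export
tidy.topsis_result <- function(x, ...) {
  out <- x
  attributes(out)[c("ideal", "anti_ideal", "weights", "directions")] <- NULL
  class(out) <- setdiff(class(out), "topsis_result")
  arrange(as_tibble(out), .data$rank)
}

#' @describeIn topsis One-row summary of a ranking.
#' @method glance topsis_result
#' @export
glance.topsis_result <- function(x, ...) {
  tibble(
    n_alternatives = nrow(x),
    n_criteria = length(attr(x, "directions")),
    closeness_min = min(x$closeness),
    closeness_max = max(x$closeness),
    closeness_mean = mean(x$closeness)
  )
}

#' @describeIn topsis Lollipop chart of closeness scores in rank order.
#' @param object A `topsis_result`.
#' @method autoplot topsis_result
#' @export
autoplot.topsis_result <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(alternative = stats::reorder(factor(.data$alternative), .data$closeness))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$closeness, y = .data$alternative)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$closeness,
                                       yend = .data$alternative),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "#b2182b", size = 2) +
    ggplot2::labs(x = expression(C[i] ~ "(closeness to ideal flavor)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Taste, odor and overall flavor evaluation of accessions
#'
#' Runs three independent TOPSIS rankings on Z-score-standardized criteria:
#' the taste block alone, the odor block alone, and both blocks
#' concatenated. Sourness (taste block) and irritant odor (odor block) are
#' cost criteria; every other criterion is a benefit. Weights default to
#' uniform within each run.
#'
#' @param df A data frame with one row per accession: an identifier column
#'   plus the taste and odor criterion columns.
#' @param taste_cols,odor_cols Criterion column names for the two blocks.
#'   A block whose columns are absent from `df` is skipped with a warning
#'   and its composite score omitted.
#' @param cost_cols Criteria scored as costs wherever they appear.
#' @param id Name of the accession identifier column.
#' @return A `flavor_evaluation` tibble: `accession`, `c_taste`, `c_odor`,
#'   `c_overall` (canonical closeness in `[0, 1]`) and their Z-scored forms
#'   `c_taste_z`, `c_odor_z`, `c_overall_z`. The three underlying
#'   `topsis_result` objects are carried in the `"runs"` attribute.
#' @export
evaluate_flavor <- function(df,
                            taste_cols = c("sweetness", "sourness",
                                           "sweet_sour_ratio",
                                           "characteristic_flavor",
                                           "overall_acceptability"),
                            odor_cols = c("green", "floral", "fruity",
                                          "vegetable", "fatty", "irritant"),
                            cost_cols = c("sourness", "irritant"),
                            id = "accession") {
  df <- as_tibble(df)
  if (!id %in% names(df)) {
    abort(sprintf("Identifier column `%s` not found.", id))
  }
  if (nrow(df) == 0L) {
    abort("Empty accession set: nothing to evaluate.")
  }
  blocks <- list(taste = taste_cols, odor = odor_cols)
  runs <- list()
  out <- tibble(accession = df[[id]])
  for (block in names(blocks)) {
    cols <- blocks[[block]]
    if (!all(cols %in% names(df))) {
      warn(sprintf("%s block columns missing (%s): c_%s omitted.",
                   block, toString(setdiff(cols, names(df))), block))
      blocks[[block]] <- NULL
      next
    }
  }
  run_block <- function(cols) {
    std <- zscore_standardize(df[cols], cols = dplyr::everything())
    std$..id.. <- df[[id]]
    dirs <- setNames(ifelse(cols %in% cost_cols, "cost", "benefit"), cols)
    topsis(std, directions = dirs, id = "..id..")
  }
  for (block in names(blocks)) {
    res <- run_block(blocks[[block]])
    runs[[block]] <- res
    out[[paste0("c_", block)]] <- res$closeness
    out[[paste0("c_", block, "_z")]] <- res$closeness_z
  }
  if (length(blocks) == 2L) {
    res <- run_block(unlist(blocks, use.names = FALSE))
    runs$overall <- res
    out$c_overall <- res$closeness
    out$c_overall_z <- res$closeness_z
  } else {
    warn("Both blocks are needed for the overall evaluation: c_overall omitted.")
  }
  out <- out %>% relocate(any_of(c("accession", "c_taste", "c_odor", "c_overall")))
  structure(out, runs = runs, class = c("flavor_evaluation", class(out)))
}

#' Partition ranked scores into flavor classes
#'
#' Assigns class labels (I = best flavor downwards) either by fixed class
#' sizes applied to the descending sort of the scores, or by fixed cut
#' points on the score scale. With sizes, ties straddling a boundary are
#' broken deterministically by input order (document the accession order of
#' your table); with cut points, a score falling exactly on a cut joins the
#' higher class.
#'
#' @param scores Numeric scores (e.g. overall closeness), higher = better.
#' @param sizes Integer class sizes summing to `length(scores)`, best class
#'   first. Exactly one of `sizes`/`breaks` must be given.
#' @param breaks Increasing numeric cut points; `length(breaks) + 1`
#'   classes.
#' @param labels Class labels, best first; default Roman numerals.
#' @return A factor of class labels, same length and order as `scores`.
#' @export
#' @examples
#' assign_classes(c(0.9, 0.2, 0.5, 0.7), sizes = c(1, 2, 1))
assign_classes <- function(scores, sizes = NULL, breaks = NULL, labels = NULL) {
  if (is.null(sizes) == is.null(breaks)) {
    abort("Supply exactly one of `sizes` or `breaks`.")
  }
  n <- length(scores)
  if (anyNA(scores)) abort("Scores must not contain NA.")
  if (!is.null(sizes)) {
    if (sum(sizes) != n) {
      abort(sprintf("Class sizes sum to %d but there are %d scores.",
                    sum(sizes), n))
    }
    labels <- labels %||% as.character(utils::as.roman(seq_along(sizes)))
    ord <- order(-scores, seq_len(n))
    cls <- character(n)
    cls[ord] <- rep(labels, times = sizes)
    factor(cls, levels = labels)
  } else {
    if (is.unsorted(breaks, strictly = TRUE)) {
      abort("`breaks` must be strictly increasing.")
    }
    k <- length(breaks) + 1L
    labels <- labels %||% as.character(utils::as.roman(seq_len(k)))
    # class I is the top interval; a score equal to a cut joins the higher class
    idx <- k - findInterval(scores, breaks, left.open = TRUE)
    factor(labels[idx], levels = labels)
  }
}

#' Map of taste versus odor closeness scores
#'
#' Scatter plot of the taste and odor closeness scores of a flavor
#' evaluation, optionally colored by flavor class.
#'
#' @param evaluation A `flavor_evaluation` from [evaluate_flavor()].
#' @param class Optional vector of class labels, same order.
#' @return A ggplot object.
#' @export
plot_flavor_map <- function(evaluation, class = NULL) {
  d <- as_tibble(evaluation)
  if (!is.null(class)) d$class <- class
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$c_taste, y = .data$c_odor))
  p <- if (is.null(class)) {
    p + ggplot2::geom_point(colour = "#2166ac", alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.8)
  }
  p +
    ggplot2::labs(x = expression(C[i] ~ (taste)), y = expression(C[i] ~ (odor)),
                  colour = "Flavor class") +
    ggplot2::theme_minimal()
}
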