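sig_flag <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pearson correlation with significance flags
#'
#' Pearson's r with the two-sided t-test p-value, flagged `"**"` for
#' p < 0.01 and `"*"` for 0.01 <= p < 0.05 (the usual table-starring
#' convention). Zero variance in either vector leaves the correlation
#' undefined: `NA` with an empty flag and a warning.
#'
#' @param x,y Paired numeric vectors; at least 3 complete pairs.
#' @return A one-row tibble: `r`, `p`, `flag`, `n`.
#' @export
#' @examples
#' pearson_with_flags(1:10, (1:10)^2)
pearson_with_flags <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    abort("Pearson correlation needs at least 3 complete pairs.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance: correlation undefined.")
    return(tibble(r = NA_real_, p = NA_real_, flag = "", n = n))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, flag = sig_flag(ct$p.value), n = n)
}

#' Compound-by-sensory correlation table
#'
#' All pairwise Pearson correlations between the columns of a compound
#' block and a sensory block measured on the same samples (rows aligned),
#' in long format with significance flags. By default each cell is starred
#' on its own p-value, matching the usual printed-table convention; set
#' `adjust = "BH"` for Benjamini-Hochberg-corrected flags.
#'
#' @param compounds,sensory Data frames with one row per sample and numeric
#'   columns; non-numeric columns are dropped.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with columns `compound`, `sensory`, `r`, `p`, `flag`.
#' @export
correlation_table <- function(compounds, sensory, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  compounds <- select(as_tibble(compounds), where(is.numeric))
  sensory <- select(as_tibble(sensory), where(is.numeric))
  if (nrow(compounds) != nrow(sensory)) {
    abort("`compounds` and `sensory` must describe the same samples (equal row counts).")
  }
  comp_df <- compounds
  sens_df <- sensory
  grid <- tidyr::expand_grid(compound = names(comp_df), sensory = names(sens_df))
  grid$cell <- map2(grid$compound, grid$sensory, function(cc, ss) {
    pearson_with_flags(comp_df[[cc]], sens_df[[ss]])
  })
  out <- tidyr::unnest(grid, "cell")
  if (adjust == "BH") {
    out <- mutate(out, p = p.adjust(.data$p, method = "BH"), flag = sig_flag(.data$p))
  }
  out
}

#' One-way ANOVA across fruit types
#'
#' Standard one-way F-test of a numeric response across group labels (e.g.
#' the PC / RC / PL / RL fruit types). Groups with fewer than 2 members are
#' excluded with a warning; at least 2 usable groups are required. A zero
#' within-group sum of squares (identical values within every group but
#' different means) is reported as an infinite F with p = 0 rather than an
#' error.
#'
#' @param values Numeric response.
#' @param type Group labels, same length.
#' @return A one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @export
#' @examples
#' anova_by_type(c(1, 2, 5, 6), c("a", "a", "b", "b"))
anova_by_type <- function(values, type) {
  if (length(values) != length(type)) {
    abort("`values` and `type` must have the same length.")
  }
  ok <- is.finite(values) & !is.na(type)
  values <- values[ok]
  type <- as.character(type[ok])
  counts <- table(type)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warn(paste0("Group(s) with fewer than 2 members excluded: ", toString(small)))
    keep <- !type %in% small
    values <- values[keep]
    type <- type[keep]
  }
  if (length(unique(type)) < 2L) {
    abort("One-way ANOVA needs at least 2 groups with >= 2 members each.")
  }
  g <- factor(type)
  grand <- mean(values)
  ss_between <- sum(tapply(values, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(tibble(f_statistic = 0, p_value = 1, df_between = df_b, df_within = df_w))
    }
    inform("Zero within-group variance: F reported as Inf, p as 0.")
    return(tibble(f_statistic = Inf, p_value = 0, df_between = df_b, df_within = df_w))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  tibble(
    f_statistic = f,
    p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
    df_between = df_b,
    df_within = df_w
  )
}
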