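test_that("z-score standardization yields mean 0, SD 1 per column", {
  expect_equal(zscore_standardize(tibble::tibble(x = c(1, 2, 3)))$x, c(-1, 0, 1))
  expect_warning(z <- zscore_standardize(tibble::tibble(x = rep(2, 5))), "Zero-SD")
  expect_equal(z$x, rep(0, 5))
  expect_error(zscore_standardize(tibble::tibble(x = c(1, NA, NA))), "2 finite")
  set.seed(13)
  df <- tibble::tibble(a = rnorm(40, 5, 3), b = runif(40, -2, 9))
  std <- zscore_standardize(df)
  for (col in names(std)) {
    expect_equal(mean(std[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[col]]), 1, tolerance = 1e-12)
  }
})

test_that("extreme alternatives attain closeness 0 and 1, directions flip them", {
  m <- tibble::tibble(crit = c(1, 0))
  benefit <- topsis(m, c(crit = "benefit"))
  expect_equal(benefit$closeness, c(1, 0))
  cost <- topsis(m, c(crit = "cost"))
  expect_equal(cost$closeness, c(0, 1))
  sym <- topsis(tibble::tibble(a = c(1, 0, 0.5), b = c(0, 1, 0.5)),
                c(a = "benefit", b = "benefit"))
  expect_equal(sym$closeness, c(0.5, 0.5, 0.5))
  expect_error(topsis(tibble::tibble(x = c(1, 1)), c(x = "benefit")),
               "identical")
})

test_that("closeness matches the brute-force oracle on small random matrices", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    k <- sample(1:3, 1)
    R <- matrix(rnorm(n * k), n, k)
    dirs <- sample(c("benefit", "cost"), k, replace = TRUE)
    w <- runif(k, 0.2, 2)
    df <- tibble::as_tibble(as.data.frame(R))
    names(dirs) <- names(df)
    if (any(apply(R, 2, function(col) diff(range(col))) == 0)) next
    got <- topsis(df, dirs, weights = w)
    expect_equal(got$closeness, topsis_oracle(R, dirs, w), tolerance = 1e-12)
    expect_true(all(got$closeness >= 0 & got$closeness <= 1))
  }
})

test_that("improving a benefit criterion never decreases closeness", {
  set.seed(19)
  R <- matrix(runif(5 * 3), 5, 3)
  df <- tibble::as_tibble(as.data.frame(R))
  dirs <- setNames(c("benefit", "benefit", "cost"), names(df))
  base <- topsis(df, dirs)$closeness
  # raise alternative 3 on criterion 1 without moving the ideal
  df2 <- df
  df2[[1]][3] <- df2[[1]][3] + 0.5 * (max(df[[1]]) - df2[[1]][3])
  after <- topsis(df2, dirs)$closeness
  expect_gte(after[3], base[3])
})

test_that("negating a column and flipping its direction leaves closeness unchanged", {
  set.seed(23)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(6 * 2, sd = 2), 6, 2)))
  dirs <- setNames(c("benefit", "cost"), names(df))
  a <- topsis(zscore_standardize(df), dirs)$closeness
  df_flip <- df
  df_flip[[2]] <- -df_flip[[2]]
  dirs_flip <- dirs
  dirs_flip[2] <- "benefit"
  b <- topsis(zscore_standardize(df_flip), dirs_flip)$closeness
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("uniform weights equal the unweighted formulation", {
  set.seed(29)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(8 * 3), 8, 3)))
  dirs <- setNames(rep("benefit", 3), names(df))
  expect_equal(topsis(df, dirs)$closeness,
               topsis(df, dirs, weights = c(5, 5, 5))$closeness,
               tolerance = 1e-12)
})

test_that("tidy, glance and autoplot expose the ranking", {
  res <- topsis(tibble::tibble(x = c(1, 0, 0.2)), c(x = "benefit"))
  td <- tidy(res)
  expect_false(inherits(td, "topsis_result"))
  expect_identical(td$rank, 1:3)
  gl <- glance(res)
  expect_identical(gl$n_alternatives, 3L)
  expect_identical(gl$n_criteria, 1L)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("flavor evaluation runs three rankings with sourness and irritant as costs", {
  set.seed(31)
  n <- 100
  df <- tibble::tibble(
    accession = sprintf("A%03d", 1:n),
    sweetness = rnorm(n), sourness = rnorm(n), sweet_sour_ratio = rnorm(n),
    characteristic_flavor = rnorm(n), overall_acceptability = rnorm(n),
    green = rexp(n), floral = rexp(n), fruity = rexp(n),
    vegetable = rexp(n), fatty = rexp(n), irritant = rexp(n)
  )
  ev <- evaluate_flavor(df)
  expect_true(all(c("c_taste", "c_odor", "c_overall") %in% names(ev)))
  expect_true(all(ev$c_overall >= 0 & ev$c_overall <= 1))
  # statistically independent blocks give near-zero score correlation
  expect_lt(abs(cor(ev$c_taste, ev$c_odor)), 0.25)
  # permuting accessions permutes the result identically
  perm <- sample(n)
  ev_p <- evaluate_flavor(df[perm, ])
  expect_equal(ev_p$c_overall, ev$c_overall[perm])
  # an accession dominating every criterion in its favored direction is ideal
  df_dom <- df
  df_dom[1, c("sweetness", "sweet_sour_ratio", "characteristic_flavor",
              "overall_acceptability", "green", "floral", "fruity",
              "vegetable", "fatty")] <- 99
  df_dom[1, c("sourness", "irritant")] <- -99
  ev_dom <- evaluate_flavor(df_dom)
  expect_equal(ev_dom$c_overall[1], 1)
  taste_only_df <- dplyr::select(df, -green, -floral, -fruity,
                                 -vegetable, -fatty, -irritant)
  wrns <- capture_warnings(ev_taste_only <- evaluate_flavor(taste_only_df))
  expect_match(wrns, "odor block", all = FALSE)
  expect_match(wrns, "c_overall omitted", all = FALSE)
  expect_false("c_odor" %in% names(ev_taste_only))
})

test_that("class assignment honors sizes, breaks and stable tie-breaks", {
  set.seed(37)
  scores <- rnorm(71)
  cls <- assign_classes(scores, sizes = c(10, 20, 28, 13))
  expect_identical(as.integer(table(cls)[c("I", "II", "III", "IV")]),
                   c(10L, 20L, 28L, 13L))
  # class I holds exactly the 10 highest scores
  expect_setequal(which(cls == "I"), order(-scores)[1:10])

  top1 <- assign_classes(c(0.3, 0.9, 0.1), sizes = c(1, 2))
  expect_identical(as.character(top1), c("II", "I", "II"))

  # tie straddling a boundary resolves by input order
  tied <- assign_classes(c(0.5, 0.5, 0.1), sizes = c(1, 2))
  expect_identical(as.character(tied), c("I", "II", "II"))

  expect_error(assign_classes(rnorm(5), sizes = c(2, 2)), "sum to")
  expect_error(assign_classes(rnorm(5)), "exactly one")

  by_breaks <- assign_classes(c(0.9, 0.5, 0.2, 0.5), breaks = c(0.4, 0.8))
  expect_identical(as.character(by_breaks), c("I", "II", "III", "II"))
})
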