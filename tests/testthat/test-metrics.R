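test_that("odor activity values follow the concentration-threshold ratio", {
  expect_equal(odor_activity_value(1174.85, 45), 1174.85 / 45)
  expect_equal(odor_activity_value(17, 17), 1)
  # scale invariance
  expect_equal(odor_activity_value(330 * 7, 20 * 7), odor_activity_value(330, 20))
  expect_true(is.na(odor_activity_value(100, NA)))
  expect_error(odor_activity_value(1, 0), "positive")
})

test_that("the OAV reporting form rounds half-up with a <1 floor", {
  expect_identical(oav_report(c(26.1, 36.46, 0.65, 0.43, NA)),
                   c("26", "36", "1", "<1", NA))
  # machine check over the whole shipped reference: the reporting rule
  # reproduces every printed OAV
  ref <- volatile_table()
  with_thr <- ref[!is.na(ref$threshold), ]
  expect_identical(oav_report(with_thr$mean_conc / with_thr$threshold),
                   with_thr$oav_printed)
  expect_true(all(is.na(ref$oav_printed[is.na(ref$threshold)])))
})

test_that("sugar-acid ratios reproduce the printed reference rows", {
  expect_equal(sugar_acid_ratio(1290.00, 838.50, 251.33, 144.17), 5.38)
  expect_equal(sugar_acid_ratio(2391.07, 1358.22, 243.89, 143.57), 9.68)
  expect_equal(sugar_acid_ratio(100, 100, 150, 50), 1)
  expect_warning(out <- sugar_acid_ratio(1, 1, 0, 0), "undefined")
  expect_true(is.na(out))
  # whole-table property: recomputation agrees with every printed ratio
  t1 <- taste_metrics(taste_table(), digits = NULL)
  printed <- taste_table()$sugar_acid_ratio
  expect_true(all(abs(t1$sugar_acid_ratio - printed) <= 0.01 + 1e-9))
})

test_that("class aggregation sums member means and conserves the grand total", {
  ref <- volatile_table()
  agg <- aggregate_by_class(ref)
  expect_identical(sort(agg$class),
                   sort(c("alcohol", "aldehyde", "ester", "ketone", "other", "phenol")))
  expect_identical(agg$n_components[agg$class == "aldehyde"], 17L)
  expect_equal(attr(agg, "grand_total"), sum(ref$mean_conc))
  one <- aggregate_by_class(tibble::tibble(functional_class = "ester", mean_conc = 42))
  expect_equal(one$total_conc, 42)
  expect_warning(
    miss <- aggregate_by_class(tibble::tibble(functional_class = c("ester", NA),
                                              mean_conc = c(1, 2))),
    "other"
  )
  expect_equal(miss$total_conc[miss$class == "other"], 2)
  prec <- aggregate_by_class(ref, by = "precursor_class")
  expect_identical(sort(prec$n_components, decreasing = TRUE), c(31L, 17L, 8L, 4L))
})

test_that("odor-category aggregation sums member OAVs under the keyword map", {
  ref <- volatile_table()
  # the five volatiles named as the irritant-odor carriers all map to irritant
  irritant_ids <- c("V43", "V51", "V54", "V55", "V56")
  oavs <- ref |>
    dplyr::transmute(compound_id = abbreviation, description,
                     oav = odor_activity_value(mean_conc, threshold))
  members <- oavs[oavs$compound_id %in% irritant_ids, ]
  five <- odor_category_oav(members)
  expect_equal(five$category_oav[five$category == "irritant"],
               sum(members$oav, na.rm = TRUE))
  expect_identical(five$n_members[five$category == "irritant"], 5L)
  # over the full reference the irritant sum can only grow
  cats <- suppressMessages(odor_category_oav(oavs))
  expect_gte(cats$category_oav[cats$category == "irritant"],
             five$category_oav[five$category == "irritant"])

  # empty categories report zero; undefined OAVs are skipped, not zeroed
  toy <- tibble::tibble(compound_id = c("a", "b"),
                        description = c("grassy", "floral"),
                        oav = c(2, NA))
  tc <- odor_category_oav(toy)
  expect_equal(tc$category_oav[tc$category == "green"], 2)
  expect_equal(tc$category_oav[tc$category == "floral"], 0)
  expect_equal(tc$category_oav[tc$category == "fruity"], 0)

  # monotone: adding a positive-OAV member never decreases a category sum
  tc2 <- odor_category_oav(dplyr::add_row(toy, compound_id = "c",
                                          description = "green", oav = 0.4))
  expect_gt(tc2$category_oav[tc2$category == "green"],
            tc$category_oav[tc$category == "green"])

  # all-below-threshold: every category sum is below its member count
  sub <- tibble::tibble(compound_id = c("a", "b", "c"),
                        description = c("grassy", "grassy", "floral"),
                        oav = c(0.2, 0.9, 0.5))
  ts <- odor_category_oav(sub)
  expect_true(all(ts$category_oav < pmax(ts$n_members, 1)))

  expect_message(odor_category_oav(tibble::tibble(
    compound_id = "x", description = "chicken-like", oav = 3
  )), "no odor-category keyword")
})

test_that("descriptive statistics use sample SD and guard the zero mean", {
  out <- descriptive_stats(c(1, 3))
  expect_equal(out$mean, 2)
  expect_equal(out$sd, sqrt(2))
  expect_equal(out$cv, sqrt(2) / 2)
  const <- descriptive_stats(rep(5, 4))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_warning(zero <- descriptive_stats(c(-1, 1)), "undefined")
  expect_true(is.na(zero$cv))
  expect_error(descriptive_stats(3), "at least 2")
  # a planted CV is recovered from a large log-normal sample
  set.seed(21)
  x <- rlnorm(1e4, meanlog = log(1174) - log(1 + 0.54^2) / 2,
              sdlog = sqrt(log(1 + 0.54^2)))
  expect_lt(abs(descriptive_stats(x)$cv / 0.54 - 1), 0.05)
})
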