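cfg <- exposure_config()
tab <- shanghai_food_table()

test_that("per-food exposure formulas reproduce the survey arithmetic", {
  # mean level: mean concentration x mean intake
  expect_equal(food_exposure_mean(0.023, 208.5), 4.80, tolerance = 0.01 / 4.8)
  expect_equal(food_exposure_mean(0.025, 205.3), 5.13, tolerance = 0.01 / 5.1)
  expect_equal(food_exposure_mean(0, 100), 0)
  # median level: median concentration x median intake
  expect_equal(food_exposure_median(0.009, 200), 1.80)
  expect_equal(food_exposure_median(0.005, 200), 1.00)
  expect_equal(food_exposure_median(0.007, 0), 0)
  # P90 level: mean concentration x P90 intake
  expect_equal(food_exposure_p90(0.023, 300), 6.90)
  expect_equal(food_exposure_p90(0.043, 50), 2.15)
  expect_equal(food_exposure_p90(0.05, 0), 0)
  # extreme level: P90 concentration x P90 intake, override, fallback
  expect_equal(food_exposure_extreme(0.17, 300), 51.00)
  expect_equal(food_exposure_extreme(0.09, 300), 27.00)
  expect_equal(food_exposure_extreme(NA, 24.3, override = 0.10), 0.10)
  expect_warning(
    fb <- food_exposure_extreme(NA, 10, conc_mean = 0.02, conc_std = 0.01),
    "fallback")
  expect_equal(fb, (0.02 + 1.2816 * 0.01) * 10)
  expect_error(food_exposure_extreme(NA, 10, food = "mystery"), "mystery")
  expect_error(food_exposure_mean(-0.1, 10), "negative")
})

test_that("dietary totals and daily totals match the published breakdown", {
  expect_equal(dietary_total(tab, "mean"), 12.77, tolerance = 0.05 / 12.77)
  expect_equal(dietary_total(tab, "median"), 3.28, tolerance = 0.02 / 3.28)
  expect_equal(dietary_total(tab, "p90"), 20.57, tolerance = 0.05 / 20.57)
  expect_equal(dietary_total(tab, "extreme_p90"), 94.18,
               tolerance = 0.05 / 94.18)
  single <- as_food_table(data.frame(food = "x", conc_mean = 0.01,
                                     intake_mean = 100))
  expect_equal(dietary_total(single, "mean"), 1.0)
  expect_equal(total_exposure(12.77, 0.03, 3.93), 16.73)
  expect_equal(total_exposure(94.18, 0.05, 16.39), 110.62, tolerance = 2e-4)
  expect_equal(total_exposure(0, 0, 0), 0)
})

test_that("every cell of the published breakdown table is reproduced", {
  ref <- reported_exposure_breakdown()
  bd <- exposure_breakdown(tab, cfg)
  levels <- c("mean", "median", "p90", "extreme")
  ours_cols <- c("mean", "median", "p90", "extreme_p90")
  for (k in seq_along(levels)) {
    exp_col <- paste0("exposure_", levels[k])
    cr_col <- paste0("cr_", levels[k])
    per_food_ref <- ref[match(bd$per_food$food, ref$source), ]
    expect_false(anyNA(per_food_ref$source))
    ours_exp <- bd$per_food[[paste0("exposure_", ours_cols[k])]]
    ours_cr <- bd$per_food[[paste0("cr_", ours_cols[k])]]
    expect_true(all(abs(ours_exp - per_food_ref[[exp_col]]) <= 0.02),
                label = paste("per-food exposures at", levels[k]))
    expect_true(all(abs(ours_cr - per_food_ref[[cr_col]]) <= 0.3),
                label = paste("contribution rates at", levels[k]))
    # totals block: dietary, water, smoking, daily
    tot_ref <- ref[15:18, exp_col]
    tot_ours <- bd$totals[[paste0("exposure_", ours_cols[k])]]
    expect_true(all(abs(tot_ours - tot_ref) <= 0.05),
                label = paste("totals at", levels[k]))
  }
})

test_that("contribution rates normalise to 100 and match headline shares", {
  expo <- per_food_exposure(tab, "mean")
  cr <- contribution_rates(expo)
  expect_equal(sum(cr), 100, tolerance = 0.002)
  expect_equal(unname(cr["Rice"]), 37.6, tolerance = 0.3 / 37.6)
  expect_equal(unname(cr["Fresh vegetable"]), 40.2, tolerance = 0.3 / 40.2)
  expect_equal(unname(cr["Aquatic product"]), 8.5, tolerance = 0.3 / 8.5)
  cr_ex <- contribution_rates(per_food_exposure(tab, "extreme_p90"))
  expect_equal(unname(cr_ex["Fresh vegetable"]), 54.15,
               tolerance = 0.3 / 54.15)
  expect_equal(unname(contribution_rates(c(only = 5))), 100)
  expect_error(contribution_rates(c(a = 0, b = 0)), "not positive")
})

test_that("water, tobacco and PTDI-fraction arithmetic is exact", {
  expect_equal(water_exposure(0.025, 1.2), 0.03)
  expect_equal(water_exposure(0, 1.2), 0)
  expect_equal(water_exposure(0.05, 1.0), 0.05)
  expect_equal(tobacco_exposure(1.5, 1.0, 0), 0)
  expect_equal(tobacco_exposure(1.5, 1.0, 10), 15.0)
  # cigarettes/day implied by the smokers' mean dose of 13.8 ug/day
  expect_equal(tobacco_exposure(1.5, 1.0, 9.2), 13.8)
  expect_equal(ptdi_fraction(16.73, 49.5), 33.8, tolerance = 0.1 / 33.8)
  expect_equal(ptdi_fraction(12.77, 49.5), 25.8, tolerance = 0.1 / 25.8)
  expect_equal(ptdi_fraction(49.5, 49.5), 100)
  expect_error(ptdi_fraction(10, 0), "positive")
})

test_that("dietary totals are additive and monotone in every input", {
  expo <- per_food_exposure(tab, "mean")
  expect_equal(sum(expo), dietary_total(tab, "mean"))
  # increasing any concentration or intake never decreases any exposure
  for (col in c("conc_mean", "intake_mean", "conc_median", "intake_median",
                "conc_p90", "intake_p90")) {
    bumped <- tab
    bumped[[col]] <- bumped[[col]] * 1.1
    for (lv in c("mean", "median", "p90", "extreme_p90")) {
      expect_true(dietary_total(bumped, lv) >= dietary_total(tab, lv),
                  label = paste("monotonicity of", lv, "in", col))
    }
  }
})

test_that("results are invariant under equivalent unit expressions", {
  # concentration in ug/kg with intake in kg/day is the same dose
  rescaled <- tab
  for (col in c("conc_mean", "conc_std", "conc_median", "conc_p90")) {
    rescaled[[col]] <- rescaled[[col]] * 1000
  }
  for (col in c("intake_mean", "intake_std", "intake_median", "intake_p90")) {
    rescaled[[col]] <- rescaled[[col]] / 1000
  }
  rescaled$extreme_override <- tab$extreme_override
  for (lv in c("mean", "median", "p90", "extreme_p90")) {
    expect_equal(dietary_total(rescaled, lv), dietary_total(tab, lv))
  }
})

test_that("the mean-concentration median convention is available as a flag", {
  default <- per_food_exposure(tab, "median")
  expect_equal(unname(default["Rice"]), 0.009 * 200)
  variant <- per_food_exposure(tab, "median", median_conc_is_mean = TRUE)
  expect_equal(unname(variant["Rice"]), 0.023 * 200)
})

test_that("breakdown CSV output carries units and the PTDI summary", {
  bd <- exposure_breakdown(tab, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_exposure_breakdown(bd, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# units:.*ug/day")
  expect_match(lines[2], "ptdi_fraction")
  body <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(body), 18) # 14 foods + 4 totals rows
})
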