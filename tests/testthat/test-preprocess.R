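test_that("brood filtering applies the first-clutch, experiment, fledgling and broods-per-year rules", {
  # 10 records: 2 experimental, 1 second clutch, 1 zero-fledgling; the
  # remaining 6 valid records spread 3 + 2 + 1 over three population-years.
  rec <- dplyr::bind_rows(
    brood("A", 2000), brood("A", 2000), brood("A", 2000),      # 3 valid
    brood("B", 2000), brood("B", 2000),                        # 2 valid
    brood("C", 2000),                                          # singleton
    brood("A", 2000, is_experimental = TRUE),
    brood("B", 2000, is_experimental = TRUE),
    brood("C", 2000, is_first_clutch = FALSE),
    brood("C", 2000, fledgling_number = 0)
  )
  out <- filter_broods(rec, "fledgling_number")
  expect_equal(nrow(out), 5)  # singleton year C drops after row rules
  expect_setequal(unique(out$population_id), c("A", "B"))

  # threshold exactly met: 3 broods, one experimental -> year kept with 2
  r2 <- dplyr::bind_rows(brood("A"), brood("A"),
                         brood("A", is_experimental = TRUE))
  expect_equal(nrow(filter_broods(r2, "laying_date")), 2)

  # below threshold: 2 broods, one experimental -> year dropped entirely
  r3 <- dplyr::bind_rows(brood("A"), brood("A", is_experimental = TRUE))
  expect_equal(nrow(filter_broods(r3, "laying_date")), 0)

  # fledgling rule applies only to fledgling traits
  r4 <- dplyr::bind_rows(brood("A", fledgling_number = 0),
                         brood("A", fledgling_number = 0))
  expect_equal(nrow(filter_broods(r4, "laying_date")), 2)
  expect_equal(nrow(filter_broods(r4, "fledgling_number")), 0)

  # idempotence and order preservation
  once <- filter_broods(rec, "fledgling_number")
  expect_identical(filter_broods(once, "fledgling_number"), once)
  expect_identical(once, rec[c(1:5), ])

  # malformed record: fledglings > clutch names the record
  bad <- brood("Z", 2001, clutch_size = 5, fledgling_number = 7)
  expect_error(filter_broods(dplyr::bind_rows(rec, bad), "clutch_size"),
               "fledgling_number exceeds clutch_size.*Z.*2001")
})

test_that("annual aggregation uses the median for laying date and means elsewhere", {
  rec <- dplyr::bind_rows(
    brood("A", 2000, laying_date = 10, clutch_size = 8),
    brood("A", 2000, laying_date = 20, clutch_size = 9),
    brood("A", 2000, laying_date = 30, clutch_size = 10),
    brood("A", 2001, laying_date = 10, clutch_size = 13),
    brood("A", 2001, laying_date = 20, clutch_size = 8)
  )
  ld <- annual_average(rec, "laying_date")
  expect_equal(ld$values["A", "2000"], 20)      # odd-count median
  expect_equal(ld$values["A", "2001"], 15)      # even count: mean of middles

  rec4 <- dplyr::bind_rows(
    brood("A", 2000, clutch_size = 8), brood("A", 2000, clutch_size = 9),
    brood("A", 2000, clutch_size = 10), brood("A", 2000, clutch_size = 13))
  cs <- annual_average(rec4, "clutch_size")
  expect_equal(cs$values["A", "2000"], 10)      # arithmetic mean

  # fledgling success: mean of per-brood ratios
  recf <- dplyr::bind_rows(
    brood("A", 2000, clutch_size = 8, fledgling_number = 4),
    brood("A", 2000, clutch_size = 10, fledgling_number = 10))
  fs <- annual_average(recf, "fledgling_success")
  expect_equal(fs$values["A", "2000"], mean(c(0.5, 1)))

  # invariant to within-year record order
  perm <- rec[c(3, 5, 1, 4, 2), ]
  expect_equal(annual_average(perm, "laying_date")$values,
               ld$values)

  # population-years with < 2 broods never enter the panel
  rec1 <- dplyr::bind_rows(rec, brood("B", 2000, laying_date = 5))
  p1 <- annual_average(rec1, "laying_date")
  expect_false("B" %in% p1$populations)
  expect_true(all(p1$mask["A", c("2000", "2001")]))

  expect_error(annual_average(rec, "body_mass"))
  expect_error(annual_average(
    dplyr::bind_rows(brood("A", clutch_size = 0, fledgling_number = 0),
                     brood("A", clutch_size = 0, fledgling_number = 0)),
    "fledgling_success"), "clutch_size 0")
})

test_that("seasonal window means respect the calendar and the missing-day tolerance", {
  # constant series over a full year -> the constant
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  out <- seasonal_mean(tibble::tibble(date = days, value = 5))
  expect_equal(out$value, 5)
  expect_equal(out$n_expected, 120L)   # non-leap Feb-May: 28+31+30+31

  # leap year window has 121 days, Feb 29 included
  days04 <- seq(as.Date("2004-02-01"), as.Date("2004-05-31"), by = "day")
  out04 <- seasonal_mean(tibble::tibble(date = days04, value = 1))
  expect_equal(out04$n_days, 121L)
  expect_equal(out04$n_expected, 121L)

  # series equal to the day-of-window index 1..120 -> 60.5
  days01 <- seq(as.Date("2001-02-01"), as.Date("2001-05-31"), by = "day")
  expect_equal(
    seasonal_mean(tibble::tibble(date = days01, value = seq_along(days01)))$value,
    60.5)

  # > 10% of window days missing -> year dropped; <= 10% kept
  drop20 <- seasonal_mean(tibble::tibble(date = days01[-(1:20)], value = 1))
  expect_equal(nrow(drop20), 0)
  keep10 <- seasonal_mean(tibble::tibble(date = days01[-(1:10)], value = 1))
  expect_equal(keep10$year, 2001L)

  expect_error(seasonal_mean(tibble::tibble(date = as.Date(character()),
                                            value = numeric())), "empty")
})

test_that("detrending and normalizing leaves unit-SD, zero-mean, trend-free series", {
  # hand-checked OLS on {0, 1, -1, 0} over consecutive years:
  # slope -0.2, intercept at year offset 0.5 -> residuals (-.3,.9,-.9,.3)/sd
  p <- tiny_panel(matrix(c(0, 1, -1, 0), 1), years = 1:4)
  out <- detrend_normalize(p)
  r <- c(-0.3, 0.9, -0.9, 0.3)
  expect_equal(unname(out$values[1, ]), r / sd(r), tolerance = 1e-12)
  expect_equal(mean(out$values[1, ]), 0, tolerance = 1e-10)
  expect_equal(sd(out$values[1, ]), 1, tolerance = 1e-10)

  # invariance to adding any affine-in-year function to one population
  set.seed(4)
  vals <- matrix(rnorm(3 * 12), 3, 12)
  years <- 1991:2002
  base <- detrend_normalize(tiny_panel(vals, years))
  shifted <- vals
  shifted[2, ] <- shifted[2, ] + 100 - 3.7 * years
  expect_equal(detrend_normalize(tiny_panel(shifted, years))$values,
               base$values, tolerance = 1e-9)

  # mask unchanged, including with missing cells
  vals[1, 3] <- NA
  pm <- tiny_panel(vals, years)
  expect_identical(detrend_normalize(pm)$mask, pm$mask)

  # exactly linear series -> zero-variance error naming the population
  lin <- tiny_panel(matrix(2 * (1:5) + 3, 1), years = 1:5)
  expect_error(detrend_normalize(lin), "p1.*zero residual variance")
  # fewer than 3 observed years -> error
  expect_error(detrend_normalize(tiny_panel(matrix(c(1, 2), 1), years = 1:2)),
               "fewer than 3")
})

test_that("coefficient of variation uses the sample SD over the mean", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(c(10, 10, 10, 14)), 2 / 11,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})
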