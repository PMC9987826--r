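test_that("snag index maps field categories to numerical quantities", {
  expect_identical(snag_index(c("<=5", "<=5", "<=5")), 3)
  expect_identical(snag_index(c(">100", ">100", ">100")), 303)
  expect_identical(snag_index(c("6-15", "16-30", "31-50")), 53)
  expect_error(snag_index(c("<=5", "lots", ">100")), "unknown snag category")
  expect_error(snag_index(c("<=5", "<=5")), "3 values")
})

test_that("snag index is monotone in every size class", {
  cats <- mtoccu:::SNAG_CATEGORIES
  set.seed(7)
  for (rep in 1:50) {
    triple <- sample(cats, 3, replace = TRUE)
    slot <- sample(3, 1)
    pos <- match(triple[slot], cats)
    if (pos == length(cats)) next
    higher <- triple
    higher[slot] <- cats[sample(pos:length(cats), 1)]
    expect_gte(snag_index(higher), snag_index(triple))
  }
})

test_that("a minimal one-fire one-point fixture reads into a valid dataset", {
  dir <- withr::local_tempdir()
  writeLines(c("fire_id,year_burned,n_points,survey_years",
               "f1,2017,1,2018"), file.path(dir, "design.csv"))
  writeLines(c("fire_id,point_id,year,interval,type,detected,censored",
               "f1,p1,2018,1,1,1,0",
               "f1,p1,2018,2,1,,1",
               "f1,p1,2018,3,1,,1"), file.path(dir, "detections.csv"))
  writeLines(c("point_id,num_trees,activity", "p1,6,20"),
             file.path(dir, "beetle.csv"))
  writeLines(c("point_id,fire_id,elevation_m,latitude,pine_prop",
               "p1,f1,1500,38.2,0.5"), file.path(dir, "covariates.csv"))
  ds <- read_dataset(file.path(dir, "detections.csv"),
                     file.path(dir, "beetle.csv"),
                     file.path(dir, "covariates.csv"),
                     file.path(dir, "design.csv"))
  expect_s3_class(ds, "mtocc_data")
  expect_equal(nrow(ds$design$fires), 1)
  expect_equal(nrow(ds$covariates), 1)
  expect_equal(ds$beetle$activity, 20)
})

test_that("validation rejects activity above the per-tree maximum", {
  bt <- data.frame(point_id = "p1", num_trees = 6, activity = 49)
  expect_error(mini_dataset(beetle = bt), "activity")
  expect_silent(mini_dataset(beetle = data.frame(point_id = "p1",
                                                 num_trees = 6,
                                                 activity = 48)))
})

test_that("validation enforces structural invariants", {
  # unknown point
  expect_error(mini_dataset(detections = det_row("p9", 2018, detected = 1)),
               "unknown point")
  # intervals after first detection must be censored
  bad <- rbind(det_row("p1", 2018, 1, detected = 1),
               det_row("p1", 2018, 2, detected = 0))
  expect_error(mini_dataset(detections = bad), "censored")
  # censored intervals carry no detected value
  bad2 <- det_row("p1", 2018, 1)
  bad2$censored <- 1
  expect_error(mini_dataset(detections = bad2), "no detected value")
  # detection year outside the fire's survey years
  expect_error(mini_dataset(detections = det_row("p1", 2016, detected = 0)),
               "survey years")
  # pine proportion out of range
  cv <- mini_covariates()
  cv$pine_prop[1] <- 1.2
  expect_error(survey_dataset(mini_design(), empty_detections(),
                              empty_beetle(), cv), "pine_prop")
})

test_that("write/read round trip reproduces the dataset", {
  sim <- simulate_dataset(generator_config(seed = 3))
  dir <- withr::local_tempdir()
  write_dataset(sim$dataset, dir)
  back <- read_dataset(file.path(dir, "detections.csv"),
                       file.path(dir, "beetle.csv"),
                       file.path(dir, "covariates.csv"),
                       file.path(dir, "design.csv"))
  expect_equal(back$design$fires, sim$dataset$design$fires)
  expect_equal(back$design$survey_years, sim$dataset$design$survey_years)
  expect_equal(back$detections, sim$dataset$detections)
  expect_equal(back$beetle, sim$dataset$beetle)
  cv0 <- sim$dataset$covariates
  expect_equal(back$covariates[names(cv0)], cv0, tolerance = 1e-15)
})

test_that("standardization gives z-scores and stores invertible constants", {
  cv <- mini_covariates()
  cv$elevation_m <- c(1000, 2000)
  ds <- survey_dataset(mini_design(), empty_detections(), empty_beetle(), cv)
  std <- standardize_covariates(ds)
  expect_equal(std$std$elev, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # invertible from stored constants
  expect_equal(std$std$elev * std$scaling$elevation["spread"] +
                 std$scaling$elevation["center"],
               cv$elevation_m, tolerance = 1e-12, ignore_attr = TRUE)
  # pine untouched
  expect_identical(std$std$pine, cv$pine_prop)
  # idempotent: re-standardizing returns identical values
  std2 <- standardize_covariates(std)
  expect_identical(std2$std, std$std)
  # an already mean-0 sd-1 raw column passes through unchanged
  cv2 <- cv
  cv2$elevation_m <- c(-1, 1) / sqrt(2)
  std3 <- standardize_covariates(
    survey_dataset(mini_design(), empty_detections(), empty_beetle(), cv2))
  expect_equal(std3$std$elev, cv2$elevation_m, tolerance = 1e-12)
})

test_that("zero-variance point covariates are rejected by name", {
  cv <- mini_covariates()
  cv$elevation_m <- c(1500, 1500)
  ds <- survey_dataset(mini_design(), empty_detections(), empty_beetle(), cv)
  expect_error(standardize_covariates(ds), "elevation")
})
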