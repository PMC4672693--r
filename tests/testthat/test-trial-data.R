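test_that("constructor validates arms, departures and day grid", {
  d <- tiny_dataset()
  expect_s3_class(d, "trial_data")
  expect_identical(d$n, 3L)
  expect_identical(d$m, 2L)
  expect_false(any(d$missing_mask))

  expect_error(trial_data(R = c(1, 0), D = c(0, 3), Y = matrix(0, 2, 2),
                          visit_days = c(90, 180)), "0\\.\\.m")
  expect_error(trial_data(R = c(1, 0), D = c(1, 0), Y = matrix(0, 2, 2),
                          visit_days = c(90, 180)), "D = 0")
  expect_warning(trial_data(R = c(1, 0), D = c(1, 0), Y = matrix(0, 2, 2),
                            visit_days = c(90, 180), permissive = TRUE),
                 "D = 0")
  expect_error(trial_data(R = c(1, 0), D = c(0, 0), Y = matrix(0, 2, 2),
                          visit_days = c(180, 90)), "increasing")
  # exact day must agree with the grouped departure interval
  expect_error(tiny_dataset(T_days = c(10, 400, 200)), "inconsistent")
  expect_silent(tiny_dataset(T_days = c(10, 150, Inf)))
})

test_that("missing outcomes are recorded in the mask, not filled", {
  Y <- rbind(c(12, NA), c(20, 21), c(25, 24))
  d <- tiny_dataset(Y = Y)
  expect_identical(sum(d$missing_mask), 1L)
  expect_true(d$missing_mask[1, 2])
  expect_true(is.na(d$Y[1, 2]))
})

test_that("compliance type is observed in controls, latent otherwise", {
  d <- tiny_dataset()
  cs <- derive_compliance(d)
  expect_identical(cs$C, c(NA_integer_, 1L, 2L))
  expect_identical(cs$known, c(FALSE, TRUE, TRUE))
  all_ctrl <- trial_data(R = c(0, 0), D = c(2, 1), Y = matrix(0, 2, 2),
                         visit_days = c(90, 180))
  expect_false(anyNA(derive_compliance(all_ctrl)$C))
})

test_that("day-to-visit grouping uses (t_c, t_{c+1}] intervals", {
  grid <- c(90, 180, 365, 550, 730)
  expect_identical(days_to_grouped(100, grid), 1L)
  expect_identical(days_to_grouped("never", grid), 5L)
  expect_identical(days_to_grouped(90, grid), 0L)   # boundary: earlier interval
  expect_identical(days_to_grouped(730, grid), 4L)
  expect_identical(days_to_grouped(731, grid), 5L)
  expect_error(days_to_grouped(0, grid), "positive")
  # monotone non-decreasing in T
  ts <- sort(c(runif(200, 1, 800), grid))
  grp <- vapply(ts, days_to_grouped, integer(1), visit_days = grid)
  expect_true(all(diff(grp) >= 0))
})

test_that("CSV round-trip preserves values, mask and metadata", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,R,D,y1,y2",
               "a,1,0,12,14",
               "b,0,1,20,21",
               "c,0,2,25,24"), csv)
  d <- read_trial_csv(csv, visit_days = c(90, 180))
  expect_identical(d$n, 3L)
  expect_identical(d$D, c(0L, 1L, 2L))
  expect_false(any(d$missing_mask))

  # empty cell becomes exactly one masked entry
  writeLines(c("id,R,D,y1,y2", "a,1,0,12,", "b,0,1,20,21"), csv)
  d2 <- read_trial_csv(csv, visit_days = c(90, 180))
  expect_identical(sum(d2$missing_mask), 1L)

  # write-then-read reproduces everything bit-exactly
  set.seed(11)
  d3 <- generate_dataset(sim_config(n = 40, missingness_rate = 0.15,
                                    base_seed = 3), 1)
  out <- tempfile(fileext = ".csv")
  write_trial_csv(d3, out)
  d4 <- read_trial_csv(out, visit_days = d3$visit_days)
  expect_identical(d4$Y, unname(d3$Y))
  expect_identical(d4$missing_mask, unname(d3$missing_mask))
  expect_identical(d4$R, d3$R)
  expect_identical(d4$D, d3$D)
})

test_that("CSV errors name the offending cell or rule", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,R,D,y1,y2", "a,1,0,12,oops"), csv)
  expect_error(read_trial_csv(csv, visit_days = c(90, 180)), "y2.*row 1")
  writeLines(c("id,R,D,y1,y2", "a,1,3,12,14"), csv)
  expect_error(read_trial_csv(csv, visit_days = c(90, 180)), "0\\.\\.m")
  writeLines(c("id,R,D,y1,y2", "a,1,1,12,14"), csv)
  expect_error(read_trial_csv(csv, visit_days = c(90, 180)), "D = 0")
  expect_warning(read_trial_csv(csv, visit_days = c(90, 180),
                                permissive = TRUE), "D = 0")
  # schema remapping
  writeLines(c("subject,arm,dep,h1,h2", "a,1,0,12,14"), csv)
  d <- read_trial_csv(csv, visit_days = c(90, 180),
                      schema = list(id = "subject", R = "arm", D = "dep",
                                    y1 = "h1", y2 = "h2"))
  expect_identical(d$Y[1, ], c(12, 14))
})
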