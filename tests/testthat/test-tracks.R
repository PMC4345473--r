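test_that("velocity and displacement follow their definitions", {
  # 3-4-5 triangle: one step of length 5 in one minute
  tr <- data.frame(track_id = "a", t_min = c(0, 1),
                   x_um = c(0, 3), y_um = c(0, 4))
  s <- track_summaries(tr)
  expect_equal(s$velocity_um_min, 5)
  expect_equal(s$displacement_um, 5)

  # out-and-back: path 10 over 2 min, displacement 0
  tr <- data.frame(track_id = "a", t_min = 0:2,
                   x_um = c(0, 0, 0), y_um = c(0, 5, 0))
  s <- track_summaries(tr)
  expect_equal(s$velocity_um_min, 5)
  expect_equal(s$displacement_um, 0)

  expect_error(track_summaries(
    data.frame(track_id = "a", t_min = 0, x_um = 0, y_um = 0)),
    class = "gsn_invalid_error")
})

test_that("displacement never exceeds path length on random walks", {
  tracks <- synthesize_tracks(30, step_sd = 2, n_steps = 20, seed = 7)
  s <- track_summaries(tracks)
  expect_true(all(s$displacement_um <= s$path_length_um + 1e-9))
  expect_true(all(s$velocity_um_min >= 0))
})

test_that("proximity partition splits strictly at the threshold", {
  mk <- function(id, x) data.frame(track_id = id, t_min = 0:1,
                                   x_um = c(x, x + 1), y_um = 0)
  tracks <- rbind(mk("near", 49.9), mk("edge", 50), mk("far", 80))
  p <- partition_tracks(tracks, centre = c(0, 0), threshold_um = 50)
  expect_identical(p$near, "near")
  expect_setequal(p$far, c("edge", "far"))
  # classification uses the first position, not later ones
  moved <- mk("m", 10)
  moved$x_um <- c(10, 200)
  p2 <- partition_tracks(moved, centre = c(0, 0))
  expect_identical(p2$near, "m")

  empty <- data.frame(track_id = character(), t_min = numeric(),
                      x_um = numeric(), y_um = numeric())
  p3 <- partition_tracks(empty, centre = c(0, 0))
  expect_length(p3$near, 0)
  expect_length(p3$far, 0)

  expect_error(partition_tracks(tracks, c(0, 0), threshold_um = 0),
               class = "gsn_invalid_error")
})

test_that("the track generator is seed-reproducible and analytically sane", {
  a <- synthesize_tracks(5, step_sd = 1.5, n_steps = 10, seed = 123)
  b <- synthesize_tracks(5, step_sd = 1.5, n_steps = 10, seed = 123)
  expect_identical(a, b)
  c <- synthesize_tracks(5, step_sd = 1.5, n_steps = 10, seed = 124)
  expect_false(identical(a, c))

  # pure drift: displacement = path = drift * steps, velocity = drift/interval
  d <- synthesize_tracks(3, drift = c(1, 0), step_sd = 0, n_steps = 10,
                         interval_min = 1, seed = 1)
  s <- track_summaries(d)
  expect_equal(s$displacement_um, rep(10, 3))
  expect_equal(s$path_length_um, rep(10, 3))
  expect_equal(s$velocity_um_min, rep(1, 3))

  # no drift, no noise: nothing moves
  s0 <- track_summaries(synthesize_tracks(2, drift = c(0, 0), step_sd = 0,
                                          n_steps = 5, seed = 1))
  expect_equal(s0$velocity_um_min, c(0, 0))

  expect_error(synthesize_tracks(0, seed = 1), class = "gsn_invalid_error")
  expect_error(synthesize_tracks(2, n_steps = 0, seed = 1),
               class = "gsn_invalid_error")
  expect_error(synthesize_tracks(2, step_sd = -1, seed = 1),
               class = "gsn_invalid_error")
})

test_that("with zero drift mean displacement grows sub-linearly in steps", {
  # diffusive scaling: E[displacement] ~ sqrt(steps); check loosely that
  # quadrupling the steps far less than quadruples the mean displacement
  mean_disp <- function(steps, seed) {
    mean(track_summaries(synthesize_tracks(60, drift = c(0, 0), step_sd = 2,
                                           n_steps = steps,
                                           seed = seed))$displacement_um)
  }
  d1 <- mean_disp(10, 31)
  d4 <- mean_disp(40, 32)
  expect_lt(d4 / d1, 3)
  expect_gt(d4 / d1, 1)
})

test_that("track CSV round-trips through the documented dialect", {
  tracks <- synthesize_tracks(4, step_sd = 1, n_steps = 5, seed = 99,
                              cell_type = "LTi")
  f <- tempfile(fileext = ".csv")
  write_tracks(tracks, f)
  header <- readLines(f, n = 1)
  expect_equal(header, "track_id,t_min,x_um,y_um,cell_type")
  back <- read_tracks(f)
  expect_equal(back$x_um, tracks$x_um, tolerance = 1e-12)
  expect_identical(back$track_id, tracks$track_id)

  # non-uniform sampling is rejected
  bad <- data.frame(track_id = "a", t_min = c(0, 1, 3),
                    x_um = 0:2, y_um = 0)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_tracks(f2), class = "gsn_format_error")
  expect_error(read_tracks(tempfile()), class = "gsn_not_found_error")
})
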