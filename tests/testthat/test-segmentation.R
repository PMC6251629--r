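test_that("velocity is zero for a stationary animal and exact for straight motion", {
  pos <- line_position(0, duration_s = 20)
  vel <- compute_velocity(pos)
  expect_true(all(vel$speed_cm_s == 0))

  pos10 <- line_position(10, duration_s = 60)
  vel10 <- compute_velocity(pos10)
  inner <- 30:(nrow(vel10) - 30)
  expect_true(all(abs(vel10$speed_cm_s[inner] - 10) < 0.1))
})

test_that("position smoothing suppresses tracking jitter", {
  set.seed(11)
  pos <- line_position(0, duration_s = 60)
  pos$x_cm <- pos$x_cm + rnorm(nrow(pos), 0, 0.2)
  pos$y_cm <- pos$y_cm + rnorm(nrow(pos), 0, 0.2)
  vel <- compute_velocity(pos, smooth_s = 0.5)
  expect_lt(mean(vel$speed_cm_s), 0.5)
})

test_that("duplicate timestamps are rejected", {
  pos <- line_position(5, duration_s = 2)
  pos$time_s[4] <- pos$time_s[3]
  expect_error(compute_velocity(pos), "duplicates|increasing")
})

test_that("constant-speed traces produce single segments with the 20-s rest cap", {
  vel <- tibble::tibble(time_s = seq(0, 100 - 1 / 30, by = 1 / 30),
                        speed_cm_s = 10)
  seg <- segment_states(vel)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "run")
  expect_equal(c(seg$start_s, seg$end_s), c(0, 100), tolerance = 1e-6)

  vel0 <- tibble::tibble(time_s = seq(0, 60 - 1 / 30, by = 1 / 30),
                         speed_cm_s = 0)
  seg0 <- segment_states(vel0)
  expect_equal(nrow(seg0), 1)
  expect_equal(seg0$state, "rest")
  expect_equal(c(seg0$start_s, seg0$end_s), c(0, 20))
})

test_that("threshold ties count as running and intermediate speeds as neither", {
  vel <- tibble::tibble(time_s = seq(0, 10 - 1 / 30, by = 1 / 30),
                        speed_cm_s = 7)
  seg <- segment_states(vel)
  expect_equal(seg$state, "run")
  vel_mid <- tibble::tibble(time_s = seq(0, 10 - 1 / 30, by = 1 / 30),
                            speed_cm_s = 3)
  expect_equal(nrow(segment_states(vel_mid)), 0)
})

test_that("alternating speed blocks segment at the block boundaries", {
  rate <- 30
  block_s <- 5
  n_blocks <- 8
  speed <- rep(rep(c(10, 0), length.out = n_blocks), each = block_s * rate)
  tt <- (seq_along(speed) - 1) / rate
  seg <- segment_states(tibble::tibble(time_s = tt, speed_cm_s = speed))
  # brute-force oracle: scan the labeled samples for maximal runs
  lab <- ifelse(speed >= 7, "run", "rest")
  rr <- rle(lab)
  ends <- cumsum(rr$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  expect_equal(nrow(seg), n_blocks)
  expect_equal(seg$state, rr$values)
  expect_equal(seg$start_s, tt[starts], tolerance = 1e-9)
  expect_equal(seg$end_s, tt[ends] + 1 / rate, tolerance = 1e-9)
})

test_that("rest bouts are truncated to their first 20 s", {
  rate <- 30
  speed <- c(rep(10, 10 * rate), rep(0, 50 * rate), rep(10, 10 * rate))
  tt <- (seq_along(speed) - 1) / rate
  seg <- segment_states(tibble::tibble(time_s = tt, speed_cm_s = speed))
  rest <- seg[seg$state == "rest", ]
  expect_equal(nrow(rest), 1)
  expect_equal(rest$start_s, 10, tolerance = 0.05)
  expect_equal(rest$end_s - rest$start_s, 20)
})

test_that("window restriction is exact interval intersection", {
  seg <- new_segments(c(1500, 2100, 3700), c(2100, 2400, 3900),
                      c("run", "rest", "run"))
  w <- restrict_to_window(seg, c(1800, 3600))
  expect_equal(w$start_s, c(1800, 2100))
  expect_equal(w$end_s, c(2100, 2400))

  expect_equal(nrow(restrict_to_window(seg, c(10000, 20000))), 0)

  # interval-arithmetic oracle on random segments
  set.seed(21)
  for (rep in 1:5) {
    st <- sort(runif(10, 0, 100))
    en <- st + runif(10, 0.5, 3)
    en <- pmin(en, c(st[-1], Inf) - 1e-6)
    segs <- new_segments(st, en, rep(c("run", "rest"), 5))
    win <- sort(runif(2, 0, 100))
    if (diff(win) < 1) next
    out <- restrict_to_window(segs, win)
    grid <- seq(win[1], win[2], by = 1e-3)
    covered <- rep(FALSE, length(grid))
    for (i in seq_len(nrow(segs))) {
      covered <- covered | (grid >= segs$start_s[i] & grid < segs$end_s[i])
    }
    expect_equal(sum(out$end_s - out$start_s), mean(covered) * diff(win),
                 tolerance = 0.01)
  }
})

test_that("segmentation recovers simulated state intervals within the smoothing window", {
  p <- sim_params(duration_s = 300)
  pos <- simulate_position(p, seed = 7)
  seg <- segment_states(compute_velocity(pos$position))
  truth <- pos$states
  # interior truth bouts (not clipped by the session edges)
  run_t <- truth[truth$state == "run" & truth$start_s > 0 &
                   truth$end_s < 300, ]
  run_d <- seg[seg$state == "run", ]
  for (i in seq_len(nrow(run_t))) {
    j <- which.min(abs(run_d$start_s - run_t$start_s[i]))
    expect_lt(abs(run_d$start_s[j] - run_t$start_s[i]), 0.5)
    expect_lt(abs(run_d$end_s[j] - run_t$end_s[i]), 0.5)
  }
  # run and rest never overlap
  seg_sorted <- seg[order(seg$start_s), ]
  expect_true(all(seg_sorted$start_s[-1] >= seg_sorted$end_s[-nrow(seg_sorted)] - 1e-9))
})
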