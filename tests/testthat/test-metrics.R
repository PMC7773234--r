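test_that("area durations sum interval lengths, split combined codes, skip uncoded", {
  ints <- fake_intervals(rep("0102", 10))
  d <- area_durations(ints)
  expect_length(d, 18)
  expect_equal(d[["0102"]], 5)
  expect_equal(attr(d, "total_s"), 5)

  ints2 <- fake_intervals(c(rep("1602", 4), rep(uncoded_label(), 2), "0103"))
  d2 <- area_durations(ints2)
  expect_equal(d2[["0102"]], 1)   # 2 s of 1602 split evenly
  expect_equal(d2[["0602"]], 1)
  expect_equal(d2[["0103"]], 0.5)
  expect_equal(attr(d2, "total_s"), 2.5)  # uncoded time excluded
})

test_that("event counting restricts to the area set, collapses runs", {
  expect_equal(count_events(rep("0102", 10)), 0)
  expect_equal(count_events(c("A1" = "0102", "0102", "0202", "0202", "0102")), 2)
  # an occlusal interruption returning to the same smooth area is not a change
  expect_equal(count_events(c("0102", "0101", "0102"), area_set = smooth_areas()), 0)
  expect_equal(count_events(character(0)), 0)
  expect_equal(count_events(rep(uncoded_label(), 5)), 0)
  # brute-force oracle on random sequences
  withr::with_seed(101, {
    for (rep in 1:50) {
      labs <- sample(c(enumerate_areas(TRUE), uncoded_label()), 100, replace = TRUE)
      set <- sample(enumerate_areas(TRUE), 10)
      expect_equal(count_events(labs, set), oracle_events(labs, set))
    }
  })
})

test_that("consistency matches its closed form and clamps at zero", {
  expect_equal(consistency(b = 11, x = 120, i_reached = 12, n = 12),
               (1 - 11 / 120), tolerance = 1e-12)
  expect_equal(round(consistency(11, 120, 12, 12), 4), 0.9083)
  expect_equal(consistency(120, 60, 12, 12), 0)  # b >= x clamps
  expect_equal(consistency(0, 60, 12, 12), 1)    # no changes, all areas
  expect_equal(consistency(0, 60, 6, 12), 0.5)
  expect_error(consistency(5, 0, 6, 12), class = "tt_validation_error")
  expect_error(consistency(5, 10, 13, 12), class = "tt_validation_error")
})

test_that("isochronicity matches its closed form at the extremes and a hand case", {
  expect_equal(isochronicity(rep(10, 12)), 1)
  expect_equal(isochronicity(c(120, rep(0, 11))), 0)
  # hand evaluation: n = 12, d = (x/2, x/2, 0, ...) -> 1 - (12/22)*(20/12)
  x <- 100
  d <- c(x / 2, x / 2, rep(0, 10))
  expect_equal(isochronicity(d, x), 1 - (12 / 22) * (2 * abs(1 / 2 - 1 / 12) + 10 / 12),
               tolerance = 1e-12)
  expect_equal(round(isochronicity(d, x), 4), 0.0909)
  expect_error(isochronicity(rep(1, 12), x = 0), class = "tt_validation_error")
  expect_error(isochronicity(c(5, 5), x = 20), class = "tt_validation_error")
})

test_that("C and I stay in [0, 1] and I is permutation invariant (randomized)", {
  withr::with_seed(111, {
    for (rep in 1:300) {
      n <- 12
      d <- runif(n) * rbinom(n, 1, 0.8)
      if (sum(d) == 0) d[1] <- 1
      x <- sum(d)
      b <- sample(0:200, 1)
      i <- sum(d > 0)
      C <- consistency(b, x, i, n)
      I <- isochronicity(d, x)
      expect_gte(C, 0); expect_lte(C, 1)
      expect_gte(I, 0); expect_lte(I, 1)
      expect_equal(isochronicity(sample(d), x), I, tolerance = 1e-12)
    }
  })
})

test_that("TSI composes C and I on the 12 smooth areas, combined codes included", {
  # 12 smooth areas, equal time (10 bins each), 11 changes, x = 60 s
  labs <- unlist(lapply(smooth_areas(), rep, 10))
  ts <- tsi(fake_intervals(labs))
  expect_equal(ts$b, 11L)
  expect_equal(ts$x, 60)
  expect_equal(ts$i_reached, 12L)
  expect_equal(ts$I, 1)
  expect_equal(ts$C, (1 - 11 / 60))
  expect_equal(ts$TSI, ts$C + ts$I)

  # occlusal intervals are ignored entirely; interruption is not a change
  labs2 <- c(rep("0102", 4), rep("0101", 4), rep("0102", 4), rep("0103", 4))
  ts2 <- tsi(fake_intervals(labs2))
  expect_equal(ts2$b, 1L)
  expect_equal(ts2$x, 6)
  expect_equal(ts2$i_reached, 2L)

  # combined codes contribute to x and count as moves
  labs3 <- c(rep("0202", 4), rep("1602", 4))
  ts3 <- tsi(fake_intervals(labs3))
  expect_equal(ts3$x, 4)
  expect_equal(ts3$b, 1L)
  expect_equal(ts3$i_reached, 3L)  # 0202 + split halves on 0102 and 0602

  # a session with only occlusal time has no defined TSI
  expect_error(tsi(fake_intervals(rep("0101", 6))), class = "tt_validation_error")

  # range check over random sessions
  withr::with_seed(121, {
    for (rep in 1:50) {
      labs <- sample(c(enumerate_areas(TRUE), uncoded_label()), 80, replace = TRUE)
      res <- tryCatch(tsi(fake_intervals(labs)), tt_validation_error = function(e) NULL)
      if (!is.null(res)) {
        expect_gte(res$TSI, 0); expect_lte(res$TSI, 2)
        expect_equal(res$TSI, res$C + res$I)
        expect_lte(res$i_reached, res$n)
      }
    }
  })
})

test_that("metrics are idempotent under merging adjacent equal-label runs", {
  # doubling every interval (same labels, half bins merged) preserves b,
  # i_reached and the duration proportions driving C and I
  labs <- c(rep("0102", 4), rep("0202", 4), rep("0103", 2), rep("0102", 2))
  a <- tsi(fake_intervals(labs, bin_s = 0.5))
  b <- tsi(fake_intervals(rep(labs, each = 2), bin_s = 0.25))
  expect_equal(a$b, b$b)
  expect_equal(a$i_reached, b$i_reached)
  expect_equal(a$x, b$x)
  expect_equal(a$TSI, b$TSI, tolerance = 1e-12)
})

test_that("session_metrics emits one row with durations, events and scores", {
  labs <- c(rep("0102", 6), rep("0101", 2), rep("0203", 4))
  m <- session_metrics(fake_intervals(labs, source = "MT"))
  expect_equal(nrow(m), 1)
  expect_equal(m$source, "MT")
  expect_equal(m$events, 2L)
  expect_equal(m$total_coded_s, 6)
  expect_equal(m$d_0102, 3)
  expect_equal(m$d_0203, 2)
  expect_equal(m$TSI, m$C + m$I)
  # all-occlusal session: NA scores with warning, durations still reported
  expect_warning(m2 <- session_metrics(fake_intervals(rep("0101", 4))), "TSI")
  expect_true(is.na(m2$TSI))
  expect_equal(m2$d_0101, 2)
})
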