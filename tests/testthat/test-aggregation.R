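test_that("majority vote picks the most frequent label, first-in-time on ties", {
  expect_equal(majority_label(c(rep("0102", 30), rep("0202", 20))), "0102")
  # tie of 2 vs 2: the label occurring first wins
  expect_equal(majority_label(c("0202", "0102", "0102", "0202")), "0202")
  expect_equal(majority_label(rep("0603", 50)), "0603")
  # uncoded samples are ignored; all-uncoded input yields the sentinel
  expect_equal(majority_label(c("uncoded", "0102", "uncoded")), "0102")
  expect_equal(majority_label(rep(uncoded_label(), 5)), uncoded_label())
  expect_equal(majority_label(character(0)), uncoded_label())
})

test_that("binning matches per-interval brute force on randomized streams", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      n <- sample(40:160, 1)
      t <- (0:(n - 1)) / 100
      labs <- sample(c(enumerate_areas(TRUE)[1:5], uncoded_label()), n,
                     replace = TRUE, prob = c(rep(1, 5), 0.3))
      ints <- bin_stream(tibble::tibble(t_s = t, label = labs), bin_s = 0.5)
      idx <- floor(t / 0.5 + 1e-9)
      for (k in unique(idx)) {
        expect_equal(ints$label[ints$index == k], oracle_majority(labs[idx == k]))
      }
    }
  })
})

test_that("tie-break is deterministic under permutation of later occurrences", {
  # two labels, 3 each; first occurrence fixed, later positions permuted
  base <- c("0102", "0202")
  withr::with_seed(5, {
    for (rep in 1:20) {
      tail_part <- sample(c("0102", "0102", "0202", "0202"))
      labs <- c(base, tail_part)
      expect_equal(majority_label(labs), "0102")
    }
  })
})

test_that("interval grids tile the session, keep trailing partials, conserve duration", {
  vo <- vo_stream(0, 60, "0102")
  ints <- bin_stream(vo, 0.5)
  expect_equal(nrow(ints), 120)
  expect_equal(sum(ints$end_s - ints$start_s), 60)

  vo2 <- vo_stream(0, 60.2, "0102")
  ints2 <- bin_stream(vo2, 0.5)
  expect_equal(nrow(ints2), 121)
  expect_equal(ints2$end_s[121] - ints2$start_s[121], 0.2)
  expect_equal(ints2$label[121], "0102")  # partial interval still labelled
  expect_equal(sum(ints2$end_s - ints2$start_s), 60.2)

  expect_error(bin_stream(vo, 0), class = "tt_validation_error")
})

test_that("aggregation never increases the transition count", {
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(30:200, 1)
      labs <- sample(enumerate_areas()[1:4], n, replace = TRUE)
      ints <- bin_stream(tibble::tibble(t_s = (0:(n - 1)) / 100, label = labs))
      raw_tr <- sum(labs[-1] != labs[-n])
      agg <- ints$label[!is_uncoded(ints$label)]
      agg_tr <- if (length(agg) > 1) sum(agg[-1] != agg[-length(agg)]) else 0
      expect_lte(agg_tr, raw_tr)
    }
  })
})

test_that("angle classification respects the regional thresholds and the side flag", {
  expect_equal(classify_surface_from_angle(25, "molar", side = "vestibular_side"), "02")
  expect_equal(classify_surface_from_angle(15, "molar"), "01")
  expect_equal(classify_surface_from_angle(15, "anterior", side = "oral_side"), "03")
  expect_equal(classify_surface_from_angle(13, "anterior"), "01")  # at threshold
  expect_equal(classify_surface_from_angle(20, "molar"), "01")
  expect_error(classify_surface_from_angle(95, "molar"), class = "tt_validation_error")
  expect_error(classify_surface_from_angle(10, "premolar"), class = "tt_validation_error")

  # stream-level reclassification: a clear occlusal angle flips a recorded
  # smooth sample; combined codes are never touched
  mt <- mt_stream(c(0, 0.01, 0.02), c("0102", "0101", "1602"),
                  angle = c(5, 40, 5), region = rep("molar", 3))
  out <- classify_stream_surfaces(mt)$records$area
  expect_equal(out, c("0101", "0102", "1602"))
})

test_that("threshold perturbation harness reports the changed-label fraction", {
  withr::with_seed(51, {
    n <- 500
    mt <- mt_stream((0:(n - 1)) / 100, rep("0102", n),
                    angle = runif(n, 10, 30), region = rep("molar", n))
    sens <- threshold_sensitivity(mt, delta_deg = c(-3, 0, 3))
    expect_equal(nrow(sens), 3)
    expect_equal(sens$changed_fraction[sens$delta_deg == 0], 0)
    # shifting the threshold by +3 deg flips exactly the angles in (20, 23]
    frac_expected <- mean(mt$records$angle_deg > 20 & mt$records$angle_deg <= 23)
    expect_equal(sens$changed_fraction[sens$delta_deg == 3], frac_expected)
  })
})

test_that("pairing intersects coded spans and flags uncoded intervals", {
  vo <- fake_intervals(c("0102", "0202", "0302", "0102"))
  mt <- fake_intervals(c("0102", "0202", "0302", "0102"), source = "MT")
  p <- pair_streams(vo, mt)
  expect_true(all(p$vo_label == p$mt_label))
  expect_equal(matching_proportion(p), 100)

  # longer VO stream: surplus dropped with warning, MT length kept
  vo_long <- fake_intervals(rep("0102", 6))
  mt_short <- fake_intervals(rep("0102", 4), source = "MT")
  expect_warning(p2 <- pair_streams(vo_long, mt_short), "differ")
  expect_equal(nrow(p2), 4)

  # uncoded on either side leaves the pair out of the denominator
  vo_u <- fake_intervals(c("0102", uncoded_label(), "0202"))
  mt_u <- fake_intervals(c("0102", "0202", "0302"), source = "MT")
  p3 <- pair_streams(vo_u, mt_u)
  expect_equal(sum(p3$coded), 2)
  expect_equal(matching_proportion(p3), 50)

  # mismatched metadata refuse to pair
  other <- fake_intervals(rep("0102", 3), subject_id = "S999", source = "MT")
  expect_error(pair_streams(vo, other), class = "tt_validation_error")
})

test_that("combined-code durations split evenly and conserve total time", {
  expect_equal(split_combined_durations(c("1602" = 4)),
               c("0102" = 2, "0602" = 2))
  expect_equal(split_combined_durations(setNames(numeric(0), character(0))),
               setNames(numeric(0), character(0)))
  out <- split_combined_durations(c("2502" = 1, "0202" = 1))
  expect_equal(out[["0202"]], 1.5)
  expect_equal(out[["0502"]], 0.5)
  expect_equal(sum(out), 2)
  expect_error(split_combined_durations(c("9902" = 1)), class = "tt_validation_error")
  # conservation on random mixtures
  withr::with_seed(61, {
    for (rep in 1:20) {
      d <- runif(6)
      names(d) <- sample(enumerate_areas(TRUE), 6)
      expect_equal(sum(split_combined_durations(d)), sum(d))
    }
  })
})
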