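test_that("matching proportion counts identical coded pairs", {
  p <- fake_paired(rep("0102", 10), c(rep("0102", 9), "0202"))
  expect_equal(matching_proportion(p), 90)
  expect_equal(matching_proportion(fake_paired(rep("0102", 5), rep("0102", 5))), 100)
  expect_equal(matching_proportion(fake_paired(rep("0102", 5), rep("0203", 5))), 0)
  all_uncoded <- fake_paired(rep(uncoded_label(), 3), rep("0102", 3))
  expect_error(matching_proportion(all_uncoded), class = "tt_validation_error")
})

test_that("confusion matrix tallies pairs, pools additively, matches trace identity", {
  vo <- c("0102", "0102", "0202", "0202", "0103", "1602")
  mt <- c("0102", "0202", "0202", "0202", "0101", "1602")
  p <- fake_paired(vo, mt)
  cm <- confusion_matrix(p)
  expect_equal(sum(cm), 6)
  expect_equal(cm["0102", "0102"], 1L)
  expect_equal(cm["0102", "0202"], 1L)
  expect_equal(cm["0202", "0202"], 2L)
  expect_equal(cm["0103", "0101"], 1L)
  expect_equal(cm["1602", "1602"], 1L)
  # pooling two sessions is entrywise addition
  cm2 <- confusion_matrix(list(p, p))
  expect_equal(unclass(cm2), unclass(cm) * 2L, ignore_attr = TRUE)
  # matching proportion equals 100 * trace / total
  expect_equal(matching_proportion(p),
               100 * sum(diag(cm)) / sum(cm))
})

test_that("adjacency classes follow the boundary-confusion rule and are symmetric", {
  expect_equal(adjacency_class("0102", "0102"), "match")
  expect_equal(adjacency_class("0102", "0202"), "adjacent")      # neighbour sextant
  expect_equal(adjacency_class("0102", "0103"), "non_adjacent")  # vestibular vs oral
  expect_equal(adjacency_class("0101", "0102"), "adjacent")      # occlusal vs smooth
  expect_equal(adjacency_class("0102", "0602"), "adjacent")      # opposing closed-jaw pair
  expect_equal(adjacency_class("0102", "0302"), "non_adjacent")  # across the arch
  expect_equal(adjacency_class("0102", "0402"), "non_adjacent")  # opposite mouth side
  expect_equal(adjacency_class("1602", "0102"), "adjacent")      # combined vs member
  expect_equal(adjacency_class("1602", "0202"), "non_adjacent")
  expect_equal(adjacency_class("1602", "2502"), "non_adjacent")
  # symmetry on random pairs
  withr::with_seed(71, {
    a <- sample(enumerate_areas(TRUE), 80, replace = TRUE)
    b <- sample(enumerate_areas(TRUE), 80, replace = TRUE)
    expect_equal(adjacency_class(a, b), adjacency_class(b, a))
  })
})

test_that("heat-map table drops the diagonal and zero cells and normalises intensity", {
  p <- fake_paired(rep("0102", 10), rep("0102", 10))
  expect_equal(nrow(heatmap_table(confusion_matrix(p))), 0)

  vo <- c(rep("0102", 5), rep("0102", 3))
  mt <- c(rep("0103", 5), rep("0102", 3))
  ht <- heatmap_table(confusion_matrix(fake_paired(vo, mt)))
  expect_equal(nrow(ht), 1)
  expect_equal(ht$count, 5L)
  expect_equal(ht$class, "non_adjacent")
  expect_equal(ht$intensity, 1)  # the largest cell has maximal intensity

  vo2 <- c(vo, "0202", "0202")
  mt2 <- c(mt, "0302", "0302")
  ht2 <- heatmap_table(confusion_matrix(fake_paired(vo2, mt2)))
  expect_equal(max(ht2$intensity), 1)
  expect_equal(ht2$intensity[ht2$count == 2], 2 / 5)
})

test_that("Cohen's kappa matches hand fixtures and the direct oracle", {
  # identical non-constant sequences
  expect_equal(cohen_kappa(c("0102", "0202"), c("0102", "0202")), 1)
  # hand fixture: po = 0.75, pe = 0.5 -> kappa = 0.5
  a <- c("0102", "0102", "0202", "0202")
  b <- c("0102", "0202", "0202", "0202")
  expect_equal(cohen_kappa(a, b), 0.5)
  # projections: sextant-only and surface-only agreement
  expect_equal(cohen_kappa(c("0102", "0203"), c("0103", "0202"), "sextant"), 1)
  expect_equal(cohen_kappa(c("0102", "0303"), c("0202", "0403"), "surface"), 1)
  # constant identical sequences: defined as 1 with warning
  expect_warning(k <- cohen_kappa(rep("0102", 4), rep("0102", 4)), "constant")
  expect_equal(k, 1)
  # uncoded pairs are excluded
  expect_equal(cohen_kappa(c("0102", uncoded_label(), "0202"),
                           c("0102", "0302", "0202")), 1)
  # random sequences agree with the direct po/pe oracle
  withr::with_seed(81, {
    for (rep in 1:20) {
      x <- sample(enumerate_areas()[1:4], 60, replace = TRUE)
      y <- sample(enumerate_areas()[1:4], 60, replace = TRUE)
      expect_equal(cohen_kappa(x, y), oracle_kappa(x, y), tolerance = 1e-12)
      expect_lte(cohen_kappa(x, y), 1)
    }
  })
})

test_that("independent label shuffles give chance-level kappa", {
  withr::with_seed(91, {
    ks <- replicate(1000, {
      x <- sample(rep(enumerate_areas()[1:4], 25))
      y <- sample(rep(enumerate_areas()[1:4], 25))
      cohen_kappa(x, y)
    })
    expect_lt(abs(mean(ks)), 0.02)
    expect_lt(abs(median(ks)), 0.05)
  })
})

test_that("matching distribution summarises median (min; max) and inclusive threshold fractions", {
  d <- matching_distribution(100)
  expect_equal(d$summary$median_pct, 100)
  expect_equal(d$summary$fraction_ge_80, 100)
  expect_equal(d$summary$fraction_ge_90, 100)

  d2 <- matching_distribution(c(75, 85, 95))
  expect_equal(d2$summary$median_pct, 85)
  expect_equal(d2$summary$min_pct, 75)
  expect_equal(d2$summary$max_pct, 95)
  expect_equal(d2$summary$fraction_ge_80, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(d2$summary$fraction_ge_90, 100 * 1 / 3, tolerance = 1e-9)

  # thresholds are inclusive
  d3 <- matching_distribution(c(80, 90))
  expect_equal(d3$summary$fraction_ge_80, 100)
  expect_equal(d3$summary$fraction_ge_90, 50)

  # histogram uses 2.5-point bins and accounts for every session
  expect_equal(sum(d2$histogram$count), 3)
  expect_equal(unique(round(d2$histogram$bin_high - d2$histogram$bin_low, 6)), 2.5)
  expect_error(matching_distribution(c(50, 105)), class = "tt_validation_error")
})
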