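test_that("irf_ratio divides sugar by acid and flags the near-zero-acid regime", {
  expect_equal(as.numeric(irf_ratio(0, 1.0)), 0)
  expect_equal(as.numeric(irf_ratio(2.0, 1.0)), 2.0)
  unstable <- irf_ratio(1.78, 0.001)
  expect_equal(as.numeric(unstable), 1780)
  expect_false(irf_unstable(unstable))
  degenerate <- irf_ratio(1.78, 1e-9)
  expect_true(irf_unstable(degenerate))
  expect_equal(as.numeric(degenerate), 1.78 / 1e-6)
  expect_error(irf_ratio(-1, 1), "non-negative")
  expect_error(irf_ratio(1, -1), "non-negative")
})

test_that("scale-score categories reproduce the applied boundary behaviour", {
  # boundary cases as applied in the published score table
  expect_equal(as.character(categorize_scale_score(10.049)), "sweet")     # AO1
  expect_equal(as.character(categorize_scale_score(1.000)), "dry")        # WW3
  expect_equal(as.character(categorize_scale_score(2.195)), "semi-dry")   # BD2
  expect_equal(as.character(categorize_scale_score(4.000)), "semi-sweet") # WW4
  expect_equal(as.character(categorize_scale_score(4.069)), "sweet")      # MD1
  expect_equal(as.character(categorize_scale_score(0)), "dry")
  expect_error(categorize_scale_score(-0.1), "non-negative")
})

test_that("scale and sensory categorizers are non-decreasing in the score", {
  set.seed(11)
  s <- sort(c(runif(200, 0, 12), 1, 2.2, 4))
  expect_true(all(diff(dryness_level(categorize_scale_score(s))) >= 0))
  s8 <- sort(c(runif(200, 0, 8), 2, 4, 6))
  expect_true(all(diff(dryness_level(categorize_sensory_score(s8))) >= 0))
})

test_that("pH correction shifts categories per the guideline matrix", {
  expect_equal(as.character(irf_ph_adjust("dry", 3.6)), "semi-sweet")
  expect_equal(as.character(irf_ph_adjust("dry", 3.3)), "semi-dry")
  expect_equal(as.character(irf_ph_adjust("sweet", 2.8)), "semi-dry")
  expect_equal(as.character(irf_ph_adjust("sweet", 2.9)), "semi-sweet")
  expect_equal(as.character(irf_ph_adjust("semi-dry", 3.1)), "semi-dry")
  expect_equal(as.character(irf_ph_adjust("semi-dry", 2.9)), "dry")
  expect_equal(as.character(irf_ph_adjust("semi-sweet", 3.4)), "sweet")
  # overlapping low-pH thresholds: the more extreme shift wins
  expect_equal(as.character(irf_ph_adjust("semi-sweet", 2.7)), "dry")
  expect_equal(as.character(irf_ph_adjust("semi-sweet", 2.85)), "semi-dry")
  expect_error(irf_ph_adjust("dry", 0), "between 0 and 14")
})

test_that("tannin deduction follows the half-open brackets and is monotone", {
  expect_equal(tannin_deduction(c(0, 500, 600, 750, 800, 1000, 1001, 5000)),
               c(0, 0, 0.25, 0.25, 0.5, 0.5, 0.75, 0.75))
  set.seed(4)
  tt <- sort(runif(100, 0, 2000))
  expect_true(all(diff(tannin_deduction(tt)) >= 0))
  expect_error(tannin_deduction(-5), "non-negative")
})

test_that("NYCA score subtracts the deduction, floors at zero, and is monotone", {
  expect_equal(nyca_score(4.069, 5000), 3.319)
  expect_equal(nyca_score(2.587, 1500), 1.837)
  expect_equal(nyca_score(0.3, 0), 0.3)
  expect_equal(nyca_score(0.2, 5000), 0)   # floored
  set.seed(5)
  irf <- runif(50, 0, 6)
  expect_true(all(nyca_score(irf, 900) <= nyca_score(irf, 100)))
  expect_true(all(diff(nyca_score(sort(irf), 600)) >= 0))
  # NYCA rating never exceeds the IRF rating, ordinal dominance
  expect_true(all(dryness_level(categorize_scale_score(nyca_score(irf, 1200))) <=
                  dryness_level(categorize_scale_score(irf))))
})

test_that("sensory scores map to categories on the anchored 0-8 bands", {
  expect_equal(as.character(categorize_sensory_score(2.0)), "dry")     # SH3
  expect_equal(as.character(categorize_sensory_score(3.6)), "semi-dry") # MD1
  expect_equal(as.character(categorize_sensory_score(6.3)), "sweet")   # KS8
  expect_equal(as.character(categorize_sensory_score(c(4.0, 4.1, 6.0))),
               c("semi-dry", "semi-sweet", "semi-sweet"))
  expect_error(categorize_sensory_score(8.5), "\\[0, 8\\]")
  expect_error(categorize_sensory_score(-0.1), "\\[0, 8\\]")
})

test_that("anchor interpolation passes through the glucose reference standards", {
  expect_equal(anchor_score(c(0, 9, 18, 45)), c(0, 2, 4, 6))
  expect_equal(anchor_score(13.5), 3)      # midpoint of the 9-18 segment
  g <- seq(0, 45, by = 0.5)
  expect_true(all(diff(anchor_score(g)) > 0))      # strictly increasing
  expect_equal(anchor_score(1000), 8)              # capped at scale top
  expect_error(anchor_score(-1), "non-negative")
})

test_that("score_samples converts units and applies all scales at once", {
  chem <- data.frame(sample_id = c("a", "b"),
                     residual_sugar = c(200, 50),  # mg/100 mL
                     malic_acid = c(0.5, 1.0), ph = c(3.6, 3.0),
                     tannins = c(1200, 0))
  sc <- score_samples(chem)
  expect_equal(sc$irf_score, c(4.0, 0.5))
  expect_equal(sc$nyca_score, c(3.25, 0.5))
  expect_equal(as.character(sc$irf_rating), c("semi-sweet", "dry"))
  expect_equal(as.character(sc$irf_rating_ph), c("sweet", "dry"))
  expect_error(score_samples(chem[, -3]), "malic_acid")
})
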