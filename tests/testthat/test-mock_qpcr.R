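test_that("standard curve on an exact dilution series is exact", {
  # Cq = -3.3219 * log10(copies) + 38, 6 logs, 3 replicates
  copies <- rep(10^(3:8), each = 3)
  std <- data.frame(copies = copies, cq = -3.3219 * log10(copies) + 38)
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-12)
  expect_equal(curve$intercept, 38, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$dynamic_range_logs, 5)
})

test_that("efficiency follows the 10^(-1/slope) convention", {
  mk <- function(slope) {
    copies <- 10^(3:8)
    fit_standard_curve(data.frame(copies = copies,
                                  cq = slope * log10(copies) + 40))
  }
  expect_equal(mk(-3.3219)$efficiency_pct, 100, tolerance = 1e-4)
  # slope -3.5 -> 10^(1/3.5) - 1 = 0.9306977...
  expect_equal(mk(-3.5)$efficiency_pct, (10^(1 / 3.5) - 1) * 100,
               tolerance = 1e-12)
})

test_that("replicates are averaged on the Cq scale before conversion", {
  copies <- 10^(3:8)
  curve <- fit_standard_curve(
    data.frame(copies = copies, cq = -3.3219 * log10(copies) + 38))
  # mean Cq of (20, 22) is 21, NOT the mean of the two copy estimates
  q <- quantify_absolute(curve, c(20, 22))
  expect_equal(q$mean_cq, 21)
  expect_equal(q$copies, 10^((21 - 38) / -3.3219))
  naive <- mean(10^((c(20, 22) - 38) / -3.3219))
  expect_false(isTRUE(all.equal(q$copies, naive)))
})

test_that("a 10-cycle Cq difference is ~1024x in copies at 100% efficiency", {
  copies <- 10^(2:8)
  curve <- fit_standard_curve(
    data.frame(copies = copies, cq = -3.3219 * log10(copies) + 38))
  hi <- quantify_absolute(curve, 15)$copies
  lo <- quantify_absolute(curve, 25)$copies
  expect_equal(hi / lo, 2^10, tolerance = 1e-3)
})

test_that("NA replicates are dropped; all-NA is censored at zero", {
  copies <- 10^(3:8)
  curve <- fit_standard_curve(
    data.frame(copies = copies, cq = -3.3219 * log10(copies) + 38))
  q <- quantify_absolute(curve, c(20, NA, 20))
  expect_equal(q$mean_cq, 20)
  expect_false(q$censored)
  q0 <- quantify_absolute(curve, c(NA, NA))
  expect_true(q0$censored)
  expect_equal(q0$copies, 0)
})

test_that("extrapolation beyond the calibrated Cq range is flagged", {
  copies <- 10^(4:8)
  curve <- fit_standard_curve(
    data.frame(copies = copies, cq = -3.3219 * log10(copies) + 38))
  inside <- quantify_absolute(curve, mean(curve$cq_range))
  outside <- quantify_absolute(curve, max(curve$cq_range) + 2)
  expect_false(inside$extrapolated)
  expect_true(outside$extrapolated)
})

test_that("noiseless fixture round-trips true copies per virus", {
  fx <- fixture_qpcr()
  got <- quantify_samples(fx$standards, fx$samples)
  truth <- c(vacc = 2e6, lambda = 5e5, m13 = 8e4)
  expect_equal(setNames(got$copies, got$virus)[names(truth)], truth,
               tolerance = 1e-9)
})

test_that("community composition sums to 100% within each sample", {
  m <- data.frame(virus = rep(c("a", "b", "c"), 2),
                  sample = rep(c("s1", "s2"), each = 3),
                  copies = c(1e6, 1e6, 2e6, 5e5, 0, 5e5))
  comp <- community_composition(m)
  sums <- tapply(comp$relative_proportion_pct, comp$sample, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  expect_equal(comp$relative_proportion_pct[comp$sample == "s1" &
                                              comp$virus == "c"], 50)
  expect_error(community_composition(
    data.frame(virus = "a", sample = "s", copies = 0)))
})

test_that("treatment fold changes handle both modes and zero baselines", {
  before <- community_composition(
    data.frame(virus = c("a", "b"), sample = "pre", copies = c(1e6, 1e6)))
  after <- community_composition(
    data.frame(virus = c("a", "b"), sample = "post", copies = c(1e4, 1e6)))
  fc_tot <- treatment_fold_changes(before, after, "total_amount")
  expect_equal(fc_tot$fold_change[fc_tot$virus == "a"], 0.01)
  fc_rel <- treatment_fold_changes(before, after, "relative_proportion")
  # a: 50% -> 100/101 %, relative fold ~ 0.0198
  expect_equal(fc_rel$fold_change[fc_rel$virus == "a"],
               (100 / 101) / 50, tolerance = 1e-12)
  before0 <- community_composition(
    data.frame(virus = c("a", "b"), sample = "pre", copies = c(0, 1e6)))
  fc0 <- treatment_fold_changes(before0, after, "total_amount")
  expect_true(is.na(fc0$fold_change[fc0$virus == "a"]))
})
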