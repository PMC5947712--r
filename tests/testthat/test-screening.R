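test_that("REF reproduces the printed acrylamide worked examples at 2 s.f.", {
  expect_equal(format_ref(compute_ref(0.233, 0.089)), 2.6)
  expect_equal(format_ref(compute_ref(0.185, 0.033)), 5.6)
  expect_equal(compute_ref(0.42, 0.42), 1)
  expect_error(compute_ref(0, 0.1), "positive")
  expect_error(compute_ref(0.1, -1), "positive")
})

test_that("REF is invariant to a common rescaling of both rate constants", {
  set.seed(21)
  for (i in 1:20) {
    a <- stats::runif(1, 1e-4, 1)
    b <- stats::runif(1, 1e-4, 1)
    c <- 10^stats::runif(1, -3, 3)
    expect_equal(compute_ref(c * a, c * b), compute_ref(a, b),
                 tolerance = 1e-12)
  }
})

toy_fits <- function(refs, k_gsh = 1, quality = "optimal") {
  n <- length(refs)
  dplyr::bind_rows(
    tibble::tibble(fragment_id = sprintf("F%02d", 1:n), target_id = "GSH",
                   k_h = k_gsh, quality = "optimal"),
    tibble::tibble(fragment_id = sprintf("F%02d", 1:n), target_id = "P1",
                   k_h = k_gsh * refs, quality = quality))
}

test_that("hit classes follow the strict REF > 3 / < 0.3 rule", {
  calls <- call_hits(toy_fits(c(5, 3, 1, 0.3, 0.2)))
  expect_equal(calls$hit_class,
               c("accelerated", "neutral", "neutral", "neutral", "retarded"))
})

test_that("failed or missing glutathione fits yield no REF values", {
  fits <- toy_fits(c(2, 2))
  fits$quality[fits$fragment_id == "F01" & fits$target_id == "GSH"] <- "failed"
  calls <- call_hits(fits)
  expect_equal(calls$fragment_id, "F02")
  expect_error(call_hits(dplyr::filter(fits, target_id != "GSH")),
               "glutathione")
})

test_that("call_hits is a pure function of matrix and policy", {
  fits <- toy_fits(c(0.1, 9, 1, 4, 0.25))
  a <- call_hits(fits)
  b <- call_hits(fits[sample(nrow(fits)), ])
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("average reactivity is geometric, per axis, excluding GSH rows", {
  fits <- tibble::tibble(
    fragment_id = c("F1", "F1", "F1", "F2", "F2", "F2"),
    target_id = rep(c("GSH", "P1", "P2"), 2),
    k_h = c(0.5, 0.1, 0.001, 0.2, 0.04, 0.04),
    quality = "optimal")
  av <- average_reactivity(fits, "per_fragment")
  expect_equal(av$k_geomean_h[av$fragment_id == "F1"], 0.01) # not 0.0505
  expect_equal(av$k_geomean_h[av$fragment_id == "F2"], 0.04)
  expect_true(all(av$n_cells == 2))
  # log of the geometric mean equals the mean of the logs
  by_target <- average_reactivity(fits, "per_target")
  k_p1 <- fits$k_h[fits$target_id == "P1"]
  expect_equal(log(by_target$k_geomean_h[by_target$target_id == "P1"]),
               mean(log(k_p1)), tolerance = 1e-12)
  expect_true("GSH" %in% by_target$target_id)
})

test_that("derived thresholds bound the estimated FDR on a Gaussian null", {
  set.seed(99)
  refs <- 10^stats::rnorm(5000, 0, 0.2434)
  pol <- derive_thresholds(refs, target_fdr = 0.025)
  expect_equal(pol$mode, "derived")
  # a pure null forces the cutoff beyond the ~2-sigma point of the spread
  expect_gte(pol$upper, 10^(1.96 * 0.2434))
  # symmetric in log space around the median
  m <- stats::median(log10(refs))
  expect_equal(log10(pol$upper) - m, m - log10(pol$lower), tolerance = 1e-9)
})

test_that("a zero-spread REF sample collapses the cutoffs to just above 1", {
  pol <- derive_thresholds(rep(1, 100))
  expect_gt(pol$upper, 1)
  expect_lt(pol$upper, 1.0001)
  expect_equal(sum(rep(1, 100) > pol$upper), 0)
  expect_error(derive_thresholds(rep(1, 10)), "at least 30")
})

test_that("derived thresholds control empirical FDR on a planted screen", {
  res <- run_fdr_screen(123)
  pol <- derive_thresholds(res$calls$ref, target_fdr = 0.025)
  expect_lte(pol$upper, 3)
  m <- dplyr::inner_join(res$calls,
                         dplyr::filter(res$truth, target_id != "GSH"),
                         by = c("fragment_id", "target_id"))
  called <- m$ref > pol$upper
  emp_fdr <- sum(called & m$label != "accelerated") / max(1, sum(called))
  expect_lte(emp_fdr, 0.025)
})

test_that("correlation handles exact proportionality and anticorrelation", {
  fits <- tibble::tibble(
    fragment_id = rep(sprintf("F%d", 1:4), each = 2),
    target_id = rep(c("GSH", "P1"), 4),
    k_h = as.vector(rbind(c(0.01, 0.05, 0.2, 1), 2.5 * c(0.01, 0.05, 0.2, 1))),
    quality = "optimal")
  r <- correlate_reactivity(fits)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, log10(2.5), tolerance = 1e-12)

  anti <- tibble::tibble(
    fragment_id = rep(c("F1", "F2", "F3"), each = 2),
    target_id = rep(c("GSH", "P1"), 3),
    k_h = c(1, 4, 2, 2, 4, 1), quality = "optimal")
  expect_equal(correlate_reactivity(anti)$pearson_r, -1, tolerance = 1e-12)
  expect_error(correlate_reactivity(anti[1:4, ]), ">= 3 fragments")
})

test_that("threshold policies validate their ordering", {
  expect_error(ref_policy(upper = 0.5), "lower < 1 < upper")
  expect_error(ref_policy(lower = 1.5), "lower < 1 < upper")
  expect_error(ref_policy(target_fdr = 0), "target_fdr")
})
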