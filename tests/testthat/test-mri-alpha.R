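test_that("T2* estimation inverts the decay between the opposed echoes", {
  # generated with T2* = 20 ms; the estimator must recover it
  tr40 <- simulate_roi_signals(0.40, no_t1_params(t2star = 20))
  expect_equal(estimate_t2star(tr40), 20, tolerance = 1e-9)

  # ln ratio of e gives T2* = te3 - te1
  tr_e <- echo_triple(op1 = exp(1) * 5, ip = 10, op2 = 5)
  expect_equal(estimate_t2star(tr_e), 4.76, tolerance = 1e-12)

  # equal opposed echoes: no measurable decay, sentinel Inf (factor 1)
  expect_identical(estimate_t2star(echo_triple(5, 10, 5)), Inf)
  expect_identical(estimate_t2star(echo_triple(4, 10, 5)), Inf)
  expect_error(estimate_t2star(echo_triple(0, 10, 0)), "strictly positive")
})

test_that("alpha limits: water-only gives 0, equal water and fat gives 0.5", {
  expect_equal(compute_alpha(echo_triple(10, 10, 9), Inf), 0)
  expect_equal(compute_alpha(echo_triple(0, 10, 0), Inf), 0.5)
  tr40 <- simulate_roi_signals(0.40, no_t1_params(t2star = 20))
  expect_equal(compute_alpha(tr40, estimate_t2star(tr40)), 0.40,
               tolerance = 1e-9)
  expect_error(compute_alpha(echo_triple(1, 0, 1), Inf), "in-phase")
})

test_that("estimator round-trips the signal model exactly and is T2*-invariant", {
  for (f in c(0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.45)) {
    alphas <- vapply(c(5, 10, 20, 30, 40), function(t2) {
      tr <- simulate_roi_signals(f, no_t1_params(t2star = t2))
      compute_alpha(tr, estimate_t2star(tr))
    }, numeric(1))
    expect_true(all(abs(alphas - f) < 1e-6))
    expect_lt(diff(range(alphas)), 1e-9)  # independent of simulated T2*
  }
})

test_that("alpha is clamped to [0, 1] for noise-driven negative raw values", {
  # op1 so large that the raw expression goes negative
  expect_identical(compute_alpha(echo_triple(30, 10, 25), Inf), 0)
  set.seed(5)
  for (i in 1:50) {
    tr <- echo_triple(runif(1, 0, 50), runif(1, 1e-3, 50), runif(1, 0, 50))
    t2 <- tryCatch(estimate_t2star(tr), error = function(e) Inf)
    a <- compute_alpha(tr, t2)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("slice averaging is the arithmetic mean of per-slice alphas", {
  mk <- function(f) simulate_roi_signals(f, no_t1_params(t2star = 20))
  res <- alpha_from_slices(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_equal(res$alpha, mean(res$alpha_per_slice))
  expect_equal(res$alpha_per_slice, c(0.1, 0.2, 0.3), tolerance = 1e-6)
  expect_true(all(res$correction_applied))

  expect_warning(one <- alpha_from_slices(list(mk(0.2))), "fewer than 3")
  expect_equal(one$alpha, 0.2, tolerance = 1e-6)
  expect_error(alpha_from_slices(list()), "no slices")
})

test_that("ROI mean matches counting oracles", {
  img <- matrix(7, 101, 101)
  expect_equal(roi_mean(img, c(51, 51), area_mm2 = 580, pixel_spacing = 1), 7)

  # half-plane a|b with the ROI centred on the boundary
  a <- 2; b <- 10
  img2 <- cbind(matrix(a, 101, 50), matrix(b, 101, 51))
  r_px <- roi_radius_mm(580)  # spacing 1 mm
  got <- roi_mean(img2, c(51, 50.5), area_mm2 = 580, pixel_spacing = 1)
  expect_lt(abs(got - (a + b) / 2),
            (b - a) * (2 * r_px + 1) / (pi * r_px^2))

  expect_equal(roi_radius_mm(580), sqrt(580 / pi))
  expect_error(roi_mean(img, c(5, 5), 580, 1), "outside the image")
})
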