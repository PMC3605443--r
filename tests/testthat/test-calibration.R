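test_that("alpha_model closed forms and fixed points", {
  expect_equal(alpha_model(0, 5), 0)
  expect_equal(alpha_model(1, 5), 1)
  expect_equal(alpha_model(0.3, 1), 0.3)          # identity at k = 1
  expect_equal(alpha_model(0.25, 2), 0.5 / 1.25)  # 0.4
  expect_equal(invert_alpha(0.4, 2), 0.25)
  expect_equal(invert_alpha(0, 3), 0)
  expect_equal(invert_alpha(1, 3), 1)
})

test_that("model and inverse are mutually inverse bijections", {
  set.seed(42)
  f <- runif(100); k <- runif(100, 0.05, 20)
  for (i in 1:100) {
    expect_equal(invert_alpha(alpha_model(f[i], k[i]), k[i]), f[i],
                 tolerance = 1e-12)
  }
  # monotone increasing, concave above the identity for k > 1
  g <- seq(0, 1, by = 0.01)
  a <- alpha_model(g, 2.6)
  expect_true(all(diff(a) > 0))
  expect_true(all(a[2:100] >= g[2:100]))
  # initial slope equals k (the low-fat contrast gain)
  eps <- 1e-8
  expect_equal(alpha_model(eps, 2.6) / eps, 2.6, tolerance = 1e-6)
})

test_that("fit_k recovers the generating constant", {
  f <- seq(0.01, 0.4, length.out = 25)
  fit <- fit_k(alpha_model(f, 3), f)
  expect_equal(fit$k, 3, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n, 25)
})

test_that("fit_k matches a brute-force grid refit on noisy data", {
  set.seed(77)
  f <- runif(59, 0.01, 0.35)
  a <- pmin(pmax(alpha_model(f, 3) + rnorm(59, 0, 0.03), 0), 1)
  fit <- fit_k(a, f)
  grid <- seq(2, 4, by = 1e-4)
  sse <- vapply(grid, function(k) sum((a - alpha_model(f, k))^2), numeric(1))
  expect_equal(fit$k, grid[which.min(sse)], tolerance = 1e-3)
  expect_equal(fit$r_squared,
               1 - min(sse) / sum((a - mean(a))^2), tolerance = 1e-6)
})

test_that("degenerate calibration inputs are refused or flagged", {
  expect_error(fit_k(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_k(rep(0.1, 5), rep(0, 5)), "unidentifiable")
  expect_warning(fit_k(c(0.5, 0.52, 0.48), rep(0.5, 3)), "no leverage")
})

test_that("morphometric cutoffs come from the OLS regression line", {
  # identity link: 0.01 fraction per percent
  vis <- c(0, 10, 20, 40, 80)
  link <- fit_morph_vis_link(0.01 * vis, vis)
  expect_equal(unname(derive_morph_cutoffs(link, c(5, 33, 66))),
               c(0.05, 0.33, 0.66), tolerance = 1e-12)

  # hand-computed normal equations on noisy data
  set.seed(9)
  vis2 <- runif(59, 0, 98)
  morph2 <- 0.009 + 0.001 * vis2 + rnorm(59, 0, 0.005)
  link2 <- fit_morph_vis_link(morph2, vis2)
  X <- cbind(1, vis2)
  beta <- solve(t(X) %*% X, t(X) %*% morph2)
  expect_equal(link2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(link2$slope, beta[2], tolerance = 1e-10)

  # through-origin variant drops the intercept
  link0 <- fit_morph_vis_link(morph2, vis2, through_origin = TRUE)
  expect_identical(link0$intercept, 0)
})
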