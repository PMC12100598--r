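test_that("weighted R-squared matches hand-computed values", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  fit <- c(1.1, 1.9, 3.2, 3.8)
  w <- c(1, 2, 1, 2)
  mu <- weighted.mean(obs, w)
  byhand <- 1 - sum(w * (obs - fit)^2) / sum(w * (obs - mu)^2)
  expect_equal(r_squared(obs, fit, w), byhand)
  expect_warning(r_squared(c(2, 2), c(2, 2)), "zero total variance")
})

test_that("two-state fit recovers exact and noisy mixtures", {
  A <- fx_curve_dimer()
  B <- fx_curve_tubule()
  # endpoint: the basis itself
  fam1 <- curve_family(tq, rbind(A$I, B$I))
  fit1 <- two_state_fit(fam1, A, B)
  expect_equal(fit1$fractions$f_A, c(1, 0))
  expect_equal(fit1$fractions$r_squared, c(1, 1))
  # noiseless mixture: machine-precision recovery
  fam2 <- curve_family(tq, rbind(0.3 * A$I + 0.7 * B$I))
  fit2 <- two_state_fit(fam2, A, B)
  expect_equal(fit2$fractions$f_A, 0.3, tolerance = 1e-12)
  # unconstrained mode agrees on exact mixtures
  fit2u <- two_state_fit(fam2, A, B, closure = FALSE)
  expect_equal(fit2u$fractions$f_A, 0.3, tolerance = 1e-9)
  expect_equal(fit2u$fractions$f_B, 0.7, tolerance = 1e-9)
  # collinear bases rejected
  expect_error(two_state_fit(fam2, A, A), "collinear")
})

test_that("closure and non-negativity keep fractions on the simplex", {
  A <- fx_curve_dimer()
  B <- fx_curve_tubule()
  set.seed(31)
  f <- runif(20, -0.2, 1.2)  # includes out-of-range generating values
  I <- outer(1 - f, A$I) + outer(f, B$I)
  I <- I * (1 + matrix(rnorm(length(I), 0, 0.05), nrow(I)))
  fit <- two_state_fit(curve_family(tq, I), A, B)
  expect_true(all(fit$fractions$f_A >= 0 & fit$fractions$f_A <= 1))
  expect_equal(fit$fractions$f_A + fit$fractions$f_B, rep(1, 20))
})

test_that("SVD rank identifies the number of mixing components", {
  A <- fx_curve_dimer()
  B <- fx_curve_tubule()
  set.seed(32)
  f <- runif(12)
  fam <- curve_family(tq, outer(1 - f, A$I) + outer(f, B$I))
  res <- svd_rank(fam)
  expect_equal(res$effective_rank, 2)
  expect_lt(res$singular_values[3] / res$singular_values[1], 1e-10)
  # single repeated curve: rank 1
  res1 <- svd_rank(curve_family(tq, rbind(A$I, A$I, A$I)))
  expect_equal(res1$effective_rank, 1)
  expect_error(svd_rank(curve_family(tq, rbind(A$I))), "at least 2")
  # invariance to curve order and global intensity rescaling
  perm <- sample(12)
  expect_equal(svd_rank(curve_family(tq, fam$I[perm, ]))$effective_rank, 2)
  expect_equal(svd_rank(curve_family(tq, 1e3 * fam$I))$effective_rank, 2)
  # a transient third component raises the rank
  C <- assembly_intensity(build_microtubule(13, 11.2, 40), fx_dimer(), tq,
                          exact_limit = 2000)
  f3 <- 0.3 * exp(-((seq_len(12) - 6) / 3)^2)
  I3 <- outer(pmax(0, 1 - f - f3), A$I) + outer(f, B$I) + outer(f3, C$I)
  expect_equal(svd_rank(curve_family(tq, I3))$effective_rank, 3)
})

test_that("isosbestic points coincide with basis-curve crossings", {
  A <- fx_curve_dimer()
  B <- fx_curve_tubule()
  # normalize so the two basis curves cross inside the q window
  An <- saxs_curve(tq, A$I / A$I[1])
  Bn <- saxs_curve(tq, B$I / B$I[1])
  f <- seq(0.05, 0.95, length.out = 8)
  fam <- curve_family(tq, outer(1 - f, An$I) + outer(f, Bn$I))
  found <- find_isosbestic(fam, tolerance = 0.01)
  crossings <- tq[which(diff(sign(An$I - Bn$I)) != 0)]
  expect_gt(length(found), 0)
  for (qx in found) {
    expect_lt(min(abs(qx - crossings)) / qx, 0.05)
  }
  # three-component family with no common crossing: empty
  C <- assembly_intensity(build_microtubule(13, 11.2, 40), fx_dimer(), tq,
                          exact_limit = 2000)
  Cn <- saxs_curve(tq, C$I / C$I[1])
  f3 <- seq(0.1, 0.4, length.out = 8)
  I3 <- outer(pmax(0, 1 - f - f3), An$I) + outer(f, Bn$I) + outer(f3, Cn$I)
  expect_length(find_isosbestic(curve_family(tq, I3), tolerance = 1e-4), 0)
  # identical curves: degenerate, every q flagged
  expect_equal(find_isosbestic(curve_family(tq, rbind(An$I, An$I, An$I))), tq)
})

test_that("background subtraction recovers a constructed signal", {
  set.seed(33)
  sig <- saxs_curve(tq, exp(-tq), sigma = rep(0.01, length(tq)))
  bg <- saxs_curve(tq, 0.3 / (1 + tq^2), sigma = rep(0.01, length(tq)))
  sample <- saxs_curve(tq, sig$I + bg$I, sigma = rep(0.01, length(tq)))
  out <- subtract_background(sample, bg)
  expect_equal(out$I, sig$I, tolerance = 1e-12)
  expect_equal(out$sigma, rep(sqrt(2) * 0.01, length(tq)))
  # scale 0 leaves the sample untouched; full scale of itself zeroes it
  expect_equal(subtract_background(sample, bg, scale = 0)$I, sample$I)
  expect_equal(max(abs(subtract_background(sample, sample)$I)), 0)
  # interpolation path: background on a finer grid
  bg2 <- saxs_curve(default_q_grid(0.04, 3.1, 300), 0.3 / (1 + default_q_grid(0.04, 3.1, 300)^2))
  out2 <- subtract_background(sample, bg2)
  expect_equal(out2$I, sig$I, tolerance = 1e-3)
  # disjoint ranges rejected
  bad <- saxs_curve(tq + 10, bg$I)
  expect_error(subtract_background(sample, bad), "range")
})
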