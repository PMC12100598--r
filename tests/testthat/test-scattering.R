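test_that("sphere form factor amplitude has the known special values", {
  expect_equal(sphere_form_factor(0, 3), 1)
  # first zero of the amplitude at qR = 4.4934 (root of tan x = x)
  x0 <- uniroot(function(x) sin(x) - x * cos(x), c(4, 5), tol = 1e-12)$root
  expect_lt(abs(sphere_form_factor(x0 / 3, 3)), 1e-4)
  expect_equal(sphere_form_factor(pi / 2, 2), 3 / pi^2)
  # continuous through the small-argument series switch
  expect_equal(sphere_form_factor(1e-4 / 3, 3), sphere_form_factor(1.01e-4 / 3, 3),
               tolerance = 1e-8)
})

test_that("Debye intensity matches closed forms for one and two beads", {
  b1 <- bead_model(data.frame(x = 0, y = 0, z = 0, radius = 0.3,
                              contrast = 5))
  q <- tq
  cv <- debye_intensity(b1, q)
  expect_equal(cv$I, 25 * sphere_form_factor(q, 0.3)^2)
  # two identical point-like beads at distance d: I/f^2 = 2 (1 + sinc(qd))
  d <- 4.7
  b2 <- bead_model(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, d),
                              radius = 0.01, contrast = c(3, 3)))
  cv2 <- debye_intensity(b2, q)
  f2 <- 9 * sphere_form_factor(q, 0.01)^2
  expect_equal(cv2$I / f2, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-10)
})

test_that("Debye sum is positive, normalized at q -> 0, and symmetric", {
  m <- fx_dimer()
  cv <- debye_intensity(m, c(1e-8, tq))
  expect_true(all(cv$I >= 0))
  expect_equal(cv$I[1], total_excess_electrons(m)^2, tolerance = 1e-10)
  # permutation invariance
  perm <- sample(nrow(m$beads))
  m2 <- m
  m2$beads <- m$beads[perm, ]
  expect_equal(debye_intensity(m2, tq)$I, cv$I[-1], tolerance = 1e-12)
  # rigid translation + rotation leave I unchanged
  m3 <- m
  R <- tait_bryan_matrix(33, -51, 77)
  pos <- t(R %*% t(as.matrix(m$beads[, c("x", "y", "z")]))) +
    matrix(rep(c(5, -2, 11), each = nrow(m$beads)), ncol = 3)
  m3$beads[, c("x", "y", "z")] <- pos
  expect_equal(debye_intensity(m3, tq)$I, cv$I[-1], tolerance = 1e-8)
})

test_that("histogram accelerator agrees with the exact pair sum", {
  m <- coarse_grain_sphere(3, 0.45)
  exact <- debye_intensity(m, tq, exact_limit = 1e6)
  binned <- debye_intensity(m, tq, exact_limit = 0, bin_width = 0.01)
  expect_equal(binned$I / binned$I[1], exact$I / exact$I[1], tolerance = 2e-3)
})

test_that("bead-discretized sphere converges to the analytic curve", {
  R <- 3
  q <- exp(seq(log(0.1 / R), log(8 / R), length.out = 100))
  runmax <- function(v, w = 5) {
    vapply(seq_along(v),
           function(i) max(v[max(1, i - w):min(length(v), i + w)]),
           numeric(1))
  }
  err <- vapply(c(0.6, 0.45, 0.3, 0.2), function(d) {
    m <- coarse_grain_sphere(R, d)
    cv <- debye_intensity(m, q, bin_width = 0.005)
    R_eff <- (3 * nrow(m$beads) * d^3 / (4 * pi))^(1 / 3)
    Ia <- sphere_form_factor(q, R_eff)^2
    max(abs(cv$I / total_excess_electrons(m)^2 - Ia) / runmax(Ia))
  }, numeric(1))
  expect_true(all(diff(err) < 0))  # monotone refinement
  expect_lt(err[length(err)], 0.01)
})

test_that("ellipsoid coarse-graining reproduces volume and centering", {
  L <- 8; T_ <- 5
  m <- coarse_grain_subunit(list(list(center = c(0, 0, 0),
                                      semi_axes = c(T_ / 2, T_ / 2, L / 2))),
                            bead_spacing = 0.35)
  vol <- 4 / 3 * pi * (T_ / 2)^2 * (L / 2)
  expect_equal(nrow(m$beads) * 0.35^3, vol, tolerance = 0.05)
  expect_equal(total_excess_electrons(m), 76 * nrow(m$beads) * 0.35^3)
  dm <- make_synthetic_dimer()
  w <- dm$beads$contrast
  expect_equal(weighted.mean(dm$beads$x, w), 0, tolerance = 1e-9)
  expect_equal(weighted.mean(dm$beads$z, w), 0, tolerance = 1e-9)
  expect_equal(total_excess_electrons(dm), 76 * 2 * 4 / 3 * pi * 2.5^2 * 2,
               tolerance = 0.02)
  # shell toggle
  expect_equal(nrow(make_synthetic_dimer(bead_spacing = 1)$beads) <
                 nrow(make_synthetic_dimer(bead_spacing = 1, shell = TRUE)$beads),
               TRUE)
  expect_error(coarse_grain_subunit(list(list(center = c(0, 0, 0),
                                              semi_axes = c(0.2, 0.2, 1))),
                                    bead_spacing = 1), "envelope")
})

test_that("mirrored synthetic dimers scatter identically", {
  dm <- make_synthetic_dimer(bead_spacing = 0.8)
  dm2 <- dm
  dm2$beads$z <- -dm2$beads$z
  expect_equal(debye_intensity(dm2, tq)$I, debye_intensity(dm, tq)$I,
               tolerance = 1e-10)
})

test_that("assembly intensity composes poses correctly", {
  dm <- fx_dimer()
  # identity pose reproduces the subunit curve
  one <- assembly(data.frame(x = 0, y = 0, z = 0, alpha = 0, beta = 0,
                             gamma = 0), kind = "single_dimer")
  expect_equal(assembly_intensity(one, dm, tq)$I, fx_curve_dimer()$I)
  # two copies: coherent zero-angle addition, I(0) = 4x single copy
  two <- assembly(data.frame(x = c(0, 500), y = 0, z = 0, alpha = 0,
                             beta = 0, gamma = 0), kind = "single_dimer")
  q0 <- 1e-9
  expect_equal(assembly_intensity(two, dm, q0)$I,
               4 * debye_intensity(dm, q0)$I, tolerance = 1e-6)
  # same beads through either code path give identical curves
  tub <- fx_tubule()
  placed <- place_beads(tub, dm$beads)
  direct <- debye_intensity(bead_model(placed), tq, exact_limit = 2000)
  expect_equal(fx_curve_tubule()$I, direct$I, tolerance = 1e-12)
})

test_that("center-of-mass reduction preserves forward scattering", {
  dm <- fx_dimer()
  tub <- fx_tubule()
  full <- assembly_intensity(tub, dm, c(1e-8, 0.05), exact_limit = 2000)
  red <- assembly_intensity(tub, dm, c(1e-8, 0.05), reduce = "com")
  expect_equal(red$I[1], full$I[1], tolerance = 1e-9)
})
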