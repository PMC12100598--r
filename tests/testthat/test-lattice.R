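test_that("law-of-cosines lattice distances match the analytic identities", {
  b <- lattice_distances(1, 90)
  expect_equal(as.numeric(b), c(sqrt(2), sqrt(2)))
  b <- lattice_distances(1, 120)
  expect_equal(as.numeric(b), c(sqrt(3), 1))
  b <- lattice_distances(2.5, 105)
  expect_equal(as.numeric(b),
               2.5 * sqrt(2 * (1 - cos(c(105, 75) * pi / 180))))
})

test_that("hexagonal bundle keeps the disc of nearest sites", {
  u <- single_dimer()
  b <- build_bundle(u, a = 10, mode = "hexagonal")
  # center + 6 neighbors; the sqrt(3) a sites are outside the disc
  expect_equal(b$spec$n_tubules, 7)
  d <- sqrt(b$derived$sites$x^2 + b$derived$sites$y^2)
  expect_true(all(d <= 10 + 1e-6))
  # brute-force enumeration oracle over larger index bounds
  for (nmax in 1:3) {
    bb <- build_bundle(u, a = 10, mode = "hexagonal",
                       n1_range = -nmax:nmax, n2_range = -nmax:nmax)
    g <- expand.grid(n1 = -nmax:nmax, n2 = -nmax:nmax)
    v <- cbind(g$n1 * 10 + g$n2 * 10 * cos(2 * pi / 3),
               g$n2 * 10 * sin(2 * pi / 3))
    expect_equal(bb$spec$n_tubules,
                 sum(sqrt(rowSums(v^2)) <= 10 * nmax + 1e-8))
  }
})

test_that("single-site replication returns the unit unchanged", {
  u <- build_inverted_helical_tubule(12, 12, 30, 8)
  b <- build_bundle(u, a = 30, mode = "hexagonal", n1_range = 0, n2_range = 0)
  expect_equal(b$poses, u$poses, ignore_attr = TRUE)
  bo <- build_bundle(build_conical_spiral_tubule(6, 4, 3, 3, V_h = 4,
                                                 L_dim = 3, T_dim = 2),
                     a = 14, mode = "oblique_antiparallel",
                     n1_range = 0, n2_range = 0)
  expect_equal(nrow(bo$poses),
               nrow(build_conical_spiral_tubule(6, 4, 3, 3, V_h = 4,
                                                L_dim = 3, T_dim = 2)$poses))
})

test_that("oblique 3x3 bundle surrounds the center with 4 antiparallel + 2 parallel", {
  unit <- build_conical_spiral_tubule(6, 4, 3, 3, V_h = 4, L_dim = 3,
                                      T_dim = 2)
  b <- build_bundle(unit, a = 14, mode = "oblique_antiparallel",
                    n1_range = 0:2, n2_range = 0:2)
  s <- b$derived$sites
  expect_equal(nrow(s), 9)
  center <- s[s$n1 == 1 & s$n2 == 1, ]
  expect_false(center$antiparallel)
  d <- sqrt((s$x - center$x)^2 + (s$y - center$y)^2)
  near <- s[d > 0 & d < 14 * 1.25, ]  # distance a and b2 = 1.22 a
  expect_equal(sum(near$antiparallel), 4)
  expect_equal(sum(!near$antiparallel), 2)
  # antiparallel neighbors sit at distance a, parallel at b2
  expect_equal(sort(round(d[d > 0 & d < 14 * 1.25], 6)),
               round(c(rep(14, 4),
                       rep(lattice_distances(14, 105)[["b2"]], 2)), 6),
               ignore_attr = TRUE)
})

test_that("antiparallel copies are flipped and gamma-corrected", {
  unit <- build_conical_spiral_tubule(6, 4, 3, 3, V_h = 4, L_dim = 3,
                                      T_dim = 2)
  b <- build_bundle(unit, a = 14, mode = "oblique_antiparallel",
                    n1_range = 0:1, n2_range = 0:0)
  s <- b$derived$sites
  n1 <- nrow(unit$poses)
  flip_rows <- which(rep(s$antiparallel, each = n1))
  # the flipped copy's first-dimer orientation equals
  # Ax(180) Az(gamma_n) A(unit pose)
  gm <- atan2(s$y[2], s$x[2]) * 180 / pi
  A_expect <- tait_bryan_matrix(180, 0, gm) %*%
    tait_bryan_matrix(unit$poses$alpha[1], unit$poses$beta[1],
                      unit$poses$gamma[1])
  i <- flip_rows[1]
  A_got <- tait_bryan_matrix(b$poses$alpha[i], b$poses$beta[i],
                             b$poses$gamma[i])
  expect_equal(A_got, A_expect, tolerance = 1e-9)
  # flipped copy is upside down: z extent mirrored around its site
  expect_equal(b$poses$z[i], -unit$poses$z[1], tolerance = 1e-9)
})

test_that("non-penetration bounds are enforced", {
  hexunit <- build_inverted_helical_tubule(12, 12, 30, 8, T_dim = 5)
  expect_error(build_bundle(hexunit, a = 20, mode = "hexagonal"),
               "non-penetration")
  cone <- build_conical_spiral_tubule(6, 4, 3, 3, V_h = 4, L_dim = 3,
                                      T_dim = 2)
  expect_error(build_bundle(cone, a = 10, mode = "oblique_antiparallel"),
               "non-penetration")
})

test_that("microtubule lattice has equally spaced protofilaments", {
  mt <- build_microtubule(N_p = 13, r = 11.2, h = 0)
  expect_equal(nrow(mt$poses), 13)
  expect_equal(mt$poses$beta, (0:12) * 360 / 13)
  # chord between adjacent protofilaments
  d <- sqrt(diff(mt$poses$x)^2 + diff(mt$poses$y)^2)
  expect_equal(d, rep(2 * 11.2 * sin(pi / 13), 12))
  # smallest case: two antipodal protofilaments
  mt2 <- build_microtubule(N_p = 2, r = 5, h = 0)
  expect_equal(mt2$poses$x, c(5, -5))
  expect_equal(mt2$poses$y, c(0, 0), tolerance = 1e-12)
  expect_error(build_microtubule(N_p = 1), "at least 2")
  # stacking along z with the axial rise
  mt3 <- build_microtubule(N_p = 13, r = 11.2, h = 24, axial_rise = 8)
  expect_equal(nrow(mt3$poses), 13 * 4)
  expect_equal(sort(unique(mt3$poses$z)), c(-12, -4, 4, 12))
})
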