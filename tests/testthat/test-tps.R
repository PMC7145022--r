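test_that("kernel vector is the plain Euclidean distance", {
  set.seed(1)
  ctr <- random_config(5)
  expect_equal(tps_kernel_vector(ctr[3, ], ctr)[3], 0)
  expect_equal(tps_kernel_vector(c(1, 0, 0), matrix(0, 1, 3)), 1)
  ## brute-force per-pair loop oracle
  for (rep in 1:20) {
    q <- stats::rnorm(3); ctr <- random_config(8)
    brute <- vapply(1:8, function(i) sqrt(sum((q - ctr[i, ])^2)), 0)
    expect_equal(tps_kernel_vector(q, ctr), brute, tolerance = 1e-12)
  }
})

test_that("kernel matrix is symmetric with zero diagonal", {
  set.seed(2)
  m <- fit_tps(random_config(9), random_config(9))
  expect_equal(m$kernel, t(m$kernel))
  expect_equal(diag(m$kernel), rep(0, 9), ignore_attr = TRUE)
})

test_that("identity and affine maps are exactly affine with zero energy", {
  set.seed(3)
  src <- random_config(10)
  ident <- fit_tps(src, src)
  expect_equal(ident$affine, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(ident$nonaffine)), 1e-10)
  expect_lt(bending_energy(ident), 1e-10)

  shifted <- fit_tps(src, 2 * src + rep(c(1, 2, 3), each = nrow(src)))
  expect_lt(sqrt(sum(shifted$nonaffine^2)), 1e-9)
  expect_lt(bending_energy(shifted), 1e-10)
  expect_equal(shifted$affine[1:3, 1:3], diag(3) * 2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(shifted$affine[4, 1:3], c(1, 2, 3), tolerance = 1e-7,
               ignore_attr = TRUE)

  ## general affine A x + b, including rotation and shear
  A <- rbind(c(1.2, 0.3, 0), c(-0.1, 0.9, 0.2), c(0, 0.1, 1.1))
  aff <- fit_tps(src, src %*% A + rep(c(-4, 0, 7), each = nrow(src)))
  expect_lt(bending_energy(aff), 1e-10)
  expect_lt(sqrt(sum(aff$nonaffine^2)), 1e-8)
})

test_that("interpolation is exact at beta = 0 on random configurations", {
  set.seed(4)
  for (rep in 1:25) {
    M <- sample(6:20, 1)
    src <- random_config(M, scale = 30)
    dst <- src + random_config(M, scale = 3)
    m <- fit_tps(src, dst)
    scale <- sqrt(sum(scale(src, scale = FALSE)^2))
    expect_lt(max(rowSums((warp_points(m, src) - dst)^2)), (1e-8 * scale)^2)
    ## bordered-system orthogonality: homogeneous source columns
    ## annihilate the non-affine coefficients
    expect_lt(max(abs(crossprod(cbind(src, 1), m$nonaffine))), 1e-7)
  }
})

test_that("solution matches an independent dense solve of the bordered system", {
  set.seed(5)
  src <- random_config(10)
  dst <- src
  dst[4, ] <- dst[4, ] + c(1.5, -0.5, 0.2)  # one perturbed destination
  m <- fit_tps(src, dst)
  ## independent oracle: generic solve of the full (M+4) system built here
  Psi <- as.matrix(dist(src))
  L <- rbind(cbind(Psi, cbind(src, 1)),
             cbind(t(cbind(src, 1)), matrix(0, 4, 4)))
  sol <- solve(L, rbind(cbind(dst, 1), matrix(0, 4, 4)))
  expect_equal(m$nonaffine, sol[1:10, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m$affine, sol[11:14, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(warp_points(m, src) - dst)), 1e-8)
})

test_that("warping behaves like the fitted map on new points", {
  set.seed(6)
  src <- random_config(8)
  shift <- rep(c(3, -2, 5), each = 8)
  m <- fit_tps(src, src + shift)
  cloud <- random_config(50)
  expect_equal(warp_points(m, cloud), cloud + rep(c(3, -2, 5), each = 50),
               tolerance = 1e-8)
  ## symmetric two-point stretch: the midpoint stays the midpoint
  srcs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  dsts <- srcs; dsts[1, 1] <- -2; dsts[2, 1] <- 2
  ms <- fit_tps(srcs, dsts)
  expect_equal(as.numeric(warp_points(ms, c(0, 0, 0))), c(0, 0, 0),
               tolerance = 1e-8)
})

test_that("bending energy is invariant to adding an affine component", {
  set.seed(7)
  src <- random_config(12)
  dst <- src + random_config(12, scale = 1)
  e1 <- bending_energy(fit_tps(src, dst))
  ## adding an affine function of the source to the destinations lands in
  ## the spline's null space and must not change the energy
  A <- rbind(c(1.1, 0.2, 0), c(0, 0.95, -0.1), c(0.05, 0, 1.2))
  e2 <- bending_energy(fit_tps(src, dst + src %*% A + rep(c(5, 5, 5),
                                                          each = 12)))
  expect_gt(e1, 0)
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("bending energy is positive for a bump and monotone in beta", {
  set.seed(8)
  src <- random_config(9)
  dst <- src; dst[2, ] <- dst[2, ] + c(0, 0, 2)
  expect_gt(bending_energy(fit_tps(src, dst)), 0)
  es <- vapply(c(0, 0.05, 0.5, 5, 50), function(b)
    bending_energy(fit_tps(src, dst, beta = b)), 0)
  expect_true(all(diff(es) <= 1e-10))
})

test_that("degenerate control configurations are rejected", {
  set.seed(9)
  src <- random_config(8)
  dup <- src; dup[5, ] <- dup[2, ]
  expect_error(fit_tps(dup, src), "duplicate")
  expect_error(fit_tps(src[1:4, ], src[1:4, ]), "M >= 5")
  flat <- cbind(random_config(8)[, 1:2], 0)
  expect_error(fit_tps(flat, flat), "coplanar")
  expect_error(fit_tps(src, src, beta = -1), "beta")
})
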