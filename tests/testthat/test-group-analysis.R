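## shape space with a controlled allometric component: shapes are
## mean + cs * direction + noise
allometric_space <- function(N = 30, K = 12, slope = 0.02, noise = 0.001,
                             seed = 40) {
  set.seed(seed)
  base <- random_config(K, 10)
  cs <- runif(N, 80, 120)
  dir <- random_config(K, 1); dir <- dir / sqrt(sum(dir^2))
  arr <- array(NA, c(N, K, 3))
  for (i in seq_len(N))
    arr[i, , ] <- (base + cs[i] * slope * dir +
                     noise * random_config(K, 1)) * (cs[i] / 100)
  gpa(arr)
}

test_that("allometry regression: constructed signal is found", {
  sp <- allometric_space()
  r <- regress_shape_on_size(sp, n_perm = 199, seed = 1)
  expect_gt(r$percent_predicted, 95)
  expect_equal(r$p_value, 1 / 200)
  ## residual shapes are uncorrelated with size
  cors <- suppressWarnings(cor(r$residuals, r$sizes))
  expect_lt(max(abs(cors), na.rm = TRUE), 1e-6)
  ## predicted + residual = total
  Y <- tangent_coordinates(sp)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(sum(r$fitted^2) + sum(r$residuals^2), sum(Yc^2),
               tolerance = 1e-9)
})

test_that("allometry regression guards degenerate input", {
  sp <- allometric_space(N = 10)
  sp$centroid_sizes[] <- 100
  expect_error(regress_shape_on_size(sp, n_perm = 10), "constant")
})

test_that("pooled within-group correction removes shared allometry", {
  set.seed(41)
  N <- 40; K <- 10
  grp <- rep(c("a", "b"), each = N / 2)
  cs <- runif(N, 80, 120)
  base <- random_config(K, 10)
  dirm <- random_config(K, 1); dirm <- dirm / sqrt(sum(dirm^2))
  offs <- random_config(K, 1); offs <- offs / sqrt(sum(offs^2))
  arr <- array(NA, c(N, K, 3))
  for (i in seq_len(N))
    arr[i, , ] <- (base + cs[i] * 0.01 * dirm +
                     (grp[i] == "b") * 0.5 * offs +
                     0.01 * random_config(K, 1)) * (cs[i] / 100)
  spc <- gpa(arr)
  corr <- pooled_within_group_size_correction(spc, grp)
  ## the POOLED within-group covariance of corrected shapes with size is
  ## zero (that is what the common slope removes)
  pooled <- 0
  Yp <- corr$corrected; xp <- spc$centroid_sizes
  num <- matrix(0, 1, ncol(Yp)); den <- 0
  for (g in c("a", "b")) {
    sel <- grp == g
    Yg <- sweep(Yp[sel, ], 2, colMeans(Yp[sel, ]))
    xg <- xp[sel] - mean(xp[sel])
    num <- num + crossprod(xg, Yg)
    den <- den + sum(xg^2)
  }
  expect_lt(max(abs(num / den)), 1e-10)
  ## recovered slope points along the injected allometric direction
  inj <- as.numeric(dirm)
  cosine <- sum(corr$slope[seq_along(inj)] * inj) /
    sqrt(sum(corr$slope^2) * sum(inj^2))
  expect_gt(abs(cosine), 0.7)
  ## group mean differences survive the correction
  expect_gt(sqrt(sum((colMeans(corr$corrected[grp == "a", ]) -
                        colMeans(corr$corrected[grp == "b", ]))^2)),
            0.005)
  ## correcting a no-allometry sample changes almost nothing
  arr0 <- array(NA, c(N, K, 3))
  for (i in seq_len(N))
    arr0[i, , ] <- base + 0.01 * random_config(K, 1)
  sp0 <- gpa(arr0)
  sp0$centroid_sizes <- stats::setNames(cs, sp0$ids)
  corr0 <- pooled_within_group_size_correction(sp0, grp)
  Y0 <- tangent_coordinates(sp0)
  expect_lt(mean((corr0$corrected - Y0)^2), mean(Y0^2) * 0.05)
  ## single-member groups are excluded with a warning
  expect_warning(pooled_within_group_size_correction(
    spc, c("solo", grp[-1])), "size 1")
})

test_that("size-corrected shapes kill a follow-up allometry regression", {
  sp <- allometric_space(N = 36, seed = 42)
  grp <- rep(c("a", "b"), 18)
  corr <- pooled_within_group_size_correction(sp, grp)
  fake <- list(tangent = corr$corrected, sizes = sp$centroid_sizes)
  r <- regress_shape_on_size(fake, n_perm = 99, seed = 2)
  expect_lt(r$percent_predicted, 1)
})

test_that("MANOVA flags distinct slopes and respects Wilks bounds", {
  set.seed(43)
  N <- 60; q <- 4
  grp <- rep(c("a", "b"), each = N / 2)
  cs <- runif(N, 80, 120)
  slopes <- ifelse(grp == "a", 0.03, -0.03)
  S <- outer(cs * slopes, c(1, 0.5, 0, 0)) + matrix(rnorm(N * q, sd = 0.5),
                                                    N, q)
  m <- manova_allometry(S, grp, cs)
  expect_lt(m$p[m$effect == "slopes (group x CS)"], 0.001)
  expect_true(all(m$wilks >= 0 & m$wilks <= 1))
  expect_true(all(m$df_num > 0 & m$df_den > 0))
  ## dimensionality guard
  expect_error(manova_allometry(matrix(rnorm(20 * 18), 20, 18), grp[1:20],
                                cs[1:20], q = 18), "dimensionality")
})

test_that("CVA produces at most g-1 optimally separating axes", {
  set.seed(44)
  N <- 60; q <- 5
  grp <- rep(c("a", "b"), each = N / 2)
  X <- matrix(rnorm(N * q), N, q)
  X[grp == "b", 1:2] <- X[grp == "b", 1:2] + 3
  cv <- cva(X, grp)
  expect_equal(ncol(cv$scores), 1L)          # two groups: one axis
  ratio <- function(v) {
    bet <- (mean(v[grp == "a"]) - mean(v[grp == "b"]))^2
    wit <- stats::var(v[grp == "a"]) + stats::var(v[grp == "b"])
    bet / wit
  }
  r_cv1 <- ratio(cv$scores[, 1])
  for (j in seq_len(q)) expect_gte(r_cv1, ratio(X[, j]) - 1e-9)
  ## permuting labels destroys the separation
  set.seed(45)
  cvp <- cva(X, sample(grp))
  expect_lt(ratio(cvp$scores[, 1]) / r_cv1, 0.3)
  ## three groups: two axes
  grp3 <- rep(c("a", "b", "c"), each = 20)
  expect_equal(ncol(cva(X, grp3)$scores), 2L)
  ## unit pooled within-group variance scaling on each axis
  wv <- (sum(tapply(cv$scores[, 1], grp, function(v)
    sum((v - mean(v))^2)))) / (N - 2)
  expect_equal(wv, 1, tolerance = 1e-8)
})

test_that("CVA falls back to PCA preprocessing on singular scatter", {
  set.seed(46)
  X <- matrix(rnorm(20 * 3), 20, 3)
  X <- cbind(X, X[, 1] + X[, 2])            # exactly collinear column
  expect_message(cv <- cva(X, rep(c("a", "b"), each = 10)),
                 "singular within-group scatter")
  expect_equal(ncol(cv$scores), 1L)
})

test_that("LOO discriminant classification separates and stays honest", {
  set.seed(47)
  N <- 80; q <- 5
  grp <- rep(c("a", "b"), each = N / 2)
  ## mean separation 6x the within-group SD
  X <- matrix(rnorm(N * q), N, q)
  X[grp == "b", ] <- X[grp == "b", ] + 6 / sqrt(q)
  r <- discriminant_classify(X, grp)
  expect_gte(r$accuracy, 99)
  expect_equal(rowSums(r$confusion), c(a = 100, b = 100), tolerance = 0.01)
  expect_lt(r$wilks, 0.2)
  expect_lt(r$wilks_p, 1e-6)
  ## random labels: accuracy within binomial noise of chance
  set.seed(48)
  accs <- replicate(10, {
    discriminant_classify(matrix(rnorm(N * q), N, q), sample(grp))$accuracy
  })
  expect_lt(abs(mean(accs) - 50), 3 * 100 * sqrt(0.25 / N) / sqrt(10) + 5)
  expect_error(discriminant_classify(X, c("a", rep("b", N - 1))),
               "single member")
})

test_that("Rao's Wilks-to-F conversion matches manova for two groups", {
  set.seed(49)
  N <- 40; q <- 3
  grp <- factor(rep(c("a", "b"), each = N / 2))
  X <- matrix(rnorm(N * q), N, q)
  sm <- summary(stats::manova(X ~ grp), test = "Wilks")$stats
  mine <- craniomorph:::rao_wilks_f(sm[1, "Wilks"], p = q, q = 1,
                                    ve = N - 2)
  expect_equal(mine$F, sm[1, "approx F"], tolerance = 1e-8)
  expect_equal(mine$p, sm[1, "Pr(>F)"], tolerance = 1e-8)
})
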