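make_shape_space <- function(N = 12, K = 10, sd = 1, seed = 30) {
  set.seed(seed)
  base <- random_config(K)
  arr <- array(NA, c(N, K, 3))
  for (i in seq_len(N)) arr[i, , ] <- base + sd * random_config(K, 0.3)
  gpa(arr)
}

test_that("PCA conserves variance and reconstructs the data", {
  sp <- make_shape_space()
  Y <- tangent_coordinates(sp)
  p <- shape_pca(sp)
  expect_equal(sum(p$eigenvalues),
               sum(sweep(Y, 2, colMeans(Y))^2) / (nrow(Y) - 1),
               tolerance = 1e-9)
  ## reconstruction through loadings + mean
  recon <- p$scores %*% t(p$components) + rep(p$center, each = nrow(Y))
  expect_lt(max(abs(recon - Y)), 1e-8)
  ## loadings orthonormal
  G <- crossprod(p$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  ## descending variance fractions summing to <= 100
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  expect_lte(sum(p$variance_fractions), 100 + 1e-9)
  expect_lte(p$retained_count, min(nrow(Y) - 1, 3 * attr(Y, "K") - 7))
  ## sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(p$components)))
    expect_gt(p$components[which.max(abs(p$components[, j])), j], 0)
})

test_that("PCA eigenvalues are invariant to a joint rigid rotation", {
  sp <- make_shape_space(seed = 31)
  R <- rotation_matrix(0.7, -0.3, 0.2)
  arr2 <- sp$aligned
  for (i in seq_len(dim(arr2)[1])) arr2[i, , ] <- arr2[i, , ] %*% R
  p1 <- shape_pca(sp)
  p2 <- shape_pca(gpa(arr2))
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-8)
})

test_that("a dominant injected axis captures its share of variance", {
  set.seed(32)
  N <- 60; p <- 30
  axis <- rnorm(p); axis <- axis / sqrt(sum(axis^2))
  Y <- outer(rnorm(N, sd = 10), axis) + matrix(rnorm(N * p), N, p)
  pc <- shape_pca(Y)
  ## injected variance ratio 100 : 1 per residual dimension
  expect_gt(pc$variance_fractions[1], 70)
  expect_equal(pc$variance_fractions[1],
               100 * 100 / (100 + p), tolerance = 0.25 * 100)
})

test_that("parallel analysis keeps signal and drops noise", {
  set.seed(33)
  noise <- matrix(rnorm(40 * 30), 40, 30)
  expect_lte(parallel_analysis_retention(noise, seed = 1), 2)
  sig <- outer(rnorm(40, sd = 3), runif(30)) +
    0.1 * matrix(rnorm(40 * 30), 40, 30)
  expect_equal(parallel_analysis_retention(sig, seed = 1), 1L)
  ## retention never exceeds the rank bound
  wide <- matrix(rnorm(8 * 50), 8, 50)
  expect_lte(parallel_analysis_retention(wide, seed = 1), 7)
  expect_warning(parallel_analysis_retention(noise, n_random = 5,
                                             seed = 1), "n_random")
})

test_that("Procrustes ANOVA has the published main-effect df and full var%", {
  spec <- small_pop_spec()
  lp <- landmark_population(spec, template = mid_template())
  tab <- procrustes_anova(lp$configs, lp$meta, partition = "anchors",
                          anchor_count = 20)
  expect_equal(tab$DF[tab$effect == "ethnicity"], 53)
  expect_equal(tab$DF[tab$effect == "sex"], 53)
  expect_equal(tab$DF[tab$effect == "age_class"], 212)
  expect_equal(sum(tab$var_pct[tab$effect != "Total"]), 100,
               tolerance = 0.01)
  ## SS additivity
  expect_equal(sum(tab$SS[tab$effect != "Total"]),
               tab$SS[tab$effect == "Total"], tolerance = 1e-9)
  ## semi-landmark partition df scale with the landmark count
  tab2 <- procrustes_anova(lp$configs, lp$meta, partition = "semilandmarks",
                           anchor_count = 20)
  K <- dim(lp$configs)[2] - 20
  expect_equal(tab2$DF[tab2$effect == "ethnicity"], 3 * K - 7)
})

test_that("Procrustes ANOVA F is near 1 under a null design", {
  ## zero group effects, one digitization per individual (balanced): each
  ## factor\'s F over the individual stratum has mean about 1
  set.seed(34)
  nrep <- 150
  fstats <- matrix(NA_real_, nrep, 2)
  K <- 10; n_ind <- 16
  for (r in seq_len(nrep)) {
    base <- random_config(K)
    meta <- data.frame(id = sprintf("i%02d", seq_len(n_ind)),
                       ethnicity = rep(c("a", "b"), length.out = n_ind),
                       sex = rep(c("m", "m", "f", "f"),
                                 length.out = n_ind),
                       replicate_of = NA_character_)
    arr <- array(NA, c(n_ind, K, 3))
    for (i in seq_len(n_ind)) arr[i, , ] <- base +
        0.5 * random_config(K, 1)
    tab <- suppressWarnings(procrustes_anova(arr, meta,
                                             partition = "all",
                                             anchor_count = K,
                                             factors = c("ethnicity",
                                                         "sex")))
    fstats[r, ] <- tab$F[1:2]
  }
  expect_equal(mean(fstats[, 1]), 1, tolerance = 0.15)
  expect_equal(mean(fstats[, 2]), 1, tolerance = 0.15)
})

test_that("Procrustes ANOVA recovers injected variance structure", {
  ## between-group : individual : digitization variance in known ratio
  set.seed(35)
  nrep <- 30
  got <- matrix(NA_real_, nrep, 3)
  K <- 10; n_per <- 10
  for (r in seq_len(nrep)) {
    base <- random_config(K)
    offs <- random_config(K, 1); offs <- offs / sqrt(mean(offs^2))
    ids <- sprintf("i%02d", seq_len(2 * n_per))
    grp <- rep(c("a", "b"), each = n_per)
    ind <- lapply(seq_len(2 * n_per), function(i)
      base + (grp[i] == "b") * 0.8 * offs + 0.8 * random_config(K, 1))
    arr <- array(NA, c(2 * n_per + 6, K, 3))
    for (i in seq_len(2 * n_per)) arr[i, , ] <- ind[[i]] +
        0.08 * random_config(K, 1)
    for (i in 1:6) arr[2 * n_per + i, , ] <- ind[[i]] +
        0.08 * random_config(K, 1)
    meta <- data.frame(id = c(ids, paste0(ids[1:6], "r")),
                       ethnicity = c(grp, grp[1:6]),
                       replicate_of = c(rep(NA, 2 * n_per), ids[1:6]))
    tab <- procrustes_anova(arr, meta, partition = "all",
                            anchor_count = K, factors = "ethnicity")
    got[r, ] <- tab$var_pct[1:3]
  }
  avg <- colMeans(got)
  ## strata ordered group < individual dominant, error small, and the
  ## averaged percentages stable across replicates
  expect_gt(avg[2], avg[1])
  expect_gt(avg[1], avg[3])
  expect_lt(avg[3], 10)
  expect_equal(sum(avg), 100, tolerance = 1e-6)
})

test_that("Procrustes ANOVA guards its design assumptions", {
  spec <- small_pop_spec()
  lp <- landmark_population(spec)
  meta <- lp$meta
  meta$ethnicity <- "one_level"
  expect_error(procrustes_anova(lp$configs, meta, partition = "anchors"),
               "fewer than 2 levels")
  ## no replicates: error stratum omitted with a warning
  firsts <- is.na(lp$meta$replicate_of)
  expect_warning(
    tab <- procrustes_anova(lp$configs[firsts, , ], lp$meta[firsts, ],
                            partition = "anchors"),
    "no replicate")
  expect_false("digitizing_error" %in% tab$effect)
})

test_that("EDMA distances, logs and label handling", {
  two <- landmark_configuration(rbind(c(0, 0, 0), c(100, 0, 0)), 2,
                                labels = c("me", "op"))
  r <- edma_log_distances(two, "me-op")
  expect_equal(r$distance_mm, 100)
  expect_equal(r$log10_distance, 2)
  ## 'all' on 20 anchors gives 190 pairs
  b <- base_head()
  r20 <- edma_log_distances(b$anchors, "all")
  expect_equal(nrow(r20), 190L)
  expect_true(all(r20$distance_mm > 0))
  ## the 12 named anthropometric distances all resolve
  r12 <- edma_log_distances(b$anchors, TABLE_DISTANCE_PAIRS)
  expect_equal(nrow(r12), 12L)
  expect_true(all(is.finite(r12$log10_distance)))
  ## log10 monotone in distance
  expect_equal(order(r12$distance_mm), order(r12$log10_distance))
  expect_error(edma_log_distances(b$anchors, "me-xx"), "valid notations")
})

test_that("group mean distances scale with the group's configurations", {
  set.seed(36)
  K <- 10
  base <- random_config(K, 20)
  arr <- array(NA, c(8, K, 3))
  for (i in 1:8) arr[i, , ] <- base * (if (i <= 4) 1 else 2) +
    0.05 * random_config(K, 1)
  sp <- gpa(arr)
  labs <- rep(c("s", "l"), each = 4)
  means <- group_mean_shapes_mm(sp, labs)
  rownames(means$s) <- rownames(means$l) <- sprintf("p%02d", 1:K)
  d_s <- edma_log_distances(means$s, "p01-p02")$distance_mm
  d_l <- edma_log_distances(means$l, "p01-p02")$distance_mm
  expect_equal(d_l / d_s, 2, tolerance = 0.02)
})
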