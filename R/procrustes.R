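#' Centroid size of a landmark configuration
#'
#' Root of the summed squared distances of all points from their centroid
#' — the standard geometric-morphometric size measure (mm).
#'
#' @param config K x 3 coordinate matrix (or `landmark_config`).
#' @return positive scalar (mm).
#' @export
centroid_size <- function(config) {
  x <- if (inherits(config, "landmark_config")) config$points else
    as.matrix(config)
  if (nrow(x) < 2) stop("centroid_size: need at least 2 points")
  cs <- sqrt(sum(scale(x, scale = FALSE)^2))
  if (cs == 0) stop("centroid_size: all points coincide (zero size)")
  cs
}

## Optimal rotation (no reflection) aligning centered config b onto a:
## returns the 3x3 rotation R with det +1 minimizing ||a - b R||.
optimal_rotation <- function(a, b) {
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Translates every configuration to the origin, scales to unit centroid
#' size, and iteratively rotates all specimens to the running consensus
#' (orthogonal Procrustes by singular decomposition, rotations only — no
#' reflections, so anatomical left/right cannot flip) until the consensus
#' stabilizes.
#'
#' @param configs N x K x 3 array, or a list of K x 3 matrices /
#'   `landmark_config` objects.
#' @param ids optional specimen identifiers (defaults to array dimnames or
#'   sequence).
#' @param max_iter,tol iteration controls (defaults 1000 and 1e-11 on the
#'   consensus change).
#' @return an object of class `shape_space`: `aligned` (N x K x 3 unit-size
#'   configurations), `mean_shape` (K x 3 consensus, unit size),
#'   `centroid_sizes` (mm, pre-scaling), `ids`, `iterations`.
#' @export
gpa <- function(configs, ids = NULL, max_iter = 1000, tol = 1e-11) {
  arr <- as_config_array(configs)
  N <- dim(arr)[1]; K <- dim(arr)[2]
  if (N < 2) stop("gpa: need at least 2 configurations")
  if (K < 3) stop("gpa: need at least 3 landmarks")
  if (is.null(ids)) ids <- dimnames(arr)[[1]] %||% as.character(seq_len(N))
  sizes <- numeric(N)
  for (i in seq_len(N)) {
    x <- arr[i, , ]
    if (!all(is.finite(x))) stop("gpa: non-finite coordinates in specimen ", ids[i])
    x <- scale(x, scale = FALSE)
    sizes[i] <- sqrt(sum(x^2))
    if (sizes[i] <= 0)
      stop("gpa: degenerate configuration (zero centroid size): specimen ",
           ids[i])
    arr[i, , ] <- x / sizes[i]
  }
  ## start from the raw mean so GPA is an exact fixed point on aligned
  ## input; fall back to the first specimen when rotations scatter the
  ## mean toward zero
  consensus <- apply(arr, c(2, 3), mean)
  if (sqrt(sum(consensus^2)) < 0.1) consensus <- arr[1, , ]
  consensus <- scale(consensus, scale = FALSE)
  consensus <- consensus / sqrt(sum(consensus^2))
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(N)) {
      R <- optimal_rotation(consensus, arr[i, , ])
      arr[i, , ] <- arr[i, , ] %*% R
    }
    new_cons <- apply(arr, c(2, 3), mean)
    new_cons <- scale(new_cons, scale = FALSE)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol || it >= max_iter) break
  }
  ## final pass so every specimen is optimally rotated to the converged mean
  for (i in seq_len(N)) {
    R <- optimal_rotation(consensus, arr[i, , ])
    arr[i, , ] <- arr[i, , ] %*% R
  }
  mean_shape <- apply(arr, c(2, 3), mean)
  dimnames(arr) <- list(ids, dimnames(arr)[[2]], c("x", "y", "z"))
  structure(list(aligned = arr, mean_shape = mean_shape,
                 centroid_sizes = stats::setNames(sizes, ids), ids = ids,
                 iterations = it),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("<shape_space> ", dim(x$aligned)[1], " specimens x ",
      dim(x$aligned)[2], " landmarks (GPA, ", x$iterations,
      " iterations)\n", sep = "")
  invisible(x)
}

## Coerce list / array input to an N x K x 3 array.
as_config_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3) {
    stopifnot(dim(configs)[3] == 3)
    return(configs)
  }
  if (is.list(configs)) {
    mats <- lapply(configs, function(c)
      if (inherits(c, "landmark_config")) c$points else as.matrix(c))
    K <- nrow(mats[[1]])
    if (!all(vapply(mats, nrow, 0L) == K))
      stop("as_config_array: configurations differ in landmark count")
    arr <- array(NA_real_, c(length(mats), K, 3),
                 dimnames = list(names(mats), rownames(mats[[1]]), NULL))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    return(arr)
  }
  stop("as_config_array: expected an N x K x 3 array or list of K x 3 matrices")
}

#' Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size, and
#' optimally rotated onto each other (rotations only); the distance is the
#' square root of the summed squared coordinate differences.
#'
#' @param a,b K x 3 configurations with the same K.
#' @return non-negative scalar; 0 iff the shapes are identical.
#' @export
procrustes_distance <- function(a, b) {
  a <- if (inherits(a, "landmark_config")) a$points else as.matrix(a)
  b <- if (inherits(b, "landmark_config")) b$points else as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("procrustes_distance: landmark counts differ (", nrow(a), " vs ",
         nrow(b), ")")
  a <- scale(a, scale = FALSE); a <- a / sqrt(sum(a^2))
  b <- scale(b, scale = FALSE); b <- b / sqrt(sum(b^2))
  R <- optimal_rotation(a, b)
  sqrt(sum((a - b %*% R)^2))
}

#' Tangent-space coordinates of an aligned sample
#'
#' Orthogonal projection of the aligned (unit-size) configurations into
#' the linear tangent space at the consensus: the vectorized deviation
#' from the mean, with its component along the mean direction removed.
#' All linear statistics downstream (PCA, regression, MANOVA) operate on
#' these coordinates.
#'
#' @param shape_space a [gpa()] result.
#' @return N x 3K matrix with attributes `mean_vec` (the consensus as a
#'   3K vector) and `K`.
#' @export
tangent_coordinates <- function(shape_space) {
  arr <- shape_space$aligned
  N <- dim(arr)[1]; K <- dim(arr)[2]
  V <- t(vapply(seq_len(N), function(i) as.numeric(arr[i, , ]),
                numeric(3 * K)))
  m <- as.numeric(shape_space$mean_shape)
  mhat <- m / sqrt(sum(m^2))
  Vc <- sweep(V, 2, m)
  Vt <- Vc - (Vc %*% mhat) %*% t(mhat)
  rownames(Vt) <- shape_space$ids
  attr(Vt, "mean_vec") <- m
  attr(Vt, "K") <- K
  Vt
}

#' Permutation test on the Procrustes distance between two group means
#'
#' The observed statistic is the Procrustes distance between the two
#' group mean shapes (computed on the aligned coordinates, with a fresh
#' optimal rotation between the means). Group labels are permuted within
#' the pooled two-group sample; the p-value uses the add-one convention
#' (count of permuted distances >= observed, plus one, over n_perm + 1),
#' so it is never exactly zero.
#'
#' @param shape_space a [gpa()] result.
#' @param labels factor of group labels, one per specimen.
#' @param groups length-2 character vector naming the two groups to
#'   compare (default: the two levels present).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @return list with `observed`, `p_value`, `n_perm`.
#' @export
permutation_test_group_distance <- function(shape_space, labels,
                                            groups = NULL, n_perm = 10000,
                                            seed = NULL) {
  if (n_perm < 1) stop("permutation_test_group_distance: n_perm must be >= 1")
  labels <- as.character(labels)
  if (is.null(groups)) {
    groups <- unique(labels)
    if (length(groups) != 2)
      stop("permutation_test_group_distance: specify `groups` when more ",
           "than two labels are present")
  }
  sel <- labels %in% groups
  arr <- shape_space$aligned[sel, , , drop = FALSE]
  lab <- labels[sel]
  n1 <- sum(lab == groups[1]); n2 <- sum(lab == groups[2])
  if (n1 == 0 || n2 == 0)
    stop("permutation_test_group_distance: empty group")
  if (n1 < 2 || n2 < 2)
    warning("permutation_test_group_distance: a group has < 2 members")
  group_dist <- function(which1) {
    m1 <- apply(arr[which1, , , drop = FALSE], c(2, 3), mean)
    m2 <- apply(arr[!which1, , , drop = FALSE], c(2, 3), mean)
    procrustes_distance(m1, m2)
  }
  obs <- group_dist(lab == groups[1])
  count <- with_seed(seed, {
    cnt <- 0L
    n <- length(lab)
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n, n1)
      w <- logical(n); w[idx] <- TRUE
      if (group_dist(w) >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(observed = obs, p_value = (count + 1) / (n_perm + 1), n_perm = n_perm)
}
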