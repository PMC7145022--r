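#' Principal component analysis of shape (relative warps)
#'
#' Eigen-decomposition of the tangent-space covariance via singular value
#' decomposition. Component signs are fixed so the largest-magnitude
#' loading of each component is positive; scores are centered.
#'
#' @param x a [gpa()] `shape_space` or a tangent-coordinate matrix from
#'   [tangent_coordinates()].
#' @return an object of class `pca_result`: `eigenvalues` (descending),
#'   `components` (orthonormal loadings, one column per component),
#'   `scores` (N x retained), `variance_fractions` (percent),
#'   `retained_count`, `center`.
#' @export
shape_pca <- function(x) {
  Y <- if (inherits(x, "shape_space")) tangent_coordinates(x) else as.matrix(x)
  N <- nrow(Y)
  if (N < 3) stop("shape_pca: need at least 3 specimens")
  K <- attr(Y, "K") %||% (ncol(Y) / 3)
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  s <- svd(Yc)
  ev <- s$d^2 / (N - 1)
  rank_cap <- min(N - 1, 3 * K - 7, ncol(Y))
  keep <- which(ev > max(ev) * 1e-12)
  keep <- keep[seq_len(min(length(keep), rank_cap))]
  comps <- s$v[, keep, drop = FALSE]
  ## sign convention: largest-|loading| entry of each component positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  scores <- Yc %*% comps
  rownames(scores) <- rownames(Y)
  structure(list(eigenvalues = ev[keep], components = comps,
                 scores = scores,
                 variance_fractions = 100 * ev[keep] / sum(ev),
                 retained_count = length(keep), center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$retained_count, " components; PC1 ",
      sprintf("%.1f", x$variance_fractions[1]), "% of variance\n", sep = "")
  invisible(x)
}

#' Parallel-analysis retention of principal components
#'
#' Compares the observed eigenvalues against eigenvalues obtained from
#' randomized data (each coordinate column independently permuted across
#' specimens); a component is retained while its eigenvalue exceeds the
#' chosen quantile of the corresponding randomized eigenvalue.
#'
#' @param x `shape_space` or tangent-coordinate matrix.
#' @param n_random number of randomizations (default 100; fewer than 10
#'   draws a warning).
#' @param quantile quantile of the randomized eigenvalues (default 0.95).
#' @param seed RNG seed.
#' @return integer count of retained components.
#' @export
parallel_analysis_retention <- function(x, n_random = 100, quantile = 0.95,
                                        seed = NULL) {
  Y <- if (inherits(x, "shape_space")) tangent_coordinates(x) else as.matrix(x)
  if (n_random < 10)
    warning("parallel_analysis_retention: n_random < 10 gives unstable ",
            "quantiles")
  N <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  obs <- svd(Yc, nu = 0, nv = 0)$d^2 / (N - 1)
  r <- length(obs)
  rand <- with_seed(seed, {
    out <- matrix(0, n_random, r)
    for (b in seq_len(n_random)) {
      Yp <- apply(Yc, 2, sample)
      Yp <- sweep(Yp, 2, colMeans(Yp))
      d <- svd(Yp, nu = 0, nv = 0)$d^2 / (N - 1)
      out[b, ] <- d[seq_len(r)]
    }
    out
  })
  thresh <- apply(rand, 2, stats::quantile, probs = quantile, names = FALSE)
  exceeds <- obs > thresh
  retained <- if (all(exceeds)) length(exceeds) else which.min(exceeds) - 1L
  cap <- min(N - 1, ncol(Y))
  as.integer(min(retained, cap))
}

#' Hierarchical Procrustes ANOVA with digitization error
#'
#' Goodall-style decomposition of the summed squared Procrustes
#' deviations (tangent-space coordinates after a fresh superimposition of
#' the chosen landmark partition) into hierarchically ordered strata:
#' the main effects in the stated order (ethnicity, then sex, then age),
#' then individual, then digitization error (the residual between repeat
#' digitizations of the same individual).
#'
#' Degrees of freedom per main effect are (levels - 1) x the shape
#' dimension 3K - 7 (3K coordinates minus 7 similarity parameters).
#' Individual df are (n_individuals - 1 - sum(levels - 1)) x (3K - 7);
#' error df are (number of extra digitizations) x (3K - 7). F ratios
#' follow the hierarchical ladder: each main effect over the individual
#' mean square, and individual over the error mean square.
#'
#' @param configs N_obs x K x 3 array of raw landmark configurations (mm);
#'   replicate digitizations are separate rows.
#' @param meta data.frame with one row per configuration: columns `id`,
#'   `replicate_of` (NA/"" for first digitizations) and the factor
#'   columns.
#' @param partition which landmarks enter: `"all"`, `"anchors"` or
#'   `"semilandmarks"`.
#' @param anchor_count how many leading landmarks are anchors (default 20).
#' @param factors ordered factor columns of `meta` to decompose (default
#'   ethnicity, sex, age_class).
#' @return a data.frame of class `procrustes_anova_table` with columns
#'   effect, var_pct, SS, MS, DF, F, p.
#' @export
procrustes_anova <- function(configs, meta,
                             partition = c("all", "anchors",
                                           "semilandmarks"),
                             anchor_count = 20,
                             factors = c("ethnicity", "sex", "age_class")) {
  partition <- match.arg(partition)
  arr <- as_config_array(configs)
  K_all <- dim(arr)[2]
  idx <- switch(partition,
                all = seq_len(K_all),
                anchors = seq_len(anchor_count),
                semilandmarks = (anchor_count + 1):K_all)
  arr <- arr[, idx, , drop = FALSE]
  K <- length(idx)
  sdim <- 3 * K - 7
  N_obs <- dim(arr)[1]
  if (nrow(meta) != N_obs)
    stop("procrustes_anova: meta rows must match configuration count")

  rep_of <- meta$replicate_of
  if (is.null(rep_of)) rep_of <- rep(NA_character_, N_obs)
  individual <- ifelse(is.na(rep_of) | rep_of == "", meta$id, rep_of)
  has_reps <- any(duplicated(individual))
  if (!has_reps)
    warning("procrustes_anova: no replicate digitizations; error stratum ",
            "omitted (individual variation is the residual)")

  space <- gpa(arr, ids = paste0(meta$id, ifelse(is.na(rep_of) | rep_of == "",
                                                 "", ".r")))
  Y <- tangent_coordinates(space)

  for (f in factors) {
    if (!f %in% names(meta)) stop("procrustes_anova: no column '", f, "'")
    if (length(unique(meta[[f]])) < 2)
      stop("procrustes_anova: factor '", f, "' has fewer than 2 levels")
  }

  terms <- c(factors, "individual")
  vars <- c(lapply(factors, function(f) factor(meta[[f]])),
            list(factor(individual)))
  names(vars) <- terms

  SS <- numeric(length(terms))
  DF <- numeric(length(terms))
  X <- matrix(1, N_obs, 1)
  prev_fit <- 0
  prev_rank <- 1L
  total_SS <- sum(sweep(Y, 2, colMeans(Y))^2)
  for (t in seq_along(terms)) {
    X <- cbind(X, stats::model.matrix(~v - 1, data.frame(v = vars[[t]])))
    q <- qr(X)
    rank_gain <- q$rank - prev_rank
    expected <- nlevels(vars[[t]]) - 1L -
      if (terms[t] == "individual") sum(vapply(vars[factors], nlevels, 0L) - 1L) else 0L
    if (terms[t] != "individual" && rank_gain < expected)
      stop("procrustes_anova: factor '", terms[t], "' is confounded with a ",
           "higher-order effect (design rank gain ", rank_gain, " < ",
           expected, ")")
    fit <- qr.fitted(q, Y)
    fit_SS <- sum(fit^2) - sum(colMeans(Y)^2) * N_obs
    SS[t] <- fit_SS - prev_fit
    prev_fit <- fit_SS
    prev_rank <- q$rank
    DF[t] <- if (terms[t] == "individual")
      (nlevels(vars[[t]]) - 1L - sum(vapply(vars[factors], nlevels, 0L) - 1L)) * sdim
    else (nlevels(vars[[t]]) - 1L) * sdim
  }
  err_SS <- total_SS - prev_fit
  n_ind <- nlevels(vars$individual)
  err_DF <- (N_obs - n_ind) * sdim

  effects <- c(factors, "individual", if (has_reps) "digitizing_error")
  SS_all <- c(SS, if (has_reps) err_SS)
  if (!has_reps) SS_all[length(SS_all)] <- SS[length(SS)] + err_SS
  DF_all <- c(DF, if (has_reps) err_DF)
  MS <- SS_all / DF_all
  nf <- length(factors)
  Fv <- rep(NA_real_, length(effects))
  pv <- rep(NA_real_, length(effects))
  denom_ms <- MS[nf + 1]          # individual stratum
  for (t in seq_len(nf)) {
    Fv[t] <- MS[t] / denom_ms
    pv[t] <- stats::pf(Fv[t], DF_all[t], DF_all[nf + 1], lower.tail = FALSE)
  }
  if (has_reps) {
    Fv[nf + 1] <- MS[nf + 1] / MS[nf + 2]
    pv[nf + 1] <- stats::pf(Fv[nf + 1], DF_all[nf + 1], DF_all[nf + 2],
                            lower.tail = FALSE)
  }
  tab <- data.frame(effect = c(effects, "Total"),
                    var_pct = c(100 * SS_all / sum(SS_all), 100),
                    SS = c(SS_all, sum(SS_all)),
                    MS = c(MS, NA),
                    DF = c(DF_all, sum(DF_all)),
                    F = c(Fv, NA), p = c(pv, NA))
  class(tab) <- c("procrustes_anova_table", "data.frame")
  attr(tab, "partition") <- partition
  attr(tab, "K") <- K
  tab
}

#' The twelve anthropometric distances reported for sex and age groups
#'
#' Cranial length (me-op), facial heights and widths, eye, nose, mouth and
#' chin/jaw segments — the standard craniofacial measurement set.
#' @export
TABLE_DISTANCE_PAIRS <- c("me-op", "me-n", "me-gn", "tl-tr", "enl-enr",
                          "exl-exr", "n-pr", "all-alr", "chl-chr", "ls-li",
                          "li-gn", "tl-gn")

#' Euclidean distance matrix analysis on a mean configuration
#'
#' Computes the Euclidean lengths (mm) of the line segments connecting
#' selected anchor landmarks on a mean shape, and their base-10
#' logarithms (base 10 matches the magnitude of anthropometric lengths:
#' log10 of a 200 mm cranial length is about 2.3).
#'
#' @param mean_config a `landmark_config` or a K x 3 matrix with labelled
#'   rows, in mm.
#' @param pairs `"all"` for every anchor pair, or a character vector of
#'   `"a-b"` pair labels (see [TABLE_DISTANCE_PAIRS]).
#' @return a data.frame of class `edma_result`: pair, distance_mm,
#'   log10_distance.
#' @export
edma_log_distances <- function(mean_config, pairs = "all") {
  if (inherits(mean_config, "landmark_config")) {
    pts <- anchor_points(mean_config)
    labs <- mean_config$labels
  } else {
    pts <- as.matrix(mean_config)
    labs <- rownames(pts)
    if (is.null(labs)) stop("edma_log_distances: configuration needs ",
                            "labelled rows")
  }
  if (identical(pairs, "all")) {
    cmb <- utils::combn(labs, 2)
    pairs <- paste(cmb[1, ], cmb[2, ], sep = "-")
  }
  parts <- strsplit(pairs, "-", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) != 2 || !all(p %in% labs), TRUE)
  if (any(bad))
    stop("edma_log_distances: unknown landmark label(s) in: ",
         paste(pairs[bad], collapse = ", "), "; valid notations: ",
         paste(labs, collapse = ", "))
  d <- vapply(parts, function(p)
    sqrt(sum((pts[match(p[1], labs), ] - pts[match(p[2], labs), ])^2)),
    0)
  out <- data.frame(pair = pairs, distance_mm = d, log10_distance = log10(d))
  class(out) <- c("edma_result", "data.frame")
  out
}

#' Group mean shapes in millimetres
#'
#' Mean of the GPA-aligned configurations per group, rescaled by the
#' group's mean centroid size so inter-landmark distances are plain
#' anthropometric lengths in mm.
#'
#' @param shape_space a [gpa()] result.
#' @param labels group label per specimen.
#' @param anchor_labels optional anchor labels to attach as rownames.
#' @return named list of K x 3 matrices (mm).
#' @export
group_mean_shapes_mm <- function(shape_space, labels, anchor_labels = NULL) {
  labels <- as.character(labels)
  out <- list()
  for (g in unique(labels)) {
    sel <- labels == g
    m <- apply(shape_space$aligned[sel, , , drop = FALSE], c(2, 3), mean)
    m <- m * mean(shape_space$centroid_sizes[sel])
    if (!is.null(anchor_labels))
      rownames(m)[seq_along(anchor_labels)] <- anchor_labels
    out[[g]] <- m
  }
  out
}
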