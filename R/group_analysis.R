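#' Multivariate regression of shape on centroid size (allometry)
#'
#' Least-squares regression of every tangent-space coordinate on centroid
#' size. The predicted and residual components are expressed as
#' percentages of the total variation; significance comes from permuting
#' centroid size against the shapes (add-one p-value convention).
#'
#' @param shape_space a [gpa()] result, or a list with `tangent` (N x p)
#'   and `sizes`.
#' @param subset optional logical/integer index of specimens to use.
#' @param n_perm permutations for the significance test (default 10000).
#' @param seed RNG seed.
#' @return an object of class `allometry_result`: `percent_predicted`,
#'   `p_value`, `coefficients` (p x 1 slope of shape on size),
#'   `residuals` (N x p residual shapes), `fitted`, `sizes`.
#' @export
regress_shape_on_size <- function(shape_space, subset = NULL,
                                  n_perm = 10000, seed = NULL) {
  if (inherits(shape_space, "shape_space")) {
    Y <- tangent_coordinates(shape_space)
    cs <- shape_space$centroid_sizes
  } else {
    Y <- shape_space$tangent; cs <- shape_space$sizes
  }
  if (!is.null(subset)) {
    Y <- Y[subset, , drop = FALSE]
    cs <- cs[subset]
  }
  N <- nrow(Y)
  if (N < 5) stop("regress_shape_on_size: need at least 5 specimens")
  if (stats::sd(cs) == 0)
    stop("regress_shape_on_size: centroid size is constant")
  Yc <- sweep(Y, 2, colMeans(Y))
  xc <- cs - mean(cs)
  ssx <- sum(xc^2)
  b <- crossprod(Yc, xc) / ssx                  # p x 1 slope
  fitted <- outer(xc, as.numeric(b))
  ss_total <- sum(Yc^2)
  ss_pred <- sum(fitted^2)
  obs_pct <- 100 * ss_pred / ss_total

  count <- with_seed(seed, {
    cnt <- 0L
    block <- 1000L
    done <- 0L
    CtY <- t(Yc)                                 # p x N
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      Xp <- vapply(seq_len(nb), function(i) sample(xc), numeric(N))
      Xp <- sweep(Xp, 2, colMeans(Xp))
      num <- colSums((CtY %*% Xp)^2)             # ||Y'x||^2 per permutation
      stat <- num / colSums(Xp^2)
      cnt <- cnt + sum(stat >= ss_pred - 1e-12 * ss_pred)
      done <- done + nb
    }
    cnt
  })
  structure(list(percent_predicted = obs_pct,
                 p_value = (count + 1) / (n_perm + 1),
                 coefficients = b, residuals = Yc - fitted,
                 fitted = fitted, sizes = cs, n = N),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat("<allometry_result> ", sprintf("%.2f", x$percent_predicted),
      "% of shape variation predicted by centroid size (p = ",
      format.pval(x$p_value), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Pooled within-group regression and size correction
#'
#' Estimates a common within-group allometric slope on group-centered
#' data and returns 'size corrected' shapes: the within-group allometric
#' component is removed while group mean differences are retained.
#'
#' @param shape_space a [gpa()] result.
#' @param labels group label per specimen.
#' @return list with `corrected` (N x p tangent coordinates), `slope`
#'   (p-vector), `labels`.
#' @export
pooled_within_group_size_correction <- function(shape_space, labels) {
  Y <- tangent_coordinates(shape_space)
  cs <- shape_space$centroid_sizes
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("pooled_within_group_size_correction: need at least 2 groups")
  sizes_tab <- table(labels)
  singles <- names(sizes_tab)[sizes_tab < 2]
  if (length(singles))
    warning("pooled_within_group_size_correction: group(s) of size 1 ",
            "excluded from slope estimation: ",
            paste(singles, collapse = ", "))
  use <- !(labels %in% singles)
  Yc <- Y; xc <- cs
  for (g in unique(labels)) {
    sel <- labels == g
    Yc[sel, ] <- sweep(Y[sel, , drop = FALSE], 2,
                       colMeans(Y[sel, , drop = FALSE]))
    xc[sel] <- cs[sel] - mean(cs[sel])
  }
  b <- crossprod(Yc[use, , drop = FALSE], xc[use]) / sum(xc[use]^2)
  corrected <- Y - outer(xc, as.numeric(b))
  list(corrected = corrected, slope = as.numeric(b), labels = labels)
}

#' MANOVA tests of allometric slopes and intercepts
#'
#' Two nested Wilks' lambda tests on retained PC scores with centroid
#' size as covariate: the group x size interaction from the full model
#' tests for common slopes (parallel allometric trajectories); the group
#' effect from the reduced model (without the interaction) tests for
#' different intercepts after controlling for size. F approximations are
#' Rao's, via [stats::manova()].
#'
#' @param scores N x q PC score matrix, or a `pca_result` (its scores are
#'   truncated by `cutoff`).
#' @param labels group label per specimen.
#' @param cs centroid sizes (covariate).
#' @param cutoff cumulative variance fraction used to pick q when a
#'   `pca_result` is given (default 0.9998).
#' @param q explicit number of score columns (overrides `cutoff`).
#' @return a data.frame of class `manova_result` with one row per test
#'   (slopes, intercepts): wilks, df_num, df_den, F, p.
#' @export
manova_allometry <- function(scores, labels, cs, cutoff = 0.9998, q = NULL) {
  if (inherits(scores, "pca_result")) {
    vf <- cumsum(scores$variance_fractions) / 100
    if (is.null(q)) q <- max(1L, which(vf >= cutoff)[1])
    scores <- scores$scores
  }
  if (is.null(q)) q <- ncol(scores)
  labels <- factor(labels)
  g <- nlevels(labels)
  N <- nrow(scores)
  if (q >= N - 2 * g)
    stop("manova_allometry: dimensionality error: q = ", q,
         " score columns leave no residual degrees of freedom for N = ", N,
         " and ", g, " groups; lower the variance cutoff or pass a ",
         "smaller q")
  S <- scores[, seq_len(q), drop = FALSE]
  cs <- as.numeric(cs)
  full <- stats::manova(S ~ labels * cs)
  red <- stats::manova(S ~ cs + labels)
  pick <- function(fit, term) {
    sm <- summary(fit, test = "Wilks")$stats
    row <- sm[rownames(sm) == term, , drop = FALSE]
    data.frame(wilks = row[1, "Wilks"], df_num = row[1, "num Df"],
               df_den = row[1, "den Df"], F = row[1, "approx F"],
               p = row[1, "Pr(>F)"])
  }
  out <- rbind(cbind(effect = "slopes (group x CS)",
                     pick(full, "labels:cs")),
               cbind(effect = "intercepts (group)", pick(red, "labels")))
  class(out) <- c("manova_result", "data.frame")
  attr(out, "q") <- q
  out
}

#' Canonical variate analysis
#'
#' Eigen-decomposition of the within-group-scatter-inverse times
#' between-group scatter, giving at most (groups - 1) canonical axes that
#' maximize between- relative to within-group variance. If the within
#' scatter is singular the data are first reduced by PCA (logged via a
#' message). Axes are scaled so the pooled within-group variance on each
#' axis is 1.
#'
#' @param scores N x q matrix (PC scores or tangent coordinates).
#' @param labels group label per specimen.
#' @return an object of class `cva_result`: `scores` (N x axes), `axes`
#'   (q x axes), `eigenvalues`, `labels`.
#' @export
cva <- function(scores, labels) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("cva: need at least 2 groups")
  if (any(table(labels) < 2)) stop("cva: every group needs >= 2 members")
  N <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(labels)) {
    sel <- labels == lv
    mg <- colMeans(Xc[sel, , drop = FALSE])
    dev <- sweep(Xc[sel, , drop = FALSE], 2, mg)
    W <- W + crossprod(dev)
    B <- B + sum(sel) * tcrossprod(mg)
  }
  proj <- diag(ncol(X))
  ew <- eigen(W, symmetric = TRUE)
  tol <- max(ew$values) * 1e-9
  if (any(ew$values < tol)) {
    keep <- ew$values >= tol
    message("cva: singular within-group scatter; reducing from ", ncol(X),
            " to ", sum(keep), " dimensions by PCA preprocessing")
    proj <- ew$vectors[, keep, drop = FALSE]
    W <- t(proj) %*% W %*% proj
    B <- t(proj) %*% B %*% proj
    Xc <- Xc %*% proj
  }
  e <- eigen(solve(W, B))
  ord <- order(Re(e$values), decreasing = TRUE)
  naxes <- min(g - 1, ncol(W))
  vec <- Re(e$vectors[, ord[seq_len(naxes)], drop = FALSE])
  lam <- Re(e$values[ord[seq_len(naxes)]])
  ## scale: unit pooled within-group variance per axis
  for (j in seq_len(naxes)) {
    s <- sqrt(drop(t(vec[, j]) %*% W %*% vec[, j]) / (N - g))
    vec[, j] <- vec[, j] / s
  }
  structure(list(scores = Xc %*% vec, axes = proj %*% vec,
                 eigenvalues = lam, labels = labels),
            class = "cva_result")
}

## Rao's F approximation for Wilks' lambda with p variables, q hypothesis
## df, and error df ve. Exact when min(p, q) <= 2.
rao_wilks_f <- function(lambda, p, q, ve) {
  t <- sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  if (!is.finite(t) || t == 0) t <- 1
  w <- ve + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t - (p * q - 2) / 2
  L <- lambda^(1 / t)
  F <- (1 - L) / L * df2 / df1
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Cross-validated discriminant classification
#'
#' Linear discriminant analysis with pooled covariance on retained PC
#' scores, evaluated by leave-one-out cross-validation. The confusion
#' matrix is reported in row-percent of the true group; the significance
#' of the discriminant functions is a Wilks' lambda test with Rao's F
#' approximation.
#'
#' @param scores N x q score matrix.
#' @param labels true group label per specimen.
#' @param max_q cap on the number of score columns; shrunk automatically
#'   (with a message) to below the smallest group size for a stable
#'   pooled covariance.
#' @return an object of class `classification_result`: `confusion`
#'   (row-%), `accuracy` (overall %), `per_group_accuracy` (%),
#'   `predicted`, `wilks`, `wilks_F`, `wilks_p`, `q_used`.
#' @export
discriminant_classify <- function(scores, labels, max_q = NULL) {
  X <- as.matrix(scores)
  labels <- factor(labels)
  g <- nlevels(labels)
  if (g < 2) stop("discriminant_classify: need at least 2 groups")
  tab <- table(labels)
  if (any(tab < 2))
    stop("discriminant_classify: group(s) with a single member: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  q_stable <- min(ncol(X), min(tab) - 1L, nrow(X) - g - 1L)
  q <- min(max_q %||% ncol(X), ncol(X))
  if (q > q_stable) {
    message("discriminant_classify: shrinking feature count from ", q,
            " to ", q_stable, " for a stable pooled covariance")
    q <- q_stable
  }
  S <- X[, seq_len(q), drop = FALSE]
  fit <- MASS::lda(S, grouping = labels, CV = TRUE)
  pred <- fit$class
  cm <- table(true = labels, predicted = pred)
  row_pct <- sweep(cm, 1, rowSums(cm), "/") * 100
  acc <- 100 * mean(pred == labels)
  per_group <- 100 * diag(cm) / rowSums(cm)
  ## Wilks' lambda of the discriminant functions
  cv <- cva(S, labels)
  lambda <- prod(1 / (1 + cv$eigenvalues))
  rao <- rao_wilks_f(lambda, p = q, q = g - 1, ve = nrow(S) - g)
  structure(list(confusion = row_pct, counts = cm, accuracy = acc,
                 per_group_accuracy = per_group, predicted = pred,
                 wilks = lambda, wilks_F = rao$F, wilks_p = rao$p,
                 q_used = q),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> LOO accuracy ", sprintf("%.2f", x$accuracy),
      "% (", x$q_used, " features; Wilks = ", signif(x$wilks, 4), ", p = ",
      format.pval(x$wilks_p), ")\n", sep = "")
  print(round(x$confusion, 2))
  invisible(x)
}
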