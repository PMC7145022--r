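#' Thin-plate spline radial kernel vector
#'
#' In three dimensions the TPS radial kernel is the plain Euclidean
#' distance, U(r) = r: entry w of the result is the distance from `query`
#' to control point w.
#'
#' @param query a single 3D point.
#' @param controls M x 3 matrix of control points (pairwise distinct).
#' @return numeric vector of length M.
#' @export
tps_kernel_vector <- function(query, controls) {
  controls <- as.matrix(controls)
  sqrt(colSums((t(controls) - as.numeric(query))^2))
}

#' Fit a 3D thin-plate spline
#'
#' Solves the bordered linear system for the non-affine coefficients K and
#' the homogeneous affine part Gamma of the map h(p) = Psi(p) K + p Gamma,
#' where points are augmented with a trailing 1 (M x 4 homogeneous form).
#' With `beta = 0` the spline interpolates: h(source_i) = destination_i.
#' With `beta > 0` the kernel block gets `beta` added on its diagonal,
#' trading exactness for smoothness.
#'
#' The direction convention is fixed: the spline maps the template
#' (source) onto the target (destination) and is used that way throughout
#' the pipeline.
#'
#' @param source M x 3 control points (template side), pairwise distinct,
#'   M >= 5 and not coplanar.
#' @param destination M x 3 corresponding points (target side).
#' @param beta smoothing regularization scalar >= 0 (default 0,
#'   interpolation).
#' @return an object of class `tps_model` with elements `source_points`,
#'   `destination_points`, `nonaffine` (M x 4 coefficients K), `affine`
#'   (4 x 4 Gamma), `beta`, `bending_energy`, `kernel` (the M x M Psi).
#' @export
fit_tps <- function(source, destination, beta = 0) {
  source <- as.matrix(source); destination <- as.matrix(destination)
  M <- nrow(source)
  if (ncol(source) != 3 || ncol(destination) != 3 || nrow(destination) != M)
    stop("fit_tps: source and destination must both be M x 3")
  if (!all(is.finite(source)) || !all(is.finite(destination)))
    stop("fit_tps: non-finite coordinates")
  if (beta < 0) stop("fit_tps: beta must be >= 0")
  if (M < 5)
    stop("fit_tps: rank error: need M >= 5 control points for a full-rank ",
         "3D affine part (got ", M, ")")
  Psi <- as.matrix(stats::dist(source))
  near <- which(Psi < 1e-9 & upper.tri(Psi), arr.ind = TRUE)
  if (nrow(near))
    stop("fit_tps: duplicate (or < 1e-9 mm apart) source points: rows ",
         paste(apply(near, 1L, paste, collapse = "/"), collapse = ", "))
  sv <- svd(scale(source, scale = FALSE))$d
  if (sv[3] <= 1e-10 * sv[1])
    stop("fit_tps: rank error: source points are coplanar ",
         "(affine part would be rank deficient)")
  P <- cbind(source, 1)
  ## U(r) = r is conditionally negative definite, so the smoothing term
  ## enters with a minus sign: stationarity of the penalized objective
  ## gives (Psi - beta I) K + P Gamma = Y under this kernel convention
  ## (the familiar "+ beta I" belongs to the positive-kernel convention)
  L <- rbind(cbind(Psi - diag(beta, M), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(cbind(destination, 1), matrix(0, 4, 4))
  sol <- tryCatch(solve(L, rhs),
                  error = function(e)
                    stop("fit_tps: singular bordered system: ",
                         conditionMessage(e)))
  K <- sol[seq_len(M), , drop = FALSE]
  Gamma <- sol[M + 1:4, , drop = FALSE]
  ## U(r) = r is conditionally negative definite, so the bending-energy
  ## quadratic form carries a global sign flip to be non-negative.
  E <- -sum(K[, 1:3] * (Psi %*% K[, 1:3]))
  if (E < 0) E <- max(E, 0)  # clip numerical noise near the affine null space
  structure(list(source_points = source, destination_points = destination,
                 nonaffine = K, affine = Gamma, beta = beta,
                 bending_energy = E, kernel = Psi),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline at query points
#'
#' @param model a [fit_tps()] result.
#' @param queries N x 3 matrix (or a single point) to map.
#' @return N x 3 matrix of warped points.
#' @export
warp_points <- function(model, queries) {
  queries <- as.matrix(queries)
  if (length(queries) == 3L && ncol(queries) != 3) queries <- t(queries)
  Psi_q <- cross_dist(queries, model$source_points)
  H <- Psi_q %*% model$nonaffine + cbind(queries, 1) %*% model$affine
  H[, 1:3, drop = FALSE]
}

#' Bending energy of a fitted spline
#'
#' The integral of squared second derivatives of the map, evaluated in
#' closed form as the (sign-corrected) quadratic form of the non-affine
#' coefficients in the kernel matrix. Zero iff the map is affine.
#'
#' @param model a [fit_tps()] result.
#' @return non-negative scalar.
#' @export
bending_energy <- function(model) model$bending_energy

#' Bending-energy matrix of a control-point configuration
#'
#' The positive semi-definite K x K matrix B such that the bending energy
#' of a TPS mapping `points` onto a destination Y is trace(Y' B Y). This is
#' the top-left block of the inverse bordered matrix, sign-corrected for
#' the 3D kernel U(r) = r. Its null space is spanned by the homogeneous
#' coordinates of `points` (affine maps cost nothing).
#'
#' @param points K x 3 control configuration (pairwise distinct, K >= 5,
#'   non-coplanar).
#' @return K x K symmetric matrix.
#' @export
bending_energy_matrix <- function(points) {
  points <- as.matrix(points)
  M <- nrow(points)
  Psi <- as.matrix(stats::dist(points))
  P <- cbind(points, 1)
  L <- rbind(cbind(Psi, P), cbind(t(P), matrix(0, 4, 4)))
  Linv <- tryCatch(solve(L),
                   error = function(e)
                     stop("bending_energy_matrix: singular system ",
                          "(duplicate control points?): ",
                          conditionMessage(e)))
  B <- -Linv[seq_len(M), seq_len(M), drop = FALSE]
  (B + t(B)) / 2
}
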