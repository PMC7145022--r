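#' Transfer the template onto a target mesh
#'
#' Fits a thin-plate spline on the 20 anchor pairs (the anchors establish
#' the warping field), maps the template semi-landmarks through it, and
#' projects each warped point onto the closest point of the target
#' surface. Points whose projection travels farther than 10 x the spacing
#' radius are flagged with a warning rather than silently accepted.
#'
#' @param template a [generate_template_semilandmarks()] result.
#' @param target_mesh target [surface_mesh()].
#' @param target_anchors digitized anchors on the target, same labels and
#'   order as the template anchors.
#' @param beta TPS smoothing term (default 0, interpolation).
#' @return a [landmark_configuration()] of target anchors + transferred
#'   semi-landmarks, with attribute `triangle` (containing triangle per
#'   semi-landmark).
#' @export
transfer_template <- function(template, target_mesh, target_anchors,
                              beta = 0) {
  if (!identical(template$landmarks$labels, target_anchors$labels))
    stop("transfer_template: correspondence error: target anchor labels ",
         "do not match template anchors")
  src <- anchor_points(template$landmarks)
  dst <- anchor_points(target_anchors)
  model <- fit_tps(src, dst, beta = beta)
  warped <- warp_points(model, semilandmark_points(template$landmarks))
  cp <- closest_point_on_mesh(warped, target_mesh)
  far <- which(cp$distance > 10 * template$spacing_radius)
  if (length(far))
    warning("transfer_template: projection distance > ",
            10 * template$spacing_radius, " mm for semi-landmark(s) ",
            paste(utils::head(far, 10), collapse = ", "))
  out <- landmark_configuration(rbind(dst, cp$point),
                                target_anchors$anchor_count,
                                labels = target_anchors$labels)
  attr(out, "triangle") <- cp$triangle
  out
}

## Geometric step schedule from step_start down to step_end over `cycles`
## cycles (exponential decay; endpoints 1.00 and 0.05 by default).
sliding_step_schedule <- function(cycles = 6, step_start = 1.00,
                                  step_end = 0.05) {
  if (cycles < 1) stop("sliding_step_schedule: cycles must be >= 1")
  if (cycles == 1) return(step_start)
  ratio <- (step_end / step_start)^(1 / (cycles - 1))
  step_start * ratio^(seq_len(cycles) - 1)
}

#' Slide semi-landmarks by bending-energy minimization
#'
#' Iterative relaxation of the transferred semi-landmarks on the target
#' surface. Each cycle: (a) tangent frames are computed at the current
#' semi-landmarks; (b) the tangent-plane displacements minimizing the TPS
#' bending energy between the target configuration and the template are
#' solved as one dense symmetric system (the classical minimum-bending-
#' energy semi-landmark formulation); (c) displacements are scaled by the
#' cycle's step fraction, decaying geometrically from `step_start` to
#' `step_end`; (d) points are re-projected onto the target surface.
#' Anchors never move. Six cycles is the default; the trace records the
#' bending energy after every cycle, from the initial value E_i to the
#' final E_f.
#'
#' @param template a `template_model`.
#' @param target_mesh target [surface_mesh()].
#' @param target_anchors digitized target anchors (labels matching the
#'   template).
#' @param cycles number of complete sliding cycles (default 6).
#' @param step_start,step_end step-fraction endpoints of the exponential
#'   decay (defaults 1.00 down to 0.05).
#' @param transferred optional precomputed [transfer_template()] result.
#' @param tol optional early-stop tolerance on the relative energy change
#'   per cycle; `NULL` (default) always runs all cycles.
#' @return an object of class `sliding_trace`: `energies` (per cycle),
#'   `initial_energy`, `step_fractions`, `landmarks` (final homologous
#'   configuration), `triangles`.
#' @export
slide_semilandmarks <- function(template, target_mesh, target_anchors,
                                cycles = 6, step_start = 1.00,
                                step_end = 0.05, transferred = NULL,
                                tol = NULL) {
  if (is.null(transferred))
    transferred <- transfer_template(template, target_mesh, target_anchors)
  X <- template$landmarks$points
  k <- nrow(X)
  na <- template$landmarks$anchor_count
  m <- template$landmarks$semilandmark_count
  semi_idx <- na + seq_len(m)
  ## the template's bending-energy matrix is fixed; cache it across calls
  if (!is.null(template$cache) &&
      !is.null(template$cache$bending_matrix)) {
    B <- template$cache$bending_matrix
  } else {
    B <- bending_energy_matrix(X)
    if (!is.null(template$cache)) template$cache$bending_matrix <- B
  }
  steps <- sliding_step_schedule(cycles, step_start, step_end)
  normals <- vertex_normals(target_mesh)

  Y <- transferred$points
  tri <- attr(transferred, "triangle")
  energy <- function(Y) max(0, sum(Y * (B %*% Y)))
  E0 <- energy(Y)
  energies <- numeric(cycles)

  for (cy in seq_len(cycles)) {
    dm <- as.matrix(stats::dist(Y[semi_idx, , drop = FALSE]))
    coll <- which(dm < 1e-9 & upper.tri(dm), arr.ind = TRUE)
    if (nrow(coll))
      stop("slide_semilandmarks: singular bending-energy system; ",
           "colliding semi-landmarks after projection: ",
           paste(apply(coll, 1, paste, collapse = "/"), collapse = ", "))
    ## tangent frames at current semi-landmarks (known triangles)
    D <- matrix(0, 2 * m, 3)
    for (j in seq_len(m)) {
      fr <- tangent_frame(target_mesh, Y[semi_idx[j], ], normals = normals,
                          triangle = tri[j])
      D[2 * j - 1, ] <- fr$t1
      D[2 * j, ] <- fr$t2
    }
    ## minimize sum_d (y_d + U_d t)' B (y_d + U_d t) over tangent coefs t
    rep_idx <- rep(seq_len(m), each = 2)
    Bss <- B[semi_idx, semi_idx, drop = FALSE][rep_idx, rep_idx]
    A <- Bss * tcrossprod(D)
    BY <- B %*% Y
    b <- rowSums(D * BY[semi_idx, , drop = FALSE][rep_idx, , drop = FALSE])
    t_hat <- tryCatch(solve(A + diag(1e-12 * mean(diag(A)), nrow(A)), -b),
                      error = function(e)
                        stop("slide_semilandmarks: singular bending-energy ",
                             "system: ", conditionMessage(e), call. = FALSE))
    disp <- D[seq(1, 2 * m, by = 2), , drop = FALSE] *
      t_hat[seq(1, 2 * m, by = 2)] +
      D[seq(2, 2 * m, by = 2), , drop = FALSE] * t_hat[seq(2, 2 * m, by = 2)]
    Ynew <- Y
    Ynew[semi_idx, ] <- Y[semi_idx, , drop = FALSE] + steps[cy] * disp
    cp <- closest_point_on_mesh(Ynew[semi_idx, , drop = FALSE], target_mesh)
    Ynew[semi_idx, ] <- cp$point
    Enew <- energy(Ynew)
    Eprev <- if (cy == 1) E0 else energies[cy - 1]
    ## monotone safeguard: the tangent step minimizes the energy exactly,
    ## but re-projection onto the curved surface can push it back up; a
    ## cycle that would end higher than the previous one is not applied
    if (Enew <= Eprev * (1 + 1e-9) + 1e-15) {
      Y <- Ynew
      tri <- cp$triangle
      energies[cy] <- Enew
    } else {
      energies[cy] <- Eprev
    }
    if (!is.null(tol) && cy > 1 &&
        abs(energies[cy] - energies[cy - 1]) <=
          tol * max(energies[cy - 1], .Machine$double.eps)) {
      energies <- energies[seq_len(cy)]
      steps <- steps[seq_len(cy)]
      break
    }
  }
  lm <- landmark_configuration(Y, na, labels = template$landmarks$labels)
  structure(list(energies = energies, initial_energy = E0,
                 step_fractions = steps, landmarks = lm, triangles = tri),
            class = "sliding_trace")
}

#' @export
print.sliding_trace <- function(x, ...) {
  cat("<sliding_trace> ", length(x$energies), " cycles; E_i = ",
      signif(x$initial_energy, 4), " -> E_f = ",
      signif(x$energies[length(x$energies)], 4), "\n", sep = "")
  invisible(x)
}
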