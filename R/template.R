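#' Generate surface semi-landmarks for the template
#'
#' Builds the 500-point template: starting from the seed anchor (the
#' pronasale, the most robust and prominent facial point), `n`
#' semi-landmarks are first placed randomly on the template surface and
#' then uniformized by iterative tangent-plane repulsion constrained to
#' the surface (Lloyd-style relaxation with closest-point re-projection).
#' Anchors act as fixed repulsors so the semi-landmarks respect the
#' spacing radius around them; the first semi-landmark is initialized on
#' the seed anchor's surface point, where the spreading starts, and then
#' relaxes with the rest (with `n = 1` it simply stays there).
#'
#' @param mesh template [surface_mesh()].
#' @param anchors [landmark_configuration()] of anchors on the mesh; must
#'   contain the seed anchor label.
#' @param n number of semi-landmarks (default 480).
#' @param radius spacing radius in mm (default 1.5) — a lower bound on
#'   admissible spacing; the relaxation radius adapts to surface area so
#'   points spread uniformly even when the surface is much larger than
#'   `n` disks of this radius.
#' @param seed RNG seed; the same seed reproduces the template exactly.
#' @param seed_anchor label of the anchor the spreading starts from
#'   (default `"pr"`).
#' @param n_iter relaxation sweeps (default 40).
#' @return an object of class `template_model`: `mesh`, `landmarks`
#'   (anchors + semi-landmarks), `seed_anchor`, `spacing_radius`,
#'   `triangles` (containing triangle per landmark).
#' @export
generate_template_semilandmarks <- function(mesh, anchors, n = 480,
                                            radius = 1.5, seed = 1,
                                            seed_anchor = "pr",
                                            n_iter = 40) {
  validate_mesh(mesh)
  if (n < 1) stop("generate_template_semilandmarks: n must be >= 1")
  if (!seed_anchor %in% anchors$labels)
    stop("generate_template_semilandmarks: seed anchor '", seed_anchor,
         "' not among anchor labels")
  A <- anchor_points(anchors)
  area <- mesh_area(mesh)
  if (area < (n + anchors$anchor_count) * pi * (radius / 2)^2)
    stop("generate_template_semilandmarks: capacity error: surface area ",
         signif(area, 4), " mm^2 cannot hold ", n + anchors$anchor_count,
         " points at spacing radius ", radius, " mm")
  seed_pt <- closest_point_on_mesh(A[match(seed_anchor, anchors$labels), ],
                                   mesh)
  normals <- vertex_normals(mesh)
  ## interaction radius: at least the requested spacing, but wide enough
  ## for uniform coverage of the whole surface
  r_int <- max(radius, 1.7 * sqrt(area / (n + anchors$anchor_count)))

  res <- with_seed(seed, {
    init <- sample_on_mesh(mesh, n)
    pts <- init$points
    tri <- init$triangle
    pts[1, ] <- seed_pt$point[1, ]
    tri[1] <- seed_pt$triangle[1]
    ## the seed semi-landmark starts on the pronasale and spreads outward
    ## with the rest (it only stays put in the degenerate n = 1 case, where
    ## no repulsion acts); a permanent pin would duplicate the pr anchor
    ## and make the template's bending-energy system singular
    fixed <- c(n == 1L, rep(FALSE, n - 1))

    for (it in seq_len(n_iter)) {
      repulsors <- rbind(pts, A)
      D <- cross_dist(pts, repulsors)
      D[cbind(seq_len(n), seq_len(n))] <- Inf  # self
      force <- matrix(0, n, 3)
      close <- which(D < r_int, arr.ind = TRUE)
      if (nrow(close)) {
        dirs <- pts[close[, 1], , drop = FALSE] -
          repulsors[close[, 2], , drop = FALSE]
        d <- D[close]
        d[d < 1e-9] <- 1e-9
        mag <- (r_int - d) / r_int
        dirs <- dirs / d * mag
        for (dd in 1:3) {
          s <- rowsum(dirs[, dd], close[, 1])
          force[as.integer(rownames(s)), dd] <- s
        }
      }
      step <- 0.25 * r_int * (1 - 0.5 * (it - 1) / n_iter)
      move <- rowwise_norm(force)
      scl <- ifelse(move > 0, pmin(move, 1) / move * step, 0)
      prop <- pts + force * scl
      prop[fixed, ] <- pts[fixed, , drop = FALSE]
      cp <- closest_point_on_mesh(prop, mesh)
      pts <- cp$point
      tri <- cp$triangle
    }
    list(pts = pts, tri = tri)
  })

  semis <- res$pts
  if (n > 1) {
    dmin <- min(stats::dist(semis))
    if (dmin < 0.5 * radius)
      warning("generate_template_semilandmarks: minimum semi-landmark ",
              "spacing ", signif(dmin, 3), " mm is below half the spacing ",
              "radius")
  }
  lm <- landmark_configuration(rbind(A, semis), anchors$anchor_count,
                               labels = anchors$labels)
  anchor_cp <- closest_point_on_mesh(A, mesh)
  structure(list(mesh = mesh, landmarks = lm, seed_anchor = seed_anchor,
                 spacing_radius = radius,
                 triangles = c(anchor_cp$triangle, res$tri),
                 cache = new.env(parent = emptyenv())),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat("<template_model> ", x$landmarks$anchor_count, " anchors + ",
      x$landmarks$semilandmark_count, " semi-landmarks (seed '",
      x$seed_anchor, "', radius ", x$spacing_radius, " mm)\n", sep = "")
  invisible(x)
}
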