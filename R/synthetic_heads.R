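## Unit directions (x = left, y = up, z = anterior) for the 20 anchor
## anatomical landmarks on the synthetic head; positions are evaluated on
## the head's radial surface function and snapped to the triangulation.
.anchor_directions <- function() {
  m <- rbind(
    enl = c( 0.16, 0.28, 0.92),
    exl = c( 0.42, 0.28, 0.82),
    exr = c(-0.42, 0.28, 0.82),
    enr = c(-0.16, 0.28, 0.92),
    me  = c( 0.00, 0.75, 0.62),
    g   = c( 0.00, 0.45, 0.90),
    n   = c( 0.00, 0.32, 0.95),
    pr  = c( 0.00, 0.04, 1.00),
    all = c( 0.14, 0.00, 0.97),
    alr = c(-0.14, 0.00, 0.97),
    chl = c( 0.25, -0.22, 0.88),
    chr = c(-0.25, -0.22, 0.88),
    ls  = c( 0.00, -0.18, 0.97),
    li  = c( 0.00, -0.30, 0.95),
    pg  = c( 0.00, -0.42, 0.92),
    gn  = c( 0.00, -0.52, 0.85),
    tl  = c( 0.95, 0.00, 0.05),
    tr  = c(-0.95, 0.00, 0.05),
    op  = c( 0.00, 0.12, -1.00),
    ve  = c( 0.00, 1.00, 0.02))
  m / rowwise_norm(m)
}

#' Parameters of the synthetic head surface
#'
#' The head is a smoothly deformed ellipsoid (semi-axes in mm) with
#' Gaussian feature bumps in direction space: nose, chin, brow, a slight
#' mouth inset and cheeks. Amplitudes are millimetres of radial
#' displacement.
#'
#' @param semi_axes ellipsoid semi-axes (width, height, depth) in mm.
#' @param nose_amp,chin_amp,brow_amp,mouth_amp,cheek_amp bump amplitudes
#'   (mm); `mouth_amp` is typically negative (an inset).
#' @param n_theta,n_phi latitude/longitude resolution of the triangulated
#'   sphere (default about 2.2k vertices — desk scale, far below a real
#'   scan's 180k).
#' @return a list of class `head_params`.
#' @export
make_head_params <- function(semi_axes = c(78, 95, 88), nose_amp = 14,
                             chin_amp = 6, brow_amp = 3, mouth_amp = -2,
                             cheek_amp = 4, n_theta = 40, n_phi = 56) {
  structure(list(semi_axes = semi_axes, nose_amp = nose_amp,
                 chin_amp = chin_amp, brow_amp = brow_amp,
                 mouth_amp = mouth_amp, cheek_amp = cheek_amp,
                 n_theta = as.integer(n_theta), n_phi = as.integer(n_phi)),
            class = "head_params")
}

## Radial surface function: distance from origin to the surface along the
## unit directions in U (n x 3).
.head_radius <- function(U, params) {
  ax <- params$semi_axes
  r <- 1 / sqrt((U[, 1] / ax[1])^2 + (U[, 2] / ax[2])^2 +
                (U[, 3] / ax[3])^2)
  bump <- function(center, width, amp) {
    c0 <- center / sqrt(sum(center^2))
    ang <- acos(pmin(1, pmax(-1, U %*% c0)))
    amp * exp(-(ang / width)^2)
  }
  r <- r + bump(c(0, 0.04, 1), 0.13, params$nose_amp)
  r <- r + bump(c(0, -0.50, 0.87), 0.25, params$chin_amp)
  r <- r + bump(c(0, 0.43, 0.90), 0.22, params$brow_amp)
  r <- r + bump(c(0, -0.21, 0.95), 0.14, params$mouth_amp)
  r <- r + bump(c(0.52, -0.05, 0.75), 0.30, params$cheek_amp)
  r <- r + bump(c(-0.52, -0.05, 0.75), 0.30, params$cheek_amp)
  as.numeric(r)
}

#' Build a synthetic head mesh with ground-truth anchors
#'
#' Generates a watertight head-like triangulated surface from the radial
#' function of [make_head_params()] on a latitude/longitude grid, and
#' places the 20 anchor anatomical landmarks (enl ... ve) by construction:
#' each anchor direction is evaluated on the continuous surface and
#' snapped to the closest point of the triangulation, so every anchor
#' lies exactly on the mesh.
#'
#' @param params a [make_head_params()] list.
#' @param seed accepted for interface symmetry; the construction is fully
#'   deterministic in `params`.
#' @return list with `mesh` (a [surface_mesh()]), `anchors` (a
#'   [landmark_configuration()] with the 20 standard notations) and
#'   `anchor_bary` (triangle + barycentric weights used to carry anchors
#'   through deformations).
#' @export
make_head_mesh <- function(params = make_head_params(), seed = NULL) {
  nt <- params$n_theta; np <- params$n_phi
  theta <- seq(0, pi, length.out = nt + 2)[2:(nt + 1)]
  phi <- seq(0, 2 * pi, length.out = np + 1)[seq_len(np)]
  grid <- expand.grid(phi = phi, theta = theta)
  U <- cbind(sin(grid$theta) * sin(grid$phi),
             cos(grid$theta),
             sin(grid$theta) * cos(grid$phi))
  U <- rbind(c(0, 1, 0), U, c(0, -1, 0))   # poles first/last
  r <- .head_radius(U, params)
  if (any(r < 20))
    stop("make_head_mesh: generation error: surface radius collapses ",
         "below 20 mm (self-intersecting parameter ranges)")
  V <- U * r
  idx <- function(i, j) 1L + (i - 1L) * np + ((j - 1L) %% np) + 1L
  tris <- list()
  for (j in seq_len(np)) {                 # top cap
    tris[[length(tris) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
  }
  for (i in seq_len(nt - 1L)) {
    for (j in seq_len(np)) {
      a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j)
      d <- idx(i + 1, j + 1)
      tris[[length(tris) + 1L]] <- c(a, cc, b)
      tris[[length(tris) + 1L]] <- c(b, cc, d)
    }
  }
  bottom <- nrow(V)
  for (j in seq_len(np)) {                 # bottom cap
    tris[[length(tris) + 1L]] <- c(bottom, idx(nt, j + 1), idx(nt, j))
  }
  mesh <- surface_mesh(V, do.call(rbind, tris), name = "synthetic_head")
  dirs <- .anchor_directions()
  pts <- dirs * .head_radius(dirs, params)
  cp <- closest_point_on_mesh(pts, mesh)
  bary <- matrix(NA_real_, nrow(dirs), 3)
  for (i in seq_len(nrow(dirs))) {
    tri <- mesh$triangles[cp$triangle[i], ]
    bary[i, ] <- barycentric_coords(cp$point[i, ], mesh$vertices[tri[1], ],
                                    mesh$vertices[tri[2], ],
                                    mesh$vertices[tri[3], ])
  }
  anchors <- landmark_configuration(cp$point, nrow(dirs),
                                    labels = rownames(dirs))
  list(mesh = mesh, anchors = anchors,
       anchor_bary = list(triangle = cp$triangle, weights = bary))
}

## The fixed per-factor effect fields: smooth scalar bumps applied along
## the local surface normal (tangential displacement would slide material
## points without changing the surface, so it carries no recoverable
## shape information). Ethnicity: cranial widening/roundness; sex: nose +
## mouth protrusion scale; age: chin and forehead protrusion; allometry:
## jaw/cheek growth distinct from the sex field.
.effect_fields <- function(mesh, normals) {
  defs <- list(
    ethnicity = list(centers = rbind(c(70, 30, -10), c(-70, 30, -10),
                                     c(0, 40, -85)),
                     widths = c(45, 45, 50), amps = c(1, 1, -0.6)),
    sex = list(centers = rbind(c(0, 5, 100), c(0, -25, 88)),
               widths = c(25, 20), amps = c(1, 0.7)),
    age_class = list(centers = rbind(c(0, -48, 78), c(0, 62, 55)),
                     widths = c(25, 30), amps = c(1, 0.8)),
    allometry = list(centers = rbind(c(0, -40, 60), c(55, -10, 40),
                                     c(-55, -10, 40)),
                     widths = c(65, 60, 60), amps = c(1, 0.6, 0.6),
                     ## dominant linear part: faces elongate and narrow
                     ## relative to the neurocranium as size increases —
                     ## a trace-free anisotropic scaling (pure shape, no
                     ## isotropic size component)
                     linear = diag(c(-0.35, 0.65, -0.30)),
                     linear_weight = 0.75))
  V <- mesh$vertices
  ## normalized to unit PEAK displacement over the template surface: a
  ## factor amplitude of 6 mm means the extreme groups differ by 6 mm at
  ## the feature's centre, not everywhere — group effects are localized
  ## while individual variation is surface-wide
  lapply(defs, function(d) {
    h <- numeric(nrow(V))
    for (j in seq_along(d$amps)) {
      d2 <- rowSums(sweep(V, 2, d$centers[j, ])^2)
      h <- h + d$amps[j] * exp(-d2 / (2 * d$widths[j]^2))
    }
    disp <- normals * (h / max(abs(h)))
    if (!is.null(d$linear)) {
      lin <- V %*% t(d$linear)
      lin <- lin / max(rowwise_norm(lin))
      disp <- d$linear_weight * lin + (1 - d$linear_weight) * disp
      disp <- disp / max(rowwise_norm(disp))
    }
    list(eval = function(pts) disp)
  })
}

## Random smooth individual-variation field: a low-frequency scalar
## radial-basis offset applied along the local surface normal (surface
## shape varies as a smooth heightfield; a tangential component would
## slide material points without changing the surface at all). Kernel
## centres are biased toward the anterior (facial) region, where real
## between-individual variation concentrates. Unit RMS over the template
## vertices; draws from the current RNG stream. Returns a displacement
## matrix for the template vertices themselves.
.random_smooth_field <- function(mesh, normals, nc = 14, width = 70) {
  cand <- sample_on_mesh(mesh, 4 * nc)
  u <- cand$points / rowwise_norm(cand$points)
  w <- 1 + 4 * pmax(u[, 3], 0)^2
  keep <- sample.int(nrow(cand$points), nc, prob = w)
  centers <- cand$points[keep, , drop = FALSE]
  amps <- stats::rnorm(nc)
  h <- numeric(nrow(mesh$vertices))
  for (j in seq_len(nc)) {
    d2 <- rowSums(sweep(mesh$vertices, 2, centers[j, ])^2)
    h <- h + amps[j] * exp(-d2 / (2 * width^2))
  }
  h <- h / sqrt(mean(h^2))
  normals * h
}

#' Specification of a synthetic study population
#'
#' Cell counts over the 2 ethnicity x 2 sex x 5 age-class design plus the
#' deformation amplitudes the generator injects. The default counts are
#' the study design's cell proportions scaled to a 120-specimen desk
#' total; `n_per_cell = "full"` uses the original 292-specimen counts.
#'
#' @param n_per_cell `"default"` (120 total), `"full"` (292), or a
#'   2 x 2 x 5 array of counts (ethnicity x sex x age).
#' @param ethnicity_amp,sex_amp,age_amp per-factor effect amplitudes in mm:
#'   the peak surface displacement between the extreme groups at the
#'   feature's centre (group effects are localized; away from the feature
#'   they taper off).
#' @param allometry_amp peak shape change in mm per standard deviation of
#'   log centroid size.
#' @param individual_sd individual smooth shape variation (mm RMS).
#' @param digitization_sd landmark digitization noise SD (mm per
#'   coordinate).
#' @param n_redigitized how many randomly chosen specimens get a second
#'   digitization (default 30).
#' @param size_sd SD of log size; `size_age_trend`, `size_sex_gap` small
#'   deterministic log-size offsets for age classes and males.
#' @param head_params base surface, see [make_head_params()].
#' @param seed RNG seed governing all generator randomness.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(n_per_cell = "default", ethnicity_amp = 3,
                            sex_amp = 6, age_amp = 3, allometry_amp = 0.8,
                            individual_sd = 1, digitization_sd = 0.1,
                            n_redigitized = 30, size_sd = 0.05,
                            size_age_trend = c(-0.06, -0.02, 0, 0.01, 0.015),
                            size_sex_gap = 0.03,
                            head_params = make_head_params(), seed = 1) {
  ## per age class: (british male, irish male, british female, irish female)
  if (identical(n_per_cell, "default")) {
    counts <- array(c(9, 0, 10, 0,   5, 0, 5, 1,   11, 2, 13, 3,
                      9, 6, 14, 5,   9, 2, 13, 3),
                    dim = c(2, 2, 5))
  } else if (identical(n_per_cell, "full")) {
    counts <- array(c(21, 1, 24, 1,   13, 0, 11, 3,   26, 6, 32, 7,
                      21, 14, 33, 12,   21, 6, 32, 8),
                    dim = c(2, 2, 5))
  } else counts <- n_per_cell
  dimnames(counts) <- list(ethnicity = c("white_british", "white_irish"),
                           sex = c("male", "female"),
                           age_class = AGE_CLASSES)
  stopifnot(all(counts >= 0), all(is.finite(counts)))
  if (sum(counts) == 0) stop("population_spec: empty design")
  stopifnot(individual_sd >= 0, digitization_sd >= 0, allometry_amp >= 0)
  structure(list(counts = counts, ethnicity_amp = ethnicity_amp,
                 sex_amp = sex_amp, age_amp = age_amp,
                 allometry_amp = allometry_amp,
                 individual_sd = individual_sd,
                 digitization_sd = digitization_sd,
                 n_redigitized = as.integer(n_redigitized),
                 size_sd = size_sd, size_age_trend = size_age_trend,
                 size_sex_gap = size_sex_gap, head_params = head_params,
                 seed = seed),
            class = "population_spec")
}

#' Sample a synthetic study population
#'
#' Per specimen, the template head is deformed by its cell's fixed effect
#' fields (ethnicity, sex, age), a random smooth individual field, and an
#' allometric field coupled to log size; the result is scaled by the
#' specimen's size factor. Anchors (and, when a template with
#' semi-landmarks is given, the ground-truth semi-landmarks) are carried
#' through the deformation by their barycentric coordinates, so they lie
#' exactly on the deformed mesh. Digitized anchors add fresh Gaussian
#' digitization noise per digitization event; `n_redigitized` randomly
#' chosen specimens are digitized twice.
#'
#' @param spec a [population_spec()].
#' @param template optional `template_model` built on the spec's base
#'   mesh; its semi-landmarks are then carried as ground truth.
#' @return a list of class `synthetic_population`: `meta` (one row per
#'   digitization record: id, ethnicity, sex, age_class, replicate_of,
#'   size), `meshes` (one per individual), `anchors` (digitized
#'   [landmark_configuration()] per record), `true_landmarks` (per
#'   individual, anchors + semi-landmarks when a template was supplied),
#'   `truth` (per-individual effect codes and realized components).
#' @export
sample_population <- function(spec, template = NULL) {
  base <- make_head_mesh(spec$head_params)
  mesh0 <- base$mesh
  if (!is.null(template) &&
      !isTRUE(all.equal(template$mesh$vertices, mesh0$vertices)))
    stop("sample_population: template mesh does not match the spec's base ",
         "head")
  ## landmark carriers: triangle + barycentric weights on the base mesh
  carrier_tri <- base$anchor_bary$triangle
  carrier_w <- base$anchor_bary$weights
  n_semi <- 0L
  if (!is.null(template)) {
    n_semi <- template$landmarks$semilandmark_count
    semi_tri <- template$triangles[template$landmarks$anchor_count +
                                     seq_len(n_semi)]
    semis <- semilandmark_points(template$landmarks)
    semi_w <- matrix(NA_real_, n_semi, 3)
    for (i in seq_len(n_semi)) {
      tri <- mesh0$triangles[semi_tri[i], ]
      semi_w[i, ] <- barycentric_coords(semis[i, ],
                                        mesh0$vertices[tri[1], ],
                                        mesh0$vertices[tri[2], ],
                                        mesh0$vertices[tri[3], ])
    }
    carrier_tri <- c(carrier_tri, semi_tri)
    carrier_w <- rbind(carrier_w, semi_w)
  }
  carry <- function(V) {
    tri <- mesh0$triangles[carrier_tri, , drop = FALSE]
    carrier_w[, 1] * V[tri[, 1], , drop = FALSE] +
      carrier_w[, 2] * V[tri[, 2], , drop = FALSE] +
      carrier_w[, 3] * V[tri[, 3], , drop = FALSE]
  }
  normals0 <- vertex_normals(mesh0)
  fields <- .effect_fields(mesh0, normals0)
  cells <- expand.grid(ethnicity = dimnames(spec$counts)[[1]],
                       sex = dimnames(spec$counts)[[2]],
                       age_class = dimnames(spec$counts)[[3]],
                       stringsAsFactors = FALSE)
  cells$n <- as.numeric(spec$counts)  # expand.grid order matches array order
  meta <- cells[rep(seq_len(nrow(cells)), cells$n),
                c("ethnicity", "sex", "age_class")]
  N <- nrow(meta)
  meta$id <- sprintf("S%03d", seq_len(N))
  rownames(meta) <- NULL

  eth_code <- ifelse(meta$ethnicity == "white_irish", 0.5, -0.5)
  sex_code <- ifelse(meta$sex == "male", 0.5, -0.5)
  age_code <- seq(-0.5, 0.5, length.out = 5)[match(meta$age_class,
                                                   AGE_CLASSES)]

  out <- with_seed(spec$seed, {
    log_s <- spec$size_age_trend[match(meta$age_class, AGE_CLASSES)] +
      spec$size_sex_gap * (meta$sex == "male") +
      stats::rnorm(N, 0, spec$size_sd)
    z <- as.numeric(scale(log_s))
    meshes <- vector("list", N); names(meshes) <- meta$id
    anchors <- list(); true_lm <- vector("list", N)
    names(true_lm) <- meta$id
    comp <- vector("list", N)
    V0 <- mesh0$vertices
    for (i in seq_len(N)) {
      ind_disp <- .random_smooth_field(mesh0, normals0)
      disp <- eth_code[i] * spec$ethnicity_amp * fields$ethnicity$eval(V0) +
        sex_code[i] * spec$sex_amp * fields$sex$eval(V0) +
        age_code[i] * spec$age_amp * fields$age_class$eval(V0) +
        z[i] * spec$allometry_amp * fields$allometry$eval(V0) +
        spec$individual_sd * ind_disp
      s <- exp(log_s[i])
      Vi <- (V0 + disp) * s
      meshes[[i]] <- surface_mesh(Vi, mesh0$triangles, name = meta$id[i])
      tl <- carry(Vi)
      true_lm[[i]] <- landmark_configuration(tl, base$anchors$anchor_count,
                                             labels = base$anchors$labels)
      dig <- tl[seq_len(base$anchors$anchor_count), , drop = FALSE] +
        matrix(stats::rnorm(3 * base$anchors$anchor_count, 0,
                            spec$digitization_sd),
               ncol = 3)
      anchors[[meta$id[i]]] <-
        landmark_configuration(dig, base$anchors$anchor_count,
                               labels = base$anchors$labels)
      comp[[i]] <- list(z = z[i], size = s)
    }
    ## second digitizations of randomly chosen specimens
    n_re <- min(spec$n_redigitized, N)
    re_ids <- if (n_re > 0) sample(meta$id, n_re) else character(0)
    meta_rep <- NULL
    for (rid in re_ids) {
      tl <- true_lm[[rid]]$points[seq_len(base$anchors$anchor_count), ,
                                  drop = FALSE]
      dig <- tl + matrix(stats::rnorm(3 * base$anchors$anchor_count, 0,
                                      spec$digitization_sd), ncol = 3)
      new_id <- paste0(rid, "r")
      anchors[[new_id]] <-
        landmark_configuration(dig, base$anchors$anchor_count,
                               labels = base$anchors$labels)
      row <- meta[meta$id == rid, ]
      row$id <- new_id
      meta_rep <- rbind(meta_rep, row)
    }
    meta$replicate_of <- NA_character_
    if (!is.null(meta_rep)) {
      meta_rep$replicate_of <- sub("r$", "", meta_rep$id)
      meta <- rbind(meta, meta_rep)
    }
    meta$size <- exp(log_s)[match(ifelse(is.na(meta$replicate_of),
                                         meta$id, meta$replicate_of),
                                  names(meshes))]
    list(meta = meta, meshes = meshes, anchors = anchors,
         true_landmarks = true_lm,
         truth = data.frame(id = names(meshes), eth_code = eth_code,
                            sex_code = sex_code, age_code = age_code,
                            z = z, size = exp(log_s)))
  })
  out$spec <- spec
  out$base <- base
  class(out) <- "synthetic_population"
  out
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("<synthetic_population> ", length(x$meshes), " individuals, ",
      nrow(x$meta) - length(x$meshes), " re-digitizations\n", sep = "")
  invisible(x)
}

#' Ground-truth tables for a synthetic population
#'
#' Per-specimen injected effect codes and sizes, plus the allometric
#' percentage of shape variation computed by construction: the true
#' landmark configurations (no digitization noise, no warping, no
#' superimposition — the generator applies no rotations) are centered,
#' scaled to unit centroid size, and regressed on centroid size.
#'
#' @param population a [sample_population()] result.
#' @return list with `specimens` (truth table, one row per individual)
#'   and `allometry_percent`.
#' @export
ground_truth <- function(population) {
  tl <- population$true_landmarks
  cs <- vapply(tl, function(l) centroid_size(l$points), 0)
  Y <- t(vapply(tl, function(l) {
    x <- scale(l$points, scale = FALSE)
    as.numeric(x / sqrt(sum(x^2)))
  }, numeric(3 * nrow(tl[[1]]$points))))
  Yc <- sweep(Y, 2, colMeans(Y))
  xc <- cs - mean(cs)
  pred <- outer(xc, as.numeric(crossprod(Yc, xc) / sum(xc^2)))
  list(specimens = population$truth,
       allometry_percent = 100 * sum(pred^2) / sum(Yc^2))
}
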