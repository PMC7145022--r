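## Shared fixtures, built in code. Heavy objects (the base head, a mid-size
## template) are cached for the session so several test files can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

base_head <- function() cached("base_head", function() make_head_mesh())

## 120-point template: large enough for sliding to be non-trivial, small
## enough that the bending-energy systems solve in milliseconds
mid_template <- function() cached("mid_template", function() {
  b <- base_head()
  generate_template_semilandmarks(b$mesh, b$anchors, n = 120, seed = 7)
})

make_tetrahedron <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
               name = "tetra")
}

make_cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),  # z = 0
             c(5, 6, 7), c(6, 8, 7),  # z = side
             c(1, 2, 5), c(2, 6, 5),  # y = 0
             c(3, 7, 4), c(4, 7, 8),  # y = side
             c(1, 5, 3), c(3, 5, 7),  # x = 0
             c(2, 4, 6), c(4, 8, 6))  # x = side
  surface_mesh(v, f, name = "cube")
}

## random non-degenerate tetrahedron-topology mesh for round-trip checks
random_tetra_mesh <- function() {
  repeat {
    v <- matrix(stats::runif(12, -50, 50), 4, 3)
    m <- tryCatch(surface_mesh(v, rbind(c(1, 2, 3), c(1, 2, 4),
                                        c(1, 3, 4), c(2, 3, 4))),
                  error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
}

random_config <- function(K, scale = 10) matrix(stats::rnorm(K * 3, sd = scale), K, 3)

## rigid rotation matrix from three angles
rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

## Independent closest-point oracle: per triangle, evaluate the seven
## candidate minimizers (interior stationary point, three clamped edges,
## three vertices) and take the best over all triangles. Deliberately a
## different algorithm from the region-test implementation under test.
closest_point_oracle <- function(p, mesh) {
  best <- Inf; bp <- NULL
  v <- mesh$vertices; f <- mesh$triangles
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
    e1 <- b - a; e2 <- cc - a
    G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
    st <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
    cand <- list()
    if (all(st >= 0) && sum(st) <= 1)
      cand <- c(cand, list(a + st[1] * e1 + st[2] * e2))
    seg <- function(p0, p1) {
      tt <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
      p0 + max(0, min(1, tt)) * (p1 - p0)
    }
    cand <- c(cand, list(seg(a, b), seg(a, cc), seg(b, cc),
                         a, b, cc))
    for (q in cand) {
      d <- sqrt(sum((p - q)^2))
      if (d < best) { best <- d; bp <- q }
    }
  }
  list(point = bp, distance = best)
}

## small crossed-design population spec for statistics tests
small_pop_spec <- function(seed = 11, n_redigitized = 8, ...) {
  spec <- population_spec(seed = seed, n_redigitized = n_redigitized, ...)
  spec$counts[] <- 1
  spec$counts[1, 1, ] <- 2
  spec$counts[2, 2, ] <- 2
  spec
}

## landmark-only population: true configurations + digitized replicates,
## skipping the mesh warp (fast path for ANOVA calibration tests)
landmark_population <- function(spec, template = NULL) {
  pop <- sample_population(spec, template = template)
  meta <- pop$meta
  ind <- ifelse(is.na(meta$replicate_of), meta$id, meta$replicate_of)
  arr <- aperm(simplify2array(lapply(seq_len(nrow(meta)), function(i) {
    x <- pop$true_landmarks[[ind[i]]]$points
    x[seq_len(20), ] <- pop$anchors[[meta$id[i]]]$points
    x
  })), c(3, 1, 2))
  list(configs = arr, meta = meta, population = pop)
}
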