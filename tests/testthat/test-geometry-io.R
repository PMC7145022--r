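test_that("mesh round-trips through OBJ and PLY preserve coordinates", {
  tet <- make_tetrahedron()
  for (ext in c("obj", "ply")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(tet, path)
    back <- suppressMessages(read_mesh(path))
    expect_equal(back$vertices, tet$vertices, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(back$triangles, tet$triangles, ignore_attr = TRUE)
  }
  ## property: random meshes round-trip to < 1e-6 mm in both formats
  set.seed(41)
  for (i in 1:40) {
    m <- random_tetra_mesh()
    ext <- if (i %% 2) "obj" else "ply"
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    back <- suppressMessages(read_mesh(path))
    expect_lt(max(abs(back$vertices - m$vertices)), 1e-6)
  }
})

test_that("PLY and OBJ encodings of the same cube read back equal", {
  cube <- make_cube_mesh(side = 12.5)
  p1 <- withr::local_tempfile(fileext = ".obj")
  p2 <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cube, p1)
  write_mesh(cube, p2)
  m1 <- suppressMessages(read_mesh(p1))
  m2 <- suppressMessages(read_mesh(p2))
  expect_equal(m1$vertices, m2$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(m1$triangles, m2$triangles, ignore_attr = TRUE)
})

test_that("binary little-endian PLY reads back the written ASCII geometry", {
  ## craft a small binary PLY by hand and check the reader
  tet <- make_tetrahedron()
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header"),
             con)
  for (i in 1:4) writeBin(as.numeric(tet$vertices[i, ]), con, size = 4,
                          endian = "little")
  for (i in 1:4) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(tet$triangles[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  back <- suppressMessages(read_mesh(path))
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$triangles, tet$triangles, ignore_attr = TRUE)
})

test_that("mesh validation rejects bad geometry", {
  tet <- make_tetrahedron()
  expect_error(surface_mesh(tet$vertices, rbind(c(1, 2, 9))),
               "index out of range")
  expect_error(surface_mesh(tet$vertices[0, ], tet$triangles), "vertex")
  expect_error(surface_mesh(tet$vertices, tet$triangles[0, ]),
               "no triangles")
  v <- tet$vertices; v[2, 1] <- NaN
  expect_error(surface_mesh(v, tet$triangles), "non-finite")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(1, 2, 3))), "degenerate")
  ## OBJ face referencing a vertex beyond the vertex count
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 5"), path)
  expect_error(suppressMessages(read_mesh(path)), "out of range")
  ## malformed vertex line gets a line number
  writeLines(c("v 0 0 zap", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  expect_error(suppressMessages(read_mesh(path)), "line 1")
})

test_that("landmark CSV round-trips and validates", {
  labels <- c("enl", "exl", "exr", "enr", "me", "g", "n", "pr", "all",
              "alr", "chl", "chr", "ls", "li", "pg", "gn", "tl", "tr",
              "op", "ve")
  set.seed(5)
  cfg <- landmark_configuration(random_config(20, scale = 80), 20,
                                labels = labels)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(cfg, path)
  back <- read_landmarks(path, anchor_count = 20)
  expect_equal(back$anchor_count, 20L)
  expect_equal(back$semilandmark_count, 0L)
  expect_identical(back$labels, labels)
  expect_lt(max(abs(back$points - cfg$points)), 1e-6)

  ## with a semi-landmark block: generated labels s0001...
  cfg2 <- landmark_configuration(random_config(25), 20, labels = labels)
  expect_identical(rownames(cfg2$points)[21], "s0001")
  write_landmarks(cfg2, path)
  back2 <- read_landmarks(path, anchor_count = 20)
  expect_equal(back2$semilandmark_count, 5L)
  expect_lt(max(abs(back2$points - cfg2$points)), 1e-6)

  ## property: random round trips
  set.seed(6)
  for (i in 1:25) {
    k <- sample(5:40, 1)
    cf <- landmark_configuration(random_config(k), k)
    write_landmarks(cf, path)
    expect_lt(max(abs(read_landmarks(path, k)$points - cf$points)), 1e-6)
  }

  ## failure modes
  writeLines("label,x,y,z", path)
  expect_error(read_landmarks(path, 1), "no landmark rows")
  writeLines(c("label,x,y,z", "a,1,2,3", "b,1,oops,3"), path)
  expect_error(read_landmarks(path, 2), "row 2")
  writeLines(c("label,x,y,z", "a,1,2,3"), path)
  expect_error(read_landmarks(path, 5), "anchor_count")
})

test_that("metadata table validates age classes and replicate links", {
  meta <- data.frame(id = c("a", "b", "b2"),
                     ethnicity = "white_british", sex = "male",
                     age_class = c("<13", "20-29", "20-29"),
                     replicate_of = c(NA, NA, "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(back$replicate_of, c(NA, NA, "b"))
  meta$age_class[1] <- "ancient"
  write_metadata(meta, path)
  expect_error(read_metadata(path), "age class")
  meta$age_class[1] <- "<13"; meta$replicate_of[3] <- "zz"
  write_metadata(meta, path)
  expect_error(read_metadata(path), "unknown id")
})
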