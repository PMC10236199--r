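test_that("STL read/write round-trips and deduplicates cube vertices", {
  cube <- box_surface(c(0, 0, 0), c(1, 1, 1))
  expect_true(cube$watertight)

  for (binary in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_surface(cube, f, binary = binary)
    got <- read_surface(f, region_tag = "cube")
    # STL stores per-facet vertices; the reader must merge them back to 8
    expect_equal(nrow(got$vertices), 8L)
    expect_equal(nrow(got$triangles), 12L)
    expect_true(got$watertight)
    # same vertex set (order may differ)
    expect_equal(
      got$vertices[order(got$vertices[, 1], got$vertices[, 2],
                         got$vertices[, 3]), ],
      cube$vertices[order(cube$vertices[, 1], cube$vertices[, 2],
                          cube$vertices[, 3]), ],
      tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("STL round trip preserves an arbitrary surface exactly", {
  ph <- make_phantom(phantom_spec(surface_segments = 16L))
  skin <- ph$surfaces$skin
  f <- withr::local_tempfile(fileext = ".stl")
  write_surface(skin, f)
  got <- read_surface(f, region_tag = "skin")
  expect_equal(nrow(got$vertices), nrow(skin$vertices))
  expect_equal(nrow(got$triangles), nrow(skin$triangles))
  # winding preserved: matched triangles keep their cyclic orientation
  # (binary STL stores float32, so match by nearest vertex, not exactly)
  ix <- vapply(seq_len(nrow(got$vertices)), function(i) {
    d2 <- colSums((t(skin$vertices) - got$vertices[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > 1e-6) NA_integer_ else j
  }, integer(1))
  expect_false(anyNA(ix))
  remap <- matrix(ix[got$triangles], ncol = 3)
  canon <- function(tr) {
    s <- which.min(tr)
    paste(tr[((s - 1 + 0:2) %% 3) + 1], collapse = "-")
  }
  expect_setequal(apply(remap, 1, canon), apply(skin$triangles, 1, canon))
})

test_that("non-watertight STL reads with a warning flag, empty file errors", {
  cube <- box_surface(c(0, 0, 0), c(1, 1, 1))
  holed <- surface_mesh(cube$vertices, cube$triangles[-1, , drop = FALSE],
                        clean = FALSE)
  f <- withr::local_tempfile(fileext = ".stl")
  write_surface(holed, f)
  expect_warning(got <- read_surface(f), "watertight")
  expect_false(got$watertight)

  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines("", bad)
  expect_error(read_surface(bad))
  expect_error(read_surface("no/such/file.stl"), "not found")
})

minimal_deck <- c(
  "$ minimal single-hex deck",
  "*KEYWORD",
  "*NODE",
  sprintf("%8d%16.6f%16.6f%16.6f", 1:8,
          unit_hex_points[, 1] * 10, unit_hex_points[, 2] * 10,
          unit_hex_points[, 3] * 10),
  "*ELEMENT_SOLID",
  sprintf("%8d%8d%s", 1L, 1L, paste(sprintf("%8d", 1:8), collapse = "")),
  "*END")

test_that("LS-DYNA keyword reader parses fixed-width and comma decks", {
  f <- withr::local_tempfile(fileext = ".k")
  writeLines(minimal_deck, f)
  mesh <- read_fe_mesh(f)
  expect_equal(length(mesh$node_ids), 8L)
  expect_equal(nrow(mesh$solids), 1L)
  expect_equal(unname(mesh$solids[1, 2]), 1)  # part ID preserved
  expect_equal(mesh$nodes[2, ], c(10, 0, 0), ignore_attr = TRUE)

  # comma-separated equivalent
  fc <- withr::local_tempfile(fileext = ".k")
  writeLines(c("*KEYWORD", "*NODE",
               sprintf("%d,%g,%g,%g", 1:8, unit_hex_points[, 1],
                       unit_hex_points[, 2], unit_hex_points[, 3]),
               "*ELEMENT_SOLID",
               paste(c(1, 1, 1:8), collapse = ","), "*END"), fc)
  mc <- read_fe_mesh(fc)
  expect_equal(length(mc$node_ids), 8L)
  expect_equal(unname(mc$solids[1, 3:10]), 1:8)
})

test_that("LS-DYNA writer round-trips nodes, elements, parts and contacts", {
  ph <- make_phantom(phantom_spec(mesh_resolution = 12))
  mesh <- ph$mesh
  f <- withr::local_tempfile(fileext = ".k")
  write_fe_mesh(mesh, f)
  got <- read_fe_mesh(f)
  expect_identical(got$node_ids, mesh$node_ids)
  expect_equal(got$nodes, mesh$nodes, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(got$solids), unname(mesh$solids))
  expect_equal(got$parts$pid, mesh$parts$pid)
  expect_equal(unname(got$contact_pairs), unname(mesh$contact_pairs))
})

test_that("LS-DYNA reader flags missing nodes and passes unknown cards through", {
  bad <- c("*KEYWORD", "*NODE",
           sprintf("%8d%16.6f%16.6f%16.6f", 1:4, 1:4, 1:4, 1:4),
           "*ELEMENT_SHELL",
           sprintf("%8d%8d%8d%8d%8d%8d", 1L, 1L, 1L, 2L, 3L, 99L),
           "*END")
  f <- withr::local_tempfile(fileext = ".k")
  writeLines(bad, f)
  expect_error(read_fe_mesh(f), "99")

  ok <- c("*KEYWORD", "*SECTION_SOLID", "       1       1", "*NODE",
          sprintf("%8d%16.6f%16.6f%16.6f", 1:4,
                  c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0)),
          "*ELEMENT_SHELL",
          sprintf("%8d%8d%8d%8d%8d%8d", 7L, 3L, 1L, 2L, 3L, 4L),
          "*END")
  f2 <- withr::local_tempfile(fileext = ".k")
  writeLines(ok, f2)
  m2 <- read_fe_mesh(f2)
  expect_true(any(grepl("SECTION_SOLID", m2$extra_cards)))
  f3 <- withr::local_tempfile(fileext = ".k")
  write_fe_mesh(m2, f3)
  expect_true(any(grepl("SECTION_SOLID", readLines(f3))))
  m3 <- read_fe_mesh(f3)
  expect_identical(unname(m3$shells), unname(m2$shells))
})

test_that("tetrahedra survive the keyword round trip in repeated-node form", {
  tet <- fe_mesh(node_ids = 1:4,
                 nodes = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(0, 0, 1)),
                 solids = matrix(c(5L, 2L, 1L, 2L, 3L, 4L, 4L, 4L, 4L, 4L),
                                 nrow = 1))
  f <- withr::local_tempfile(fileext = ".k")
  write_fe_mesh(tet, f)
  got <- read_fe_mesh(f)
  expect_identical(unname(got$solids), unname(tet$solids))
  expect_equal(morphforge:::solid_nn(got$solids), 4L)
})

test_that("legacy VTK unstructured grid round-trips geometry and part ids", {
  ph <- make_phantom(phantom_spec(mesh_resolution = 12))
  mesh <- ph$mesh
  f <- withr::local_tempfile(fileext = ".vtk")
  write_fe_mesh(mesh, f, dialect = "vtk")
  got <- read_fe_mesh(f, dialect = "vtk")
  expect_equal(length(got$node_ids), length(mesh$node_ids))
  expect_equal(nrow(got$solids), nrow(mesh$solids))
  # geometry identical under the row-index renumbering
  a <- got$nodes[morphforge:::node_index(got, got$solids[1, 3:10]), ]
  b <- mesh$nodes[morphforge:::node_index(mesh, mesh$solids[1, 3:10]), ]
  expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(got$solids[, 2]), unname(mesh$solids[, 2]))
  expect_equal(unname(got$solids[, 1]), unname(mesh$solids[, 1]))
})

test_that("image round trips preserve voxels and metadata exactly", {
  arr <- array(0L, dim = c(4, 4, 4))
  arr[2, 3, 1] <- 1L; arr[1, 1, 4] <- 2L
  img <- label_image(arr, spacing = c(2, 2, 2), origin = c(10, -5, 2))
  for (ext in c(".mha", ".nii.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_image(img, f)
    got <- read_image(f)
    expect_s3_class(got, "label_image")
    expect_equal(unname(got$data), unname(img$data), ignore_attr = TRUE)
    expect_identical(got$spacing, img$spacing)
    expect_identical(got$origin, img$origin)
  }
})

test_that("vector field round trips exactly in both formats", {
  u <- constant_field(c(5L, 4L, 3L), c(1, 1.5, 2), c(0, 1, -2), c(1, 2, 3))
  u$data[2, 2, 2, ] <- c(-0.25, 0.5, 4.75)
  for (ext in c(".mha", ".nii")) {
    f <- withr::local_tempfile(fileext = ext)
    write_image(u, f)
    got <- read_image(f)
    expect_s3_class(got, "displacement_field")
    expect_equal(got$data, u$data, tolerance = 1e-12)
    expect_identical(got$spacing, u$spacing)
    expect_identical(got$origin, u$origin)
  }
})

test_that("grid mismatch between image and field is rejected", {
  img <- label_image(array(0L, dim = c(4, 4, 4)), spacing = c(1, 2, 1))
  u <- constant_field(c(4L, 4L, 4L), c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  expect_error(warp_image(img, u), "grid mismatch")
})
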