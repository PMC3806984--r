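test_that("default parameters satisfy their invariants and are deterministic", {
  p <- ear_params()
  expect_equal(p$n_cochlear_springs, 42L)
  expect_lt(p$umbo_radius, p$tm_radius)
  expect_lt(p$mesh_size, p$tm_radius / 4)
  expect_true(p$flaccida_sector_deg > 0 && p$flaccida_sector_deg < 90)
  expect_identical(ear_params(), ear_params())
  expect_error(ear_params(not_a_field = 1), "unknown")
  expect_error(ear_params(tm_radius = -1), "positive")
  expect_error(ear_params(umbo_radius = 10), "umbo_radius")
  expect_error(ear_params(flaccida_sector_deg = 95), "flaccida")
})

test_that("mesh carries the full connector complement and tagged sets", {
  mesh <- default_mesh()
  cochlear <- mesh$connectors[mesh$connectors$kind == "spring_damper", ]
  expect_equal(nrow(cochlear), 42L)
  expect_equal(sum(cochlear$k), 70, tolerance = 1e-12)
  expect_equal(sum(cochlear$c), 0.054, tolerance = 1e-12)
  expect_gt(length(mesh$tags$annulus_boundary), 0)
  expect_gt(length(mesh$tags$umbo_region), 0)
  apex <- mesh$nodes[otomech:::apex_node(mesh, mesh$params), ]
  d <- sqrt(rowSums((mesh$nodes[mesh$tags$umbo_region, , drop = FALSE] -
                       matrix(apex, length(mesh$tags$umbo_region), 3,
                              byrow = TRUE))^2))
  expect_true(all(d <= mesh$params$umbo_radius + 1e-9))
  # unit direction vectors
  nrm <- with(mesh$connectors, sqrt(dir_x^2 + dir_y^2 + dir_z^2))
  expect_equal(nrm, rep(1, nrow(mesh$connectors)), tolerance = 1e-12)
})

test_that("mesh elements are non-degenerate and refine as expected", {
  mesh <- build_ear_mesh(coarse_params())
  expect_true(all(otomech:::tet_volumes(mesh$nodes, mesh$solid) > 1e-9))
  expect_true(all(otomech:::tri_areas(mesh$nodes, mesh$shell) > 1e-6))
  fine <- build_ear_mesh(ear_params(mesh_size = 0.5))
  ratio <- nrow(fine$shell) / nrow(mesh$shell)
  expect_gte(ratio, 3)
  expect_lte(ratio, 6)
  expect_error(build_ear_mesh(ear_params(flaccida_sector_deg = 1)),
               "coarse")
})

test_that("the conduction path is topologically connected", {
  mesh <- default_mesh()
  nodes_of <- function(region) {
    sh <- mesh$shell[mesh$shell$region == region, c("n1", "n2", "n3")]
    so <- mesh$solid[mesh$solid$region == region, c("n1", "n2", "n3", "n4")]
    unique(c(unlist(sh), unlist(so)))
  }
  path <- c("tympanic_membrane_tensa", "manubrium", "malleus_handle",
            "malleus_neck", "malleus_head", "incudomalleolar_joint",
            "incus_body", "incus_short_process", "incus_long_process",
            "incudostapedial_joint", "stapes")
  for (i in seq_len(length(path) - 1)) {
    shared <- intersect(nodes_of(path[i]), nodes_of(path[i + 1]))
    expect_gt(length(shared), 0,
              label = paste(path[i], "->", path[i + 1], "shared nodes"))
  }
  # the footplate facet set belongs to the stapes
  expect_true(all(mesh$tags$footplate %in% nodes_of("stapes")))
})

test_that("every structural registry region is present in the default model", {
  mesh <- default_mesh()
  reg <- material_registry()
  present <- c(unique(mesh$shell$region), unique(mesh$solid$region),
               unique(mesh$connectors$region))
  expect_true(all(reg$region %in% present))
})

test_that("ossicle masses land at literature-typical values in order", {
  masses <- region_masses(default_mesh())
  m <- function(rs) sum(masses$mass_mg[masses$region %in% rs])
  stapes <- m("stapes")
  malleus <- m(c("malleus_head", "malleus_neck", "malleus_handle"))
  incus <- m(c("incus_body", "incus_short_process", "incus_long_process"))
  expect_equal(stapes, 3, tolerance = 0.15)
  expect_gt(malleus, 20); expect_lt(malleus, 35)
  expect_gt(incus, 20); expect_lt(incus, 40)
  expect_true(incus > malleus && malleus > stapes)
})

test_that("geometry config files round-trip through YAML and JSON", {
  p <- ear_params(mesh_size = 0.8, tm_tension = 99)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_ear_config(p, path)
    back <- read_ear_config(path)
    expect_equal(back$mesh_size, 0.8)
    expect_equal(back$tm_tension, 99)
    expect_equal(back$ossicle_dims, p$ossicle_dims)
    expect_equal(as.data.frame(back$ligaments), as.data.frame(p$ligaments),
                 tolerance = 1e-9)
  }
})

test_that("VTK export round-trips and parses independently", {
  mesh <- build_ear_mesh(coarse_params())
  path <- tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path)
  back <- read_mesh_vtk(path)
  expect_equal(nrow(back$nodes), nrow(mesh$nodes))
  expect_identical(back$shell$n1, as.integer(mesh$shell$n1))
  expect_identical(back$solid$n4, as.integer(mesh$solid$n4))
  expect_identical(back$shell$region, mesh$shell$region)
  expect_identical(back$solid$region, mesh$solid$region)
  expect_equal(back$shell$thickness_mm, mesh$shell$thickness_mm)

  # independent minimal parser (separate code path from read_mesh_vtk):
  # walk the declared section counts directly
  lines <- readLines(path)
  expect_match(lines[1], "^# vtk DataFile")
  expect_equal(lines[3], "ASCII")
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  npts <- as.integer(strsplit(lines[grep("^POINTS", lines)], " ")[[1]][2])
  expect_equal(npts, nrow(mesh$nodes))
  ctypes_at <- grep("^CELL_TYPES", lines)
  ncell <- as.integer(strsplit(lines[ctypes_at], " ")[[1]][2])
  types <- as.integer(lines[ctypes_at + seq_len(ncell)])
  expect_equal(sum(types == 5), nrow(mesh$shell))
  expect_equal(sum(types == 10), nrow(mesh$solid))
  # every connectivity index is a valid 0-based node reference
  cells_at <- grep("^CELLS", lines)
  conn <- lapply(lines[cells_at + seq_len(ncell)], function(l)
    as.integer(strsplit(l, " ")[[1]]))
  expect_true(all(vapply(conn, function(x) all(x[-1] >= 0 & x[-1] < npts),
                         logical(1))))
  expect_error(write_mesh_vtk(mesh, file.path(tempdir(), "no/such/dir/x.vtk")),
               "cannot open")
})
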