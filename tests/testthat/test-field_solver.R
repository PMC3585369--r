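test_that("pad discretization conserves current and splits it evenly", {
  lay <- standard_electrode_positions("10-10", 0.092)
  cfg1 <- stimulation_config(sources_per_pad = 1L)
  s1 <- pad_sources(cfg1, lay, 0.092)
  expect_equal(nrow(s1$positions), 2L)
  expect_equal(sort(s1$currents), sort(c(1.12e-3, -1.12e-3)))
  cfg15 <- stimulation_config(current = 1.12e-3, sources_per_pad = 15L)
  s15 <- pad_sources(cfg15, lay, 0.092)
  expect_equal(unique(s15$currents[s15$currents > 0]), 1.12e-3 / 15)
  expect_equal(sum(s15$currents), 0, tolerance = 1e-15)
  expect_lt(max(abs(sqrt(rowSums(s15$positions^2)) - 0.092)), 1e-12)
  s35 <- pad_sources(stimulation_config(), lay, 0.092)
  expect_equal(sum(s35$currents), 0, tolerance = 1e-15)
  expect_error(pad_sources(stimulation_config(anode = "XX"), lay), "unknown")
})

test_that("multishell potential matches closed form and obeys linearity", {
  sh <- shell_model(0.09, 0.4)
  src <- structure(list(positions = matrix(c(0, 0, 0.09), 1),
                        currents = 1e-3), class = "point_source_set")
  set.seed(1)
  pts <- matrix(rnorm(30), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(10, 0.02, 0.07)
  phi <- potential_multishell(sh, src, pts, n_terms = 200)
  # closed form for a surface point source on a homogeneous sphere:
  # phi = I/(4 pi sigma R) sum_n (2n+1)/n (r/R)^n P_n(cos gamma)
  closed <- vapply(seq_len(nrow(pts)), function(i) {
    r <- sqrt(sum(pts[i, ]^2)); u <- pts[i, 3] / r; s <- r / 0.09
    leg <- tacsim:::legendre_p(200, u)
    sum((2 * (1:200) + 1) / (1:200) * s^(1:200) * leg$P[-1, 1]) *
      1e-3 / (4 * pi * 0.4 * 0.09)
  }, numeric(1))
  expect_equal(phi, closed - mean(closed), tolerance = 1e-10)
  # zero currents give zero potential
  src0 <- src; src0$currents <- 0
  expect_equal(potential_multishell(sh, src0, pts, 50), rep(0, 10))
  # exact linearity in the injected current
  src2 <- src; src2$currents <- 2e-3
  expect_equal(potential_multishell(sh, src2, pts, 200), 2 * phi)
  expect_error(potential_multishell(sh, src, matrix(c(0, 0, 0.1), 1)),
               "outside head")
})

test_that("series potential agrees with the finite-volume Laplace oracle", {
  skip_if_not_installed("Matrix")
  radii <- c(0.06, 0.09)
  src <- structure(list(positions = rbind(c(0, 0, 0.09), c(0, 0, -0.09)),
                        currents = c(1e-3, -1e-3)),
                   class = "point_source_set")
  for (sig in list(c(0.4, 0.4), c(0.33, 0.01))) {
    fv <- fv_laplace_axisym(radii, sig, n_r = 90, n_th = 160,
                            boundary_sources = data.frame(
                              theta = c(0, pi), I = c(1e-3, -1e-3)))
    sel_r <- which(fv$r > 0.01 & fv$r < 0.055)
    sel_t <- which(fv$theta > 0.3 & fv$theta < pi - 0.3)
    pts <- as.matrix(expand.grid(r = fv$r[sel_r], th = fv$theta[sel_t]))
    xyz <- cbind(pts[, 1] * sin(pts[, 2]), 0, pts[, 1] * cos(pts[, 2]))
    ps <- suppressWarnings(
      potential_multishell(shell_model(radii, sig), src, xyz, n_terms = 300))
    pf <- mapply(function(r, th) fv$lookup(r, th), pts[, 1], pts[, 2])
    ps <- ps - mean(ps); pf <- pf - mean(pf)
    expect_lt(max(abs(ps - pf)) / max(abs(pf)), 0.01)
  }
})

test_that("analytic field matches the numerical potential gradient", {
  sh3 <- default_eeg_shells()
  lay <- standard_electrode_positions("10-10")
  srcs <- pad_sources(stimulation_config(), lay)
  set.seed(2)
  p0 <- matrix(rnorm(30), ncol = 3)
  p0 <- p0 / sqrt(rowSums(p0^2)) * runif(10, 0.03, 0.075)
  E <- efield_at(sh3, srcs, p0, n_terms = 150)$E
  h <- 1e-6
  for (d in 1:3) {
    pp <- p0; pp[, d] <- pp[, d] + h
    pm <- p0; pm[, d] <- pm[, d] - h
    gnum <- -(potential_multishell(sh3, srcs, pp, 150, demean = FALSE) -
                potential_multishell(sh3, srcs, pm, 150, demean = FALSE)) /
      (2 * h)
    expect_lt(max(abs(gnum - E[, d])) / max(abs(E)), 1e-3)
  }
  # zero currents -> zero field
  s0 <- srcs; s0$currents <- srcs$currents * 0
  expect_equal(efield_at(sh3, s0, p0, 50)$E, matrix(0, 10, 3))
})

test_that("antipodal sources give an axis-aligned central field", {
  sh <- shell_model(0.09, 0.4)
  src <- structure(list(positions = rbind(c(0, 0, 0.09), c(0, 0, -0.09)),
                        currents = c(1e-3, -1e-3)),
                   class = "point_source_set")
  E <- efield_at(sh, src, matrix(c(1e-4, 1e-4, 1e-4), 1), n_terms = 80)$E
  cr <- tacsim:::cross3(E, matrix(c(0, 0, 1), 1))
  expect_lt(sqrt(sum(cr^2)) / sqrt(sum(E^2)), 1e-5)
})

test_that("normal field projection is a signed scalar product", {
  mesh <- fixture_mesh()
  n_tri <- nrow(mesh$triangles)
  fm <- structure(list(E = matrix(rep(c(0, 0, 1), each = n_tri), n_tri)),
                  class = "field_map")
  En <- normal_field(fm, mesh)
  expect_equal(En, mesh$normals[, 3])
  # orthogonal field gives zero; flipping the normal flips the sign
  i <- which.max(abs(mesh$normals[, 3]))
  fo <- fm
  fo$E[i, ] <- c(mesh$normals[i, 2], -mesh$normals[i, 1], 0)
  expect_equal(normal_field(fo, mesh)[i], 0, tolerance = 1e-12)
  mflip <- mesh
  mflip$normals <- -mesh$normals
  expect_equal(normal_field(fm, mflip), -En)
  expect_error(normal_field(structure(list(E = fm$E[1:5, ]),
                                      class = "field_map"), mesh),
               "triangle counts")
})

test_that("region means average the normal field and scale by lambda", {
  parc <- structure(list(labels = c(1L, 1L, 2L, 2L), n_regions = 2L),
                    class = "parcellation")
  rc <- region_mean_field(c(1, 3, 2, 2), parc, lambda = 2)
  expect_equal(rc$mean_normal_field, c(2, 2))
  expect_equal(rc$offsets, c(4, 4))
  rc0 <- region_mean_field(c(1, 3, 2, 2), parc, lambda = 0)
  expect_equal(rc0$offsets, c(0, 0))
  bad <- structure(list(labels = c(1L, 1L, 1L, 1L), n_regions = 2L),
                   class = "parcellation")
  expect_error(region_mean_field(1:4, bad, 1), "empty region")
})

test_that("swapping anode and cathode negates the regional means", {
  mesh <- generate_cortical_mesh(2, 0.079, 0, seed = 1)
  parc <- parcellate(mesh, 8, seed = 1)
  lay <- standard_electrode_positions("10-10")
  sh <- default_field_shells()
  f1 <- efield_at(sh, pad_sources(stimulation_config("PO9", "PO10",
                                                     sources_per_pad = 4L),
                                  lay), mesh$barycenters, n_terms = 120)
  f2 <- efield_at(sh, pad_sources(stimulation_config("PO10", "PO9",
                                                     sources_per_pad = 4L),
                                  lay), mesh$barycenters, n_terms = 120)
  m1 <- region_mean_field(normal_field(f1, mesh), parc, 1)
  m2 <- region_mean_field(normal_field(f2, mesh), parc, 1)
  expect_equal(m1$mean_normal_field, -m2$mean_normal_field,
               tolerance = 1e-10)
})

test_that("the resistive skull attenuates the cortical field", {
  mesh <- generate_cortical_mesh(2, 0.079, 0, seed = 1)
  lay <- standard_electrode_positions("10-10")
  srcs <- pad_sources(stimulation_config(sources_per_pad = 9L), lay)
  sh_skull <- default_field_shells()
  sh_equal <- shell_model(sh_skull$radii,
                          rep(0.33, length(sh_skull$radii)))
  E1 <- efield_at(sh_skull, srcs, mesh$barycenters, n_terms = 150)$E
  E2 <- efield_at(sh_equal, srcs, mesh$barycenters, n_terms = 150)$E
  expect_lt(mean(sqrt(rowSums(E1^2))), mean(sqrt(rowSums(E2^2))))
})

test_that("field maps round-trip and malformed files are rejected", {
  set.seed(4)
  fm <- structure(list(E = matrix(rnorm(30), 10)), class = "field_map")
  path <- tempfile(fileext = ".tsv")
  write_field_map(fm, path)
  fm2 <- load_field_map(path)
  expect_equal(fm2$E, fm$E, tolerance = 1e-12)
  # gap in the indices
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  df$triangle_index[5] <- 99L
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_field_map(path), "format error")
  writeLines(character(0), path)
  expect_error(load_field_map(path), "format error")
})

test_that("superposing two source sets superposes their fields", {
  sh <- default_field_shells()
  lay <- standard_electrode_positions("10-10")
  sA <- pad_sources(stimulation_config("PO9", "PO10", sources_per_pad = 2L),
                    lay)
  sB <- pad_sources(stimulation_config("O1", "O2", sources_per_pad = 2L),
                    lay)
  sAB <- structure(list(positions = rbind(sA$positions, sB$positions),
                        currents = c(sA$currents, sB$currents)),
                   class = "point_source_set")
  pts <- matrix(c(0.02, 0, 0.03, -0.01, 0.02, 0.04), 2, byrow = TRUE)
  EA <- efield_at(sh, sA, pts, 100)$E
  EB <- efield_at(sh, sB, pts, 100)$E
  EAB <- efield_at(sh, sAB, pts, 100)$E
  expect_equal(EAB, EA + EB, tolerance = 1e-12)
})
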