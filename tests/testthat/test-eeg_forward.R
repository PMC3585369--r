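central_dipole <- function(orientation) {
  structure(list(positions = matrix(0, 1, 3),
                 orientations = matrix(orientation, 1),
                 moments = 1),
            class = "dipole_layer")
}

test_that("a central dipole in a homogeneous sphere matches the closed form", {
  R <- 0.09; sig <- 0.33
  sh <- shell_model(c(0.06, 0.075, R), rep(sig, 3))
  lay <- standard_electrode_positions("10-20", R)
  lf <- leadfield_3shell(sh, lay, central_dipole(c(0, 0, 1)), n_terms = 60,
                         reference = "none")
  closed <- 3 * (lay$positions[, 3] / R) / (4 * pi * sig * R^2)
  expect_equal(lf$values[, 1], closed, tolerance = 1e-12)
  # tangential central dipole: same form along x
  lf_t <- leadfield_3shell(sh, lay, central_dipole(c(1, 0, 0)), n_terms = 60,
                           reference = "none")
  closed_t <- 3 * (lay$positions[, 1] / R) / (4 * pi * sig * R^2)
  expect_equal(lf_t$values[, 1], closed_t, tolerance = 1e-12)
})

test_that("average-referenced leadfield columns sum to zero", {
  sh <- default_eeg_shells()
  lay <- standard_electrode_positions("10-20")
  mesh <- generate_cortical_mesh(2, 0.079, 0, seed = 1)
  dip <- dipole_layer(mesh)
  lf <- leadfield_3shell(sh, lay, dip, n_terms = 40)
  cs <- colSums(lf$values)
  expect_lt(max(abs(cs)) / max(sqrt(colSums(lf$values^2))), 1e-12)
  expect_error(
    leadfield_3shell(sh, lay,
                     structure(list(positions = matrix(c(0, 0, 0.085), 1),
                                    orientations = matrix(c(0, 0, 1), 1),
                                    moments = 1), class = "dipole_layer")),
    "outside inner shell")
})

test_that("the dipole series satisfies reciprocity with the field solver", {
  sh3 <- default_eeg_shells()
  lay <- standard_electrode_positions("10-20")
  set.seed(4)
  pos <- matrix(rnorm(24), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * runif(8, 0.03, 0.078)
  ori <- matrix(rnorm(24), ncol = 3)
  ori <- ori / sqrt(rowSums(ori^2))
  dl <- structure(list(positions = pos, orientations = ori,
                       moments = rep(1, 8)), class = "dipole_layer")
  lf <- leadfield_3shell(sh3, lay, dl, n_terms = 100, reference = "none")
  ia <- match("O1", lay$names); ib <- match("Fz", lay$names)
  I <- 1e-3
  srcs <- structure(list(positions = lay$positions[c(ia, ib), ],
                         currents = c(I, -I)), class = "point_source_set")
  E <- efield_at(sh3, srcs, pos, n_terms = 150)$E
  # V_a - V_b for a dipole p equals p . grad(phi_ab)(x0) / I, with phi_ab
  # the potential of current +I at a, -I at b
  recip <- -rowSums(ori * E) / I
  expect_equal(lf$values[ia, ] - lf$values[ib, ], recip, tolerance = 1e-4)
})

test_that("scalp potentials of a deep radial dipole match the finite-volume oracle", {
  skip_if_not_installed("Matrix")
  sh3 <- default_eeg_shells()
  b <- 0.05; d <- 0.002; q <- 1e-6
  fv <- fv_laplace_axisym(sh3$radii, sh3$conductivities, n_r = 184,
                          n_th = 256,
                          interior_sources = data.frame(
                            r = c(b + d / 2, b - d / 2), theta = c(0, 0),
                            I = c(q / d, -q / d)))
  lay <- standard_electrode_positions("10-20", 0.092)
  dl <- structure(list(positions = matrix(c(0, 0, b), 1),
                       orientations = matrix(c(0, 0, 1), 1), moments = 1),
                  class = "dipole_layer")
  lf <- leadfield_3shell(sh3, lay, dl, n_terms = 120, reference = "none")
  v_series <- lf$values[, 1] * q
  th <- acos(pmin(1, pmax(-1, lay$positions[, 3] / 0.092)))
  v_fv <- vapply(th, function(t_) fv$lookup(0.09175, t_), numeric(1))
  v_series <- v_series - mean(v_series)
  v_fv <- v_fv - mean(v_fv)
  expect_lt(max(abs(v_series - v_fv)) / max(abs(v_fv)), 0.02)
})

test_that("jointly rotating dipoles and electrodes permutes nothing", {
  sh <- default_eeg_shells()
  lay <- standard_electrode_positions("10-20")
  set.seed(9)
  pos <- matrix(rnorm(15), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2)) * 0.05
  ori <- matrix(rnorm(15), ncol = 3)
  ori <- ori / sqrt(rowSums(ori^2))
  dl <- structure(list(positions = pos, orientations = ori,
                       moments = rep(1, 5)), class = "dipole_layer")
  lf <- leadfield_3shell(sh, lay, dl, n_terms = 50, reference = "none")
  R <- rotation_matrix(c(2, -1, 1), 1.1)
  dlr <- structure(list(positions = pos %*% t(R), orientations = ori %*% t(R),
                        moments = rep(1, 5)), class = "dipole_layer")
  layr <- lay
  layr$positions <- lay$positions %*% t(R)
  lfr <- leadfield_3shell(sh, layr, dlr, n_terms = 50, reference = "none")
  expect_equal(lf$values, lfr$values, tolerance = 1e-10)
})

test_that("the resistive skull spreads the scalp topography", {
  lay <- standard_electrode_positions("10-10")
  dl <- structure(list(positions = matrix(c(0, 0, 0.07), 1),
                       orientations = matrix(c(0, 0, 1), 1), moments = 1),
                  class = "dipole_layer")
  sh_skull <- default_eeg_shells()
  sh_equal <- shell_model(sh_skull$radii, rep(0.33, 3))
  v1 <- leadfield_3shell(sh_skull, lay, dl, 60, reference = "none")$values[, 1]
  v2 <- leadfield_3shell(sh_equal, lay, dl, 60, reference = "none")$values[, 1]
  # spatial spread: correlation length proxy = ratio of mean |V| to max |V|
  expect_gt(mean(abs(v1)) / max(abs(v1)), mean(abs(v2)) / max(abs(v2)))
})

test_that("EEG projection is linear in the source matrix", {
  mesh <- generate_cortical_mesh(2, 0.079, 0, seed = 1)
  parc <- parcellate(mesh, 8, seed = 1)
  dip <- dipole_layer(mesh)
  lay <- standard_electrode_positions("10-20")
  A <- leadfield_3shell(default_eeg_shells(), lay, dip, n_terms = 40)
  mk_sim <- function(S) {
    structure(list(S = S, subcortical_trace = numeric(ncol(S)), fs = 512,
                   seed = 1L), class = "simulation_result")
  }
  S0 <- matrix(0, 8, 100)
  expect_equal(project_eeg(A, parc, dip, mk_sim(S0))$X,
               matrix(0, 19, 100))
  set.seed(2)
  S1 <- matrix(rnorm(800), 8)
  S2 <- matrix(rnorm(800), 8)
  X1 <- project_eeg(A, parc, dip, mk_sim(S1))$X
  X2 <- project_eeg(A, parc, dip, mk_sim(S2))$X
  X12 <- project_eeg(A, parc, dip, mk_sim(S1 + S2))$X
  expect_equal(X12, X1 + X2, tolerance = 1e-12)
  # one active region equals its moment-weighted leadfield column sum
  Sr <- matrix(0, 8, 10)
  Sr[3, ] <- 1
  Xr <- project_eeg(A, parc, dip, mk_sim(Sr))$X
  cols <- which(parc$labels == 3L)
  expected <- A$values[, cols, drop = FALSE] %*% dip$moments[cols] * 1e-3
  expect_equal(Xr[, 1], as.numeric(expected), tolerance = 1e-12)
  expect_error(project_eeg(A, parc, dip,
                           mk_sim(matrix(0, 5, 10))), "region count")
})

test_that("re-referencing is idempotent and difference-preserving", {
  set.seed(3)
  eeg <- structure(list(X = matrix(rnorm(19 * 50), 19), fs = 512,
                        electrode_names =
                          standard_electrode_positions("10-20")$names,
                        reference = "none"), class = "eeg_record")
  e1 <- rereference(eeg, "average")
  e2 <- rereference(e1, "average")
  expect_equal(e1$X, e2$X, tolerance = 1e-14)
  expect_lt(max(abs(colSums(e1$X))), 1e-12)
  ecz <- rereference(eeg, "Cz")
  icz <- match("Cz", eeg$electrode_names)
  expect_equal(ecz$X[icz, ], rep(0, 50))
  # inter-electrode differences unchanged
  expect_equal(eeg$X[1, ] - eeg$X[5, ], ecz$X[1, ] - ecz$X[5, ],
               tolerance = 1e-14)
  expect_error(rereference(eeg, "Nose"), "unknown")
})

test_that("leadfield and EEG text files round-trip", {
  lay <- standard_electrode_positions("10-20")
  set.seed(5)
  A <- structure(list(values = matrix(rnorm(19 * 7), 19),
                      electrode_names = lay$names, reference = "average"),
                 class = "leadfield_matrix")
  path <- tempfile(fileext = ".tsv")
  write_leadfield(A, path)
  A2 <- read_leadfield(path)
  expect_equal(A2$values, A$values, tolerance = 1e-12)
  expect_identical(A2$electrode_names, A$electrode_names)
  eeg <- structure(list(X = matrix(rnorm(19 * 30), 19), fs = 256,
                        electrode_names = lay$names, reference = "average"),
                   class = "eeg_record")
  ep <- tempfile(fileext = ".tsv")
  write_eeg_text(eeg, ep)
  e2 <- read_eeg_text(ep)
  expect_equal(e2$X, eeg$X, tolerance = 1e-12)
  expect_equal(e2$fs, 256)
})
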