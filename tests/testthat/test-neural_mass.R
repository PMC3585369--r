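pop <- population_params()

test_that("the wave-to-pulse sigmoid hits its midpoint and bounds", {
  expect_equal(sigmoid_rate(1, pop$P), 10)      # v0_P = 1 mV, e0 = 10
  expect_equal(sigmoid_rate(4, pop$I), 10)      # interneuron v0 = 4 mV
  expect_equal(sigmoid_rate(1e4, pop$P), 20)    # saturation at 2 e0
  expect_equal(sigmoid_rate(-1e4, pop$P), 0)
  v <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(sigmoid_rate(v, pop$Iprime)) > 0))
})

test_that("the PSP kernel vanishes at zero and peaks at the closed-form time", {
  expect_equal(psp_impulse_response(0, 5.5, 40, 80), 0)
  tstar <- log(80 / 40) / (80 - 40)
  expect_equal(tstar, log(2) / 40)
  t <- seq(0, 0.2, by = 1e-5)
  h <- psp_impulse_response(t, 5.5, 40, 80)
  expect_equal(t[which.max(h)], tstar, tolerance = 1e-3)
  expect_error(psp_impulse_response(0.1, 5.5, 80, 40), "exceed")
})

test_that("the trapezoid drive is periodic with the configured plateau", {
  drv <- list(period = 2.5, ramp_up = 0.3, plateau = 0.5, ramp_down = 0.3,
              amplitude = 120)
  expect_equal(trapezoid_drive(0.3 + 0.25, drv), 120)   # plateau midpoint
  t <- c(0.1, 0.7, 1.4, 2.2)
  expect_equal(trapezoid_drive(t, drv), trapezoid_drive(t + 2.5, drv))
  expect_true(all(trapezoid_drive(seq(0, 5, by = 0.01), drv) >= 0))
  drv0 <- drv; drv0$amplitude <- 0
  expect_equal(trapezoid_drive(seq(0, 5, by = 0.1), drv0),
               rep(0, 51))
})

test_that("stimulus offsets follow the configured waveform", {
  st0 <- stimulus_spec("none")
  expect_equal(tcs_offset(c(0, 1, 2), st0, 1), c(0, 0, 0))
  std <- stimulus_spec("dc", offsets = c(2, -1))
  expect_equal(tcs_offset(c(0, 5), std, 1), c(2, 2))
  expect_equal(tcs_offset(0.3, std, 2), -1)
  sts <- stimulus_spec("sinusoid", frequency = 10, offsets = 1.5)
  expect_equal(tcs_offset(0, sts, 1), 0)
  expect_equal(tcs_offset(0.025, sts, 1), 1.5)   # quarter period of 10 Hz
  expect_error(stimulus_spec("sinusoid", frequency = -1), "positive")
})

test_that("simulations are bit-identical under a repeated seed", {
  net <- network_config(n_cortical = 3, duration = 6, transient = 1)
  s1 <- simulate_network(pop, net, stimulus_spec("none"), seed = 42)
  s2 <- simulate_network(pop, net, stimulus_spec("none"), seed = 42)
  expect_identical(s1$S, s2$S)
  expect_identical(s1$subcortical_trace, s2$subcortical_trace)
  s3 <- simulate_network(pop, net, stimulus_spec("none"), seed = 43)
  expect_false(identical(s1$S, s3$S))
})

test_that("firing rates stay inside (0, 2 e0) at every recorded step", {
  net <- network_config(n_cortical = 2, duration = 12, transient = 1)
  st <- stimulus_spec("sinusoid", 10, offsets = c(1, -1))
  sim <- simulate_network(pop, net, st, seed = 5)
  for (k in 1:2) {
    off <- tcs_offset((seq_len(ncol(sim$S)) - 1) / sim$fs, st, k)
    rates <- sigmoid_rate(sim$S[k, ] + off, pop$P)
    expect_true(all(rates > 0 & rates < 2 * pop$P$e0))
  }
})

test_that("a single population produces an alpha-band spectral peak", {
  net <- network_config(n_cortical = 1, subcortical_gain = 0, duration = 34)
  pk <- vapply(1:2, function(sd_) {
    sim <- simulate_network(pop, net, stimulus_spec("none"), seed = sd_)
    ps <- psd_periodogram(sim$S[1, ], sim$fs)
    sel <- ps$freq >= 2 & ps$freq <= 20
    ps$freq[sel][which.max(ps$power[sel])]
  }, numeric(1))
  expect_true(all(pk >= 8 & pk <= 12))
})

test_that("subcortical coupling synchronizes otherwise independent regions", {
  corr_mean <- function(S) {
    cm <- cor(t(S)); mean(abs(cm[upper.tri(cm)]))
  }
  net0 <- network_config(n_cortical = 5, subcortical_gain = 0,
                         duration = 34)
  c0 <- corr_mean(simulate_network(pop, net0, stimulus_spec("none"),
                                   seed = 11)$S)
  expect_lt(c0, 0.2)
  net1 <- network_config(n_cortical = 5, duration = 34)
  c1 <- corr_mean(simulate_network(pop, net1, stimulus_spec("none"),
                                   seed = 11)$S)
  expect_gte(c1 - c0, 0.3)
})

test_that("depolarizing DC offsets monotonically raise the pyramidal rate", {
  net <- network_config(n_cortical = 1, subcortical_gain = 0, duration = 22)
  offsets <- c(-2, -1, 0, 1, 2)
  rates <- vapply(offsets, function(d) {
    sim <- simulate_network(pop, net, stimulus_spec("dc", offsets = d),
                            seed = 3)
    mean(sigmoid_rate(sim$S[1, ] + d, pop$P))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the noise-free undriven network settles onto the algebraic fixed point", {
  net <- network_config(n_cortical = 1, subcortical_gain = 0,
                        drive = list(period = 2.5, ramp_up = 0.3,
                                     plateau = 0.5, ramp_down = 0.3,
                                     amplitude = 0),
                        noise = list(mean = 90, sd = 0),
                        duration = 14, transient = 2)
  sim <- simulate_network(pop, net, stimulus_spec("none"), seed = 1)
  tail_v <- sim$S[1, (ncol(sim$S) - 100):ncol(sim$S)]
  expect_lt(diff(range(tail_v)), 1e-6)
  # independent oracle: solve the stationary equations by root finding
  dcg <- function(sub) sub$gain * sub$coupling / (sub$w1 * sub$w2)
  gE <- dcg(pop$P); gG <- dcg(pop$I); gB <- dcg(pop$Iprime)
  C <- pop$C
  resid <- function(v) {
    mP <- sigmoid_rate(v[1], pop$P)
    mI <- sigmoid_rate(v[2], pop$I)
    mI2 <- sigmoid_rate(v[3], pop$Iprime)
    c(gE * (C[["C_PP"]] * mP + 90) - gG * C[["C_IP"]] * mI -
        gB * C[["C_I'P"]] * mI2 - v[1],
      gE * C[["C_PI"]] * mP - gG * C[["C_II"]] * mI -
        gB * C[["C_I'I"]] * mI2 - v[2],
      gE * C[["C_PI'"]] * mP - gB * C[["C_I'I'"]] * mI2 - v[3])
  }
  sol <- stats::optim(c(0, 0, 0), function(v) sum(resid(v)^2),
                      method = "BFGS", control = list(reltol = 1e-16))
  sol <- stats::optim(sol$par, function(v) sum(resid(v)^2),
                      method = "BFGS", control = list(reltol = 1e-16))
  expect_lt(sol$value, 1e-8)
  expect_equal(mean(tail_v), sol$par[1], tolerance = 1e-3)
})

test_that("halving the integration step barely moves the alpha peak", {
  peak_of <- function(dt) {
    net <- network_config(n_cortical = 1, subcortical_gain = 0,
                          dt = dt, duration = 26)
    sim <- simulate_network(pop, net, stimulus_spec("none"), seed = 8)
    ps <- psd_periodogram(sim$S[1, ], sim$fs)
    sel <- ps$freq >= 6 & ps$freq <= 14
    sum(ps$freq[sel] * ps$power[sel]) / sum(ps$power[sel])  # band centroid
  }
  expect_lt(abs(peak_of(1 / 512) - peak_of(1 / 1024)), 0.2)
})

test_that("an unstable step size raises an instability error", {
  net <- network_config(n_cortical = 1, subcortical_gain = 0, dt = 0.02,
                        duration = 4, transient = 1)
  expect_error(simulate_network(pop, net, stimulus_spec("none"), seed = 1),
               "instability.*dt")
})

test_that("simulation export round-trips through delimited text", {
  net <- network_config(n_cortical = 2, duration = 4, transient = 1)
  sim <- simulate_network(pop, net, stimulus_spec("none"), seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_simulation(sim, path)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  expect_equal(unname(m[, 1:2]), unname(t(sim$S)), tolerance = 1e-12)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  expect_equal(meta$fs, sim$fs)
})
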