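test_that("QIF constants match direct evaluation and factor at V_R, V_T", {
  ke <- qif_constants(g_L = 0.08, C = 1, V_R = -62, V_T = -55)
  expect_equal(ke$zeta, 0.08 / 7, tolerance = 1e-12)
  expect_equal(ke$eta, 0.08 * 117 / 7, tolerance = 1e-12)
  expect_equal(ke$kappa, 0.08 * 55 * 62 / 7, tolerance = 1e-12)
  # frozen three-significant-figure values
  expect_equal(ke$zeta, 0.0114286, tolerance = 1e-5)
  expect_equal(ke$eta, 1.33714, tolerance = 1e-5)
  expect_equal(ke$kappa, 38.9714, tolerance = 1e-5)

  ki <- qif_constants(g_L = 0.1)
  expect_equal(ki$zeta, 0.0142857, tolerance = 1e-5)
  expect_equal(ki$eta, 1.67143, tolerance = 1e-5)
  expect_equal(ki$kappa, 48.7143, tolerance = 1e-5)

  # zeta v^2 + eta v + kappa = zeta (v - V_R)(v - V_T): roots at rest and
  # threshold, for both cell classes
  for (k in list(ke, ki)) {
    roots <- sort(Re(polyroot(c(k$kappa, k$eta, k$zeta))))
    expect_equal(roots, c(-62, -55), tolerance = 1e-9)
  }
})

test_that("degenerate or invalid membrane parameters are rejected", {
  expect_error(qif_constants(0.08, V_R = -55, V_T = -55),
               class = "columnet_config_error")
  expect_error(qif_constants(0.08, V_R = -50, V_T = -55),
               class = "columnet_config_error")
  expect_error(qif_constants(-0.08), class = "columnet_config_error")
})

# An isolated single population: the E-I fixture with all pathways switched
# off and negligible heterogeneity.
isolated_net <- function(delta = 1e-9, i_back_e = .state_default_iback()) {
  net <- ei_network(delta_e = delta, delta_i = delta, i_back_e = i_back_e)
  net$pathways$P <- 0
  net
}
.state_default_iback <- function() 0.02 * 16 / 3

zero_state <- function(net, r = 0, v = net$populations$V_R) {
  n <- nrow(net$populations)
  list(r = rep(r, n), v = rep(v, n)[seq_len(n)],
       g_exc_in = rep(0, n), g_inh_in = rep(0, n))
}

test_that("rest and threshold are fixed points of the isolated zero-width limit", {
  net <- isolated_net(delta = 1e-300)
  net$populations$I_back_center <- 0
  for (vfix in c(-62, -55)) {
    d <- mean_field_rhs(zero_state(net, r = 0, v = vfix), net)
    expect_equal(d$r, c(0, 0), tolerance = 1e-12)
    expect_equal(d$v, c(0, 0), tolerance = 1e-10)
    expect_equal(unname(d$g_exc_in), c(0, 0))
    expect_equal(unname(d$g_inh_in), c(0, 0))
  }
})

test_that("heterogeneity source term repels the rate from zero", {
  net <- isolated_net(delta = 0.3)
  net$populations$I_back_center <- 0
  d <- mean_field_rhs(zero_state(net, r = 0, v = -40), net)
  expect_equal(d$r[1], (0.08 / 7) * 0.3 / pi, tolerance = 1e-12)
  expect_equal(d$r[1], 1.0914e-3, tolerance = 1e-4)
  expect_gt(d$r[2], 0)
})

test_that("non-finite state is rejected with a diagnostic", {
  net <- isolated_net()
  st <- zero_state(net)
  st$v[1] <- NaN
  expect_error(mean_field_rhs(st, net), class = "columnet_numeric_error")
})

test_that("isolated population converges to the closed-form subthreshold root", {
  iback <- 0.02 * 16 / 3 # subthreshold for both classes
  net <- isolated_net(delta = 1e-9, i_back_e = iback)
  tr <- simulate_columns(net, "none", t_total = 3000, t_onset = 2999)
  pops <- net$populations
  v_end <- tr$voltages[nrow(tr$voltages), ]
  r_end <- tr$rates[nrow(tr$rates), ]
  for (i in 1:2) {
    disc <- pops$eta[i]^2 - 4 * pops$zeta[i] *
      (pops$kappa[i] + pops$I_back_center[i] / pops$C[i])
    expect_gt(disc, 0)
    v_root <- (-pops$eta[i] - sqrt(disc)) / (2 * pops$zeta[i])
    expect_equal(unname(v_end[i]), v_root, tolerance = 1e-6)
    expect_lt(r_end[i], 1e-3) # Hz
  }
})

test_that("trajectories keep rates and conductances non-negative", {
  for (cond in c("none", "S1S2_A1")) {
    tr <- simulate_columns(reference_network(), cond,
                           t_total = 2000, t_onset = 1000)
    expect_gte(min(tr$rates), 0)
  }
})

test_that("aggregated conductances reproduce the per-pathway formulation", {
  # Reference implementation: one conductance state per pathway, pure R.
  net <- reference_network()
  pops <- net$populations
  pw <- dplyr::filter(net$pathways, P > 0)
  src <- match(pw$source, pops$name)
  tgt <- match(pw$target, pops$name)
  w <- pw$g_peak * pw$P * pops$N[src]
  tau <- pops$tau_d[src]
  is_exc <- pops$cell_class[src] == "E"
  vsyn_pw <- ifelse(is_exc, 0, -70)

  dt <- 0.01; n_steps <- 4000
  r <- rep(1e-4, 16); v <- pops$V_R
  g <- rep(0, nrow(pw)) # one state per pathway
  zeta <- pops$zeta; eta <- pops$eta; kappa <- pops$kappa
  iback <- pops$I_back_center; dback <- pops$I_back_width
  for (s in seq_len(n_steps)) {
    ge <- as.vector(rowsum(g * is_exc, tgt, reorder = TRUE))
    gi <- as.vector(rowsum(g * !is_exc, tgt, reorder = TRUE))
    sum_g <- ge + gi
    dr <- 2 * zeta * r * v + eta * r - r * sum_g + (zeta / pi) * dback
    dv <- zeta * v^2 + eta * v + kappa - (pi^2 / zeta) * r^2 +
      (gi * (-70) - v * sum_g) + iback
    dg <- -g / tau + w * r[src]
    r <- r + dt * dr; v <- v + dt * dv; g <- g + dt * dg
  }

  tr <- simulate_columns(net, "none", t_total = n_steps * dt,
                         t_onset = n_steps * dt - dt, record_stride = 1)
  n <- nrow(tr$rates)
  expect_equal(unname(tr$rates[n, ]) / 1000, r, tolerance = 1e-10)
  expect_equal(unname(tr$voltages[n, ]), v, tolerance = 1e-10)
})
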