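test_that("HH rate functions match direct evaluation, including limits", {
  # oracle: direct scalar evaluation of the classic squid-axon formulas
  r <- hh_rates(-65)
  am <- 0.1 * (-65 + 40) / (1 - exp(-(-65 + 40) / 10))
  expect_equal(r$alpha_m, am, tolerance = 1e-15)
  expect_equal(r$beta_m, 4 * exp(0), tolerance = 1e-15)
  expect_equal(r$alpha_m / (r$alpha_m + r$beta_m), 0.05293, tolerance = 1e-4)

  # removable singularities evaluated by their limits
  expect_identical(hh_rates(-40)$alpha_m, 1.0)
  expect_identical(hh_rates(-55)$alpha_n, 0.1)
  # continuity just off the singular point
  expect_equal(hh_rates(-40 + 1e-9)$alpha_m, 1.0, tolerance = 1e-8)

  # strict positivity over the physiological range
  v <- seq(-100, 60, by = 0.5)
  r <- hh_rates(v)
  for (nm in names(r)) expect_true(all(r[[nm]] > 0), label = nm)
})

test_that("gating variables stay in [0,1] under the exponential update", {
  key <- c(5L, 6L, 7L, 8L)
  v <- -100 + counter_rng(key, 0:199) * 160
  dts <- c(1e-3, 0.025, 0.5, 10)[1 + floor(counter_rng(key, 200:399) * 4)][1:200]
  x <- counter_rng(key, 400:599)
  r <- hh_rates(v)
  for (dt in unique(dts)) {
    xn <- neurocable:::gate_update(x, r$alpha_m, r$beta_m, dt)
    expect_true(all(xn >= 0 & xn <= 1))
  }
  # dt -> 0 leaves states unchanged to first order
  expect_equal(neurocable:::gate_update(x, r$alpha_m, r$beta_m, 1e-12), x,
               tolerance = 1e-9)
})

test_that("passive and HH current kernels obey the linearized-current contract", {
  m <- one_compartment_model(list(mech = "pas", params = list(g = 1e-3, e = -70)))
  st <- init_state(m)
  pool <- st$pools[[1]]
  area <- m$area[1]
  # at the reversal potential the passive current vanishes
  cur <- pool$spec$current(pool, -70, 0)
  expect_equal(cur$i, 0)
  # absolute conductance g_abs = g * area * 1e-2; i = g_abs (v - e)
  cur <- pool$spec$current(pool, -65, 0)
  gabs <- 1e-3 * area * 1e-2
  expect_equal(cur$g, gabs, tolerance = 1e-15)
  expect_equal(cur$i, gabs * 5, tolerance = 1e-15)
  # purity: identical inputs, bit-identical outputs
  expect_identical(cur, pool$spec$current(pool, -65, 0))

  mh <- one_compartment_model(list(mech = "hh", params = list()))
  sth <- init_state(mh, v_init = -65)
  ph <- sth$pools[[1]]
  cur <- ph$spec$current(ph, -65, 0)
  # oracle: direct scalar evaluation of m^3 h gNa (v-eNa) + n^4 gK (v-eK) + gL (v-eL)
  ss <- neurocable:::hh_steady(-65)
  i_dens <- 0.12 * ss$m^3 * ss$h * (-65 - 50) +
    0.036 * ss$n^4 * (-65 + 77) + 3e-4 * (-65 + 54.3)
  expect_equal(cur$i, i_dens * mh$area[1] * 1e-2, tolerance = 1e-12)
})

test_that("expsyn decays exponentially and sums simultaneous events", {
  m <- one_compartment_model(list(mech = "expsyn", params = list(tau = 2)))
  st <- init_state(m)
  pool <- st$pools[[1]]
  pool$states$g <- 1
  dec <- pool$spec$state(pool, -65, 2, st$v)
  expect_equal(dec$g, exp(-1), tolerance = 1e-15)

  pool$states <- pool$spec$net_receive(pool, 1L, 0.5)
  pool$states <- pool$spec$net_receive(pool, 1L, 0.5)
  expect_equal(pool$states$g, 2.0)
  pool$states <- pool$spec$net_receive(pool, 1L, 0)
  expect_equal(pool$states$g, 2.0)   # zero-weight event changes nothing
})

test_that("current clamp injects exactly amp*dur of charge", {
  m <- one_compartment_model(list(mech = "iclamp",
                                  params = list(del = 1, dur = 2, amp = 0.1)))
  st <- init_state(m)
  run(st, 10)
  expect_equal(st$v[1] - (-65), 0.1 * 2 / m$cm_node[1], tolerance = 1e-9)
})

test_that("netstim trains are deterministic with correct statistics", {
  expect_equal(netstim_events(5, 10, 3, noise = 0), c(5, 15, 25))
  expect_error(netstim_events(5, 0, 3), class = "nc_parameter_error")

  key <- c(9L, 3L, 11L, 1013904223L)
  t1 <- netstim_events(1, 5, 1000, noise = 1, key = key)
  t2 <- netstim_events(1, 5, 1000, noise = 1, key = key)
  expect_identical(t1, t2)
  expect_true(all(diff(t1) > 0))

  big <- netstim_events(0, 5, 1e5, noise = 1, key = key)
  expect_equal(mean(diff(big)), 5, tolerance = 0.02)
})

test_that("gap junction current is antisymmetric and relaxes like the 2-compartment ODE", {
  cell <- soma_only_cell()
  m <- network_model(list(cell, cell), gids = 0:1)
  g <- 0.002
  m <- insert_mechanism(m, "gap", 0L, 1L, params = list(g = g, peer_node = 2))
  m <- insert_mechanism(m, "gap", 1L, 1L, params = list(g = g, peer_node = 1))
  dt <- 0.005
  st <- init_state(m, dt = dt)
  st$v <- c(-80, -50)
  for (pid in seq_along(st$pools)) {
    pool <- st$pools[[pid]]
    pool$states <- pool$spec$init(pool, st$v[pool$node_index], st$v)
    st$pools[[pid]] <- pool
  }
  pool <- st$pools[[1]]
  cur <- pool$spec$current(pool, st$v[pool$node_index], 0)
  expect_equal(cur$i[1] + cur$i[2], 0)     # same snapshot: i_AB + i_BA = 0
  expect_equal(cur$i[1], g * (-80 - -50))

  nstep <- 2000L
  for (k in seq_len(nstep)) step(st)
  # oracle: dv(t) = dv0 * exp(-g (1/C1 + 1/C2) t), closed form of the coupled ODE
  C <- m$cm_node[1]
  anal <- 30 * exp(-g * (2 / C) * nstep * dt)
  expect_equal(abs(st$v[2] - st$v[1]), anal, tolerance = 2e-3)

  m_bad <- insert_mechanism(network_model(list(cell), gids = 0L), "gap", 0L, 1L,
                            params = list(g = g))
  expect_error(init_state(m_bad), class = "nc_wiring_error")
})

test_that("mechanism registry rejects duplicates and keeps SoA pools consistent", {
  expect_error(register_mechanism(mechanism_spec("pas", "density")),
               class = "nc_registration_error")
  expect_error(mechanism_spec("x", "density", has_net_receive = TRUE),
               class = "nc_registration_error")
  expect_error(mechanism_spec("x", "artificial", current = function(...) NULL),
               class = "nc_registration_error")

  id <- register_mechanism(mechanism_spec("test_custom", "point",
                                          params = list(a = 1)))
  expect_true(is.integer(id) && id == nrow(list_mechanisms()))
  reset_mechanism_registry()
  expect_error(get_mechanism("test_custom"), class = "nc_registration_error")

  # SoA contract: one contiguous numeric vector per field, instance-major never
  m <- ring_network(n_types = 1, cells_per_type = 4, seed = 1)
  st <- init_state(m)
  for (pool in st$pools) {
    for (p in pool$params) expect_length(p, pool$count)
    for (s in pool$states) expect_length(s, pool$count)
    expect_false(is.unsorted(pool$node_index))
  }
})
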