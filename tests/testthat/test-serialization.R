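test_that("model archives roundtrip structurally and deterministically", {
  m <- ring_network(n_types = 2, cells_per_type = 8, ring_size = 8, seed = 3,
                    n_groups = 3)
  d1 <- withr::local_tempdir()
  write_model(m, d1)
  m2 <- read_model(d1)
  expect_identical(neurocable:::model_digest(m), neurocable:::model_digest(m2))
  expect_identical(m$parent, m2$parent)
  expect_identical(m$area, m2$area)
  expect_identical(m$cells, m2$cells)
  expect_identical(m$netcons, m2$netcons)
  expect_identical(m$cell_nodes, m2$cell_nodes)

  d2 <- withr::local_tempdir()
  write_model(m, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("decoded archives simulate identically to the in-memory model", {
  m <- ring_network(n_types = 1, cells_per_type = 16, seed = 19)
  d <- withr::local_tempdir()
  write_model(m, d)
  expect_same_raster(sim_raster(m, 50), sim_raster(read_model(d), 50))
})

test_that("archive validation rejects bad manifests and truncated data", {
  m <- ring_network(n_types = 1, cells_per_type = 2, seed = 1)
  d <- withr::local_tempdir()
  write_model(m, d)
  mfp <- file.path(d, "manifest.json")
  mf <- jsonlite::read_json(mfp)

  mf2 <- mf; mf2$tags$ins_node <- "mystery_offset"
  jsonlite::write_json(mf2, mfp, auto_unbox = TRUE)
  expect_error(read_model(d), regexp = "mystery_offset", class = "nc_archive_error")

  mf3 <- mf; mf3$version <- 99L
  jsonlite::write_json(mf3, mfp, auto_unbox = TRUE)
  expect_error(read_model(d), class = "nc_archive_error")

  mf4 <- mf; mf4$registry_digest <- "0000000000000000"
  jsonlite::write_json(mf4, mfp, auto_unbox = TRUE)
  expect_error(read_model(d), regexp = "registry", class = "nc_archive_error")

  jsonlite::write_json(mf, mfp, auto_unbox = TRUE, digits = NA)
  nf <- file.path(d, "group_001", "nodes.bin")
  writeBin(readBin(nf, "raw", 4), nf)
  expect_error(read_model(d), class = "nc_archive_error")
})

test_that("an empty network archives and runs to tstop", {
  m <- network_model(list(soma_only_cell()), gids = 0L)
  d <- withr::local_tempdir()
  write_model(m, d)
  m2 <- read_model(d)
  st <- init_state(m2)
  r <- run(st, 5)
  expect_equal(nrow(r), 0L)
  expect_equal(sim_time(st), 5)
})

test_that("checkpoints collapse undelivered deliveries into source events", {
  # source fires at t=10 with delays {1,2,3}; at t=11.5 one delivery is done,
  # two remain: the archive must hold exactly one source event (gid, 10)
  m <- one_compartment_model(list(mech = "expsyn", params = list(e = 0)))
  m <- add_netstim(m, 10L, start = 10, interval = 1, number = 1L, seed = 1L)
  for (d in c(1, 2, 3)) m <- add_netcon(m, 10L, 1L, weight = 0.001, delay = d)
  st <- init_state(m)
  run(st, 11.5)
  expect_equal(length(st$q_time), 2L)      # deliveries at 12 and 13 pending
  ck <- withr::local_tempdir()
  save_checkpoint(st, ck)
  pend_gid <- neurocable:::read_i32(file.path(ck, "pend_gid.bin"))
  pend_t <- neurocable:::read_f64(file.path(ck, "pend_t.bin"))
  expect_identical(pend_gid, 10L)
  expect_identical(pend_t, 10)

  # restore regenerates the same multiset of pending deliveries
  st2 <- restore_checkpoint(ck, m)
  expect_equal(sort(st2$q_time), sort(st$q_time))
  expect_equal(sort(st2$q_nc), sort(st$q_nc))

  # checkpoint immediately after restore is byte-identical
  ck2 <- withr::local_tempdir()
  save_checkpoint(st2, ck2)
  for (f in list.files(ck, recursive = TRUE)) {
    expect_identical(readBin(file.path(ck, f), "raw", file.size(file.path(ck, f))),
                     readBin(file.path(ck2, f), "raw", file.size(file.path(ck2, f))),
                     label = f)
  }
})

test_that("a checkpoint with no pending events stores an empty event table", {
  m <- one_compartment_model(list(mech = "pas", params = list()))
  st <- init_state(m)
  run(st, 2)
  ck <- withr::local_tempdir()
  save_checkpoint(st, ck)
  expect_length(neurocable:::read_i32(file.path(ck, "pend_gid.bin")), 0)
})

test_that("split runs reproduce the continuous run bit-identically", {
  nets <- list(
    hh_ring = ring_network(n_types = 2, cells_per_type = 8, ring_size = 8,
                           seed = 31),
    noisy = {
      m <- one_compartment_model(list(mech = "hh", params = list()),
                                 list(mech = "expsyn", params = list(e = 0)))
      m <- add_presyn(m, 0L, 1L, threshold = -20)
      m <- add_netstim(m, 5L, start = 2, interval = 3, number = 30L,
                       noise = 1, seed = 7L)
      add_netcon(m, 5L, 2L, weight = 0.03, delay = 1)
    })
  for (nm in names(nets)) {
    m <- nets[[nm]]
    r_cont <- sim_raster(m, 100)
    st <- init_state(m)
    run(st, 50)
    ck <- withr::local_tempdir()
    save_checkpoint(st, ck)
    st2 <- restore_checkpoint(ck, m)
    r2 <- run(st2, 100)
    expect_same_raster(r_cont, rbind(get_raster(st), r2))
  }
})

test_that("restoring with a different stimulus stream diverges only after t_restore", {
  m <- one_compartment_model(list(mech = "hh", params = list()),
                             list(mech = "expsyn", params = list(e = 0)))
  m <- add_presyn(m, 0L, 1L, threshold = -20)
  m <- add_netstim(m, 5L, start = 2, interval = 4, number = 40L, noise = 1,
                   seed = 7L)
  m <- add_netcon(m, 5L, 2L, weight = 0.05, delay = 1)
  r_cont <- sim_raster(m, 120)
  st <- init_state(m); run(st, 60)
  ck <- withr::local_tempdir()
  save_checkpoint(st, ck)
  st2 <- restore_checkpoint(ck, m, netstim_seed = 99L)
  r2 <- rbind(get_raster(st), run(st2, 120))
  pre <- function(r) r[r$time <= 60 + 1e-9, ]
  expect_same_raster(pre(r_cont), pre(r2))
  expect_false(identical(r_cont$time, r2$time))
})

test_that("checkpoints refuse mismatched models", {
  m <- ring_network(n_types = 1, cells_per_type = 4, seed = 1)
  st <- init_state(m); run(st, 5)
  ck <- withr::local_tempdir()
  save_checkpoint(st, ck)
  other <- ring_network(n_types = 1, cells_per_type = 4, seed = 2)
  expect_error(restore_checkpoint(ck, other), class = "nc_integrity_error")
})
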