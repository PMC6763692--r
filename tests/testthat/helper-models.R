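# Fixtures built in code: tiny cells and networks used across tests.

soma_only_cell <- function() {
  build_cell(list(section_spec(1, length = 20, diam = 20, nseg = 1)))
}

chain_cell <- function(nseg) {
  build_cell(list(section_spec(1, length = 10 * nseg, diam = 2, nseg = nseg)))
}

y_cell <- function(nseg = 2L) {
  build_cell(list(
    section_spec(1, length = 20, diam = 20, nseg = 1),
    section_spec(2, length = 50, diam = 1, nseg = nseg, parent_section = 1),
    section_spec(3, length = 50, diam = 1, nseg = nseg, parent_section = 1)))
}

# single compartment with chosen mechanisms inserted on node 1
one_compartment_model <- function(...) {
  m <- network_model(list(soma_only_cell()), gids = 0L)
  for (ins in list(...))
    m <- insert_mechanism(m, ins$mech, 0L, 1L, params = ins$params)
  m
}

# random tree parent vector (parent-before-child by construction)
random_parent_tree <- function(n, key, n_roots = 1L) {
  parent <- integer(n)
  for (i in seq_len(n)) {
    if (i <= n_roots) { parent[i] <- 0L; next }
    u <- counter_rng(key, i)
    parent[i] <- 1L + floor(u * (i - 1))
  }
  parent
}

# dense symmetric solve oracle for the tree system
dense_tree_solve <- function(d, b, rhs, parent) {
  n <- length(d)
  M <- diag(d, n, n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0) { M[i, p] <- b[i]; M[p, i] <- b[i] }
  }
  as.numeric(solve(M, rhs))
}

# random diagonally dominant coefficients on a given tree
random_tree_system <- function(parent, key) {
  n <- length(parent)
  b <- ifelse(parent == 0L, 0, -(0.5 + counter_rng(key, seq_len(n))))
  nonroot <- which(parent != 0L)
  child_load <- neurocable:::accum_add_cpp(n, parent[nonroot], -b[nonroot])
  d <- 1 + counter_rng(key, n + seq_len(n)) + abs(b) + child_load
  rhs <- counter_rng(key, 2L * n + seq_len(n)) * 10 - 5
  list(d = d, b = b, rhs = rhs)
}

sim_raster <- function(model, tstop, dt = 0.025) {
  st <- init_state(model, dt = dt)
  run(st, tstop)
}

expect_same_raster <- function(a, b) {
  expect_identical(a$time, b$time)
  expect_identical(a$gid, b$gid)
}
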