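# The per-timestep integration loop: deliver due events, assemble the
# implicit-Euler tree system, Hines-solve it, advance mechanism states with
# end-of-step voltages, detect threshold crossings. Fixed step; t is always
# step_index * dt.

#' Initialize simulator state for a model
#'
#' Builds the Structure-of-Arrays mechanism pools (one per mechanism type and
#' cell group, instances sorted by node index), the solver arrays, the spike
#' watchers, and the artificial-cell event trains. Voltage starts uniform at
#' `v_init`; gating states start at their steady state at `v_init`.
#'
#' @param model an `nc_model`.
#' @param dt time step, ms (> 0); default 0.025.
#' @param v_init initial membrane potential, mV.
#' @return an `nc_state` environment.
#' @export
init_state <- function(model, dt = 0.025, v_init = -65) {
  if (!is.finite(dt) || dt <= 0)
    nc_stop("nc_parameter_error", "dt must be > 0")
  st <- new.env(parent = emptyenv())
  class(st) <- "nc_state"
  st$model <- model
  st$dt <- dt
  st$step_index <- 0L
  st$v <- rep(v_init, model$n_nodes)
  st$op_count <- 0
  n <- model$n_nodes

  # constant parts of the matrix: off-diagonal to parent and the axial +
  # capacitive diagonal (the tree matrix is symmetric)
  st$b <- -model$g_axial
  st$cm_dt <- model$cm_node / dt
  nonroot <- which(model$parent != 0L)
  ax <- accum_add_cpp(n, c(nonroot, model$parent[nonroot]),
                      c(model$g_axial[nonroot], model$g_axial[nonroot]))
  st$d_base <- st$cm_dt + ax

  # SoA pools keyed by (mechanism type, cell group)
  st$pools <- list()
  st$syn_map <- vector("list", length(model$insertions))
  if (length(model$insertions) > 0) {
    mechs <- vapply(model$insertions, `[[`, character(1), "mech")
    nodes <- vapply(model$insertions, `[[`, numeric(1), "node")
    grp <- model$cells$group[model$cell_of_node[nodes]]
    tid <- vapply(mechs, function(m) get_mechanism(m)$type_id, integer(1))
    keyo <- order(tid, grp, nodes, seq_along(mechs))
    split_key <- paste(tid[keyo], grp[keyo])
    for (chunk in split(keyo, factor(split_key, unique(split_key)))) {
      spec <- get_mechanism(mechs[chunk[1]])
      cnt <- length(chunk)
      pr <- names(spec$params)
      pool <- list(
        mech = spec$name, spec = spec, group = grp[chunk[1]], count = cnt,
        node_index = as.integer(nodes[chunk]),
        ins_ids = as.integer(chunk),
        area = model$area[nodes[chunk]],
        params = stats::setNames(lapply(pr, function(p) vapply(
          model$insertions[chunk], function(x) as.numeric(x$params[[p]]),
          numeric(1))), pr),
        states = stats::setNames(
          lapply(names(spec$states),
                 function(s) rep(unname(spec$states[s]), cnt)),
          names(spec$states)))
      pid <- length(st$pools) + 1L
      st$pools[[pid]] <- pool
      for (j in seq_along(chunk)) st$syn_map[[chunk[j]]] <- c(pid, j)
    }
  }
  for (pid in seq_along(st$pools)) {
    pool <- st$pools[[pid]]
    if (!is.null(pool$spec$init))
      pool$states <- pool$spec$init(pool, st$v[pool$node_index], st$v)
    st$pools[[pid]] <- pool
  }

  # spike watchers
  ps <- model$presyns
  st$ps_gid <- ps$gid
  st$ps_watch <- ps$watch_node
  st$ps_thr <- ps$threshold
  st$ps_armed <- st$v[ps$watch_node] < ps$threshold

  # artificial-cell event trains (pure functions of their stream key)
  st$netstim_times <- lapply(seq_len(nrow(model$netstims)), function(j) {
    r <- model$netstims[j, ]
    netstim_events(r$start, r$interval, r$number, r$noise,
                   make_stream_key(r$seed, r$gid, "netstim"))
  })
  st$last_pull <- 0

  st$netcons_by_src <- split(seq_len(nrow(model$netcons)), model$netcons$src_gid)
  st$q_time <- numeric(0); st$q_src <- integer(0)
  st$q_nc <- integer(0); st$q_srct <- numeric(0)
  st$buf_gid <- integer(0); st$buf_t <- numeric(0)
  st$raster_t <- numeric(0); st$raster_gid <- integer(0)
  st$probe_nodes <- integer(0); st$probe_labels <- character(0)
  st$probe_t <- numeric(0); st$probe_v <- list()
  st
}

#' Current simulation time of a state (ms)
#' @param state an `nc_state`.
#' @export
sim_time <- function(state) state$step_index * state$dt

#' Record a voltage probe
#'
#' @param state an `nc_state`.
#' @param gid cell gid.
#' @param node cell-local node index.
#' @export
add_probe <- function(state, gid, node = 1L) {
  st <- state
  st$probe_nodes <- c(st$probe_nodes, node_of(st$model, gid, node))
  st$probe_labels <- c(st$probe_labels, sprintf("%d:%d", gid, node))
  invisible(st)
}

#' Probe traces as a table
#' @param state an `nc_state`.
#' @return tibble `time` (ms) plus one column per probe (`"gid:node"`, mV).
#' @export
probe_table <- function(state) {
  m <- do.call(rbind, state$probe_v)
  if (is.null(m)) m <- matrix(numeric(0), 0, length(state$probe_nodes))
  colnames(m) <- state$probe_labels
  tibble::as_tibble(cbind(tibble::tibble(time = state$probe_t),
                          tibble::as_tibble(m)))
}

# Fill d and rhs for the implicit (backward Euler) step taken from time t:
#   d_i  = cm_i/dt + sum_mech g + sum_adjacent g_axial
#   rhs_i = (cm_i/dt + sum_mech g) * v_i - sum_mech i
# so that solving M v_new = rhs advances the membrane equation by dt.
assemble <- function(state, t) {
  n <- state$model$n_nodes
  v <- state$v
  d <- state$d_base
  rhs <- state$cm_dt * v
  for (pool in state$pools) {
    if (is.null(pool$spec$current)) next
    idx <- pool$node_index
    vi <- v[idx]
    if (any(!is.finite(vi)))
      nc_stop("nc_numerical_error", "non-finite voltage at %s instance", pool$mech)
    cur <- pool$spec$current(pool, vi, t)
    d <- d + accum_add_cpp(n, idx, cur$g)
    rhs <- rhs + accum_add_cpp(n, idx, cur$g * vi - cur$i)
  }
  state$d <- d
  state$rhs <- rhs
  invisible(state)
}

#' Solve the tree-structured membrane system
#'
#' Gaussian elimination specialized to trees ordered parent-before-child: a
#' reverse sweep eliminates every node onto its parent, then forward
#' substitution recovers the voltages. The multiply/divide count depends only
#' on the number of nodes and roots, never on the branching pattern -- the
#' cost is identical to an unbranched cable of equal size.
#'
#' @param d diagonal; @param b off-diagonal to parent (root entries ignored);
#' @param rhs right-hand side; @param parent 1-based parent index, 0 = root.
#' @return list with `v` (solution) and `ops` (multiply/divide tally).
#' @export
hines_solve <- function(d, b, rhs, parent) {
  hines_solve_cpp(as.numeric(d), as.numeric(b), as.numeric(rhs),
                  as.integer(parent))
}

# Advance mechanism states using end-of-step voltages, then snapshot gap-
# junction peer voltages for the next step.
advance_states <- function(state) {
  v <- state$v
  for (pid in seq_along(state$pools)) {
    pool <- state$pools[[pid]]
    if (is.null(pool$spec$state)) next
    pool$states <- pool$spec$state(pool, v[pool$node_index], state$dt, v)
    state$pools[[pid]] <- pool
  }
  invisible(state)
}

# Record a spike (gid, t_new) when a watched voltage reaches threshold from
# below (>= rule); the watcher rearms only after falling back below.
detect_spikes <- function(state, t_new) {
  if (length(state$ps_watch) == 0) return(invisible(state))
  vw <- state$v[state$ps_watch]
  fire <- state$ps_armed & vw >= state$ps_thr
  if (any(fire)) {
    g <- state$ps_gid[fire]
    state$raster_t <- c(state$raster_t, rep(t_new, length(g)))
    state$raster_gid <- c(state$raster_gid, g)
    state$buf_gid <- c(state$buf_gid, g)
    state$buf_t <- c(state$buf_t, rep(t_new, length(g)))
    state$ps_armed[fire] <- FALSE
  }
  rearm <- !state$ps_armed & vw < state$ps_thr
  state$ps_armed[rearm] <- TRUE
  invisible(state)
}

#' Advance the simulation by one time step
#'
#' Executes, in order: (1) delivery of events due in `(t, t+dt]`, (2) matrix
#' assembly, (3) Hines solve, (4) state-variable update at the new voltages,
#' (5) threshold detection; then `t` advances by `dt`.
#'
#' @param state an `nc_state`.
#' @export
step <- function(state) {
  state$in_step <- TRUE
  t0 <- state$step_index * state$dt
  t1 <- t0 + state$dt
  deliver_events(state, t1)
  assemble(state, t0)
  sol <- hines_solve_cpp(state$d, state$b, state$rhs, state$model$parent)
  state$v <- sol$v
  state$op_count <- state$op_count + sol$ops
  advance_states(state)
  detect_spikes(state, t1)
  state$step_index <- state$step_index + 1L
  if (length(state$probe_nodes) > 0) {
    state$probe_t <- c(state$probe_t, t1)
    state$probe_v[[length(state$probe_v) + 1L]] <- state$v[state$probe_nodes]
  }
  state$in_step <- FALSE
  invisible(state)
}

#' Run the simulation to `tstop`
#'
#' The hybrid clock-event loop: fixed steps with a global spike exchange
#' every minimum-delay interval (every step if `mindelay < 2 dt`). Integrates
#' to the largest multiple of `dt` not exceeding `tstop`.
#'
#' @param state an `nc_state` (possibly mid-run or restored).
#' @param tstop end time, ms (>= current time).
#' @return tibble raster of this call's spikes: `time` (ms), `gid`, sorted by
#'   `(time, gid)`.
#' @export
run <- function(state, tstop) {
  t_now <- sim_time(state)
  if (tstop < t_now - .nc_tol)
    nc_stop("nc_parameter_error", "tstop %g is before current time %g", tstop, t_now)
  md <- compute_mindelay(state$model$netcons, max(tstop, state$dt), state$dt)
  ex_steps <- max(1L, as.integer(floor(md / state$dt + .nc_tol)))
  n_target <- as.integer(floor(tstop / state$dt + .nc_tol))
  r0 <- length(state$raster_t)
  while (state$step_index < n_target) {
    step(state)
    if (state$step_index %% ex_steps == 0L || state$step_index == n_target)
      exchange_spikes(state, sim_time(state))
  }
  out <- tibble::tibble(time = state$raster_t, gid = state$raster_gid)
  if (r0 > 0) out <- out[-seq_len(r0), ]
  out[order(out$time, out$gid), ]
}

#' Spike raster accumulated over the state's whole history
#' @param state an `nc_state`.
#' @return tibble `time`, `gid` sorted by `(time, gid)`.
#' @export
get_raster <- function(state) {
  out <- tibble::tibble(time = state$raster_t, gid = state$raster_gid)
  out[order(out$time, out$gid), ]
}
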