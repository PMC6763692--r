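# Event-driven spike machinery: minimum-delay exchange, the delivery queue,
# and its total tie-break order. Cells interact only through these events, so
# a simulation partitioned into k cell groups is bit-identical to the
# unpartitioned one; the exchange is the single-process analogue of the
# MPI allgather of (spike time, gid) pairs every minimum-delay interval.

#' Minimum NetCon delay (the spike-exchange interval)
#'
#' Spike sources need only be synchronized every `mindelay` because no
#' delivery can come due sooner than `mindelay` after its source spike.
#'
#' @param netcons tibble with a `delay` column (ms).
#' @param tstop returned when there are no netcons (a single exchange
#'   suffices).
#' @param dt integration step; delays below `dt` would require mid-interval
#'   exchange and are a configuration error.
#' @return ms.
#' @export
compute_mindelay <- function(netcons, tstop, dt = 0.025) {
  if (nrow(netcons) == 0) return(tstop)
  if (any(netcons$delay < dt - .nc_tol))
    nc_stop("nc_configuration_error",
            "netcon delay %g ms is below dt = %g ms", min(netcons$delay), dt)
  min(netcons$delay)
}

# Fan out buffered source spikes (gid, t_spike) to every NetCon with that
# source, enqueueing delivery events at t_spike + delay; clears the buffer.
exchange_spikes <- function(state, t_now) {
  # artificial sources: pull event times that fell due since the last exchange
  ns <- state$model$netstims
  if (nrow(ns) > 0) {
    for (j in seq_len(nrow(ns))) {
      ts <- state$netstim_times[[j]]
      sel <- ts > state$last_pull + .nc_tol & ts <= t_now + .nc_tol
      if (any(sel)) {
        state$buf_gid <- c(state$buf_gid, rep(ns$gid[j], sum(sel)))
        state$buf_t <- c(state$buf_t, ts[sel])
      }
    }
  }
  state$last_pull <- t_now
  if (length(state$buf_gid) > 0) {
    for (k in seq_along(state$buf_gid)) {
      gid <- state$buf_gid[k]; tsp <- state$buf_t[k]
      ncs <- state$netcons_by_src[[as.character(gid)]]
      if (is.null(ncs)) next
      nc <- state$model$netcons[ncs, ]
      state$q_time <- c(state$q_time, tsp + nc$delay)
      state$q_src <- c(state$q_src, nc$src_gid)
      state$q_nc <- c(state$q_nc, ncs)
      state$q_srct <- c(state$q_srct, rep(tsp, length(ncs)))
    }
    state$buf_gid <- integer(0)
    state$buf_t <- numeric(0)
  }
  invisible(state)
}

# Pop every event with delivery_time <= t_limit (1e-9 ms tolerance) in the
# total order (time, src_gid, netcon id) and invoke the target's net_receive.
deliver_events <- function(state, t_limit) {
  if (length(state$q_time) == 0) return(invisible(state))
  due <- which(state$q_time <= t_limit + .nc_tol)
  if (length(due) == 0) return(invisible(state))
  ord <- due[order(state$q_time[due], state$q_src[due], state$q_nc[due])]
  for (e in ord) {
    ncid <- state$q_nc[e]
    syn <- state$model$netcons$syn_id[ncid]
    w <- state$model$netcons$weight[ncid]
    tgt <- state$syn_map[[syn]]
    if (is.null(tgt))
      nc_stop("nc_integrity_error", "event targets missing pool for insertion %d", syn)
    pool <- state$pools[[tgt[1]]]
    pool$states <- pool$spec$net_receive(pool, tgt[2], w)
    state$pools[[tgt[1]]] <- pool
  }
  keep <- setdiff(seq_along(state$q_time), due)
  state$q_time <- state$q_time[keep]
  state$q_src <- state$q_src[keep]
  state$q_nc <- state$q_nc[keep]
  state$q_srct <- state$q_srct[keep]
  invisible(state)
}

# Pending deliveries collapsed to unique source events (gid, spike time) --
# what a checkpoint stores instead of per-netcon deliveries.
collapse_pending <- function(state) {
  gid <- c(state$q_src, state$buf_gid)
  tsp <- c(state$q_srct, state$buf_t)
  if (length(gid) == 0)
    return(tibble::tibble(gid = integer(), spike_time = numeric()))
  u <- !duplicated(paste(gid, sprintf("%.17g", tsp)))
  out <- tibble::tibble(gid = as.integer(gid[u]), spike_time = tsp[u])
  out[order(out$spike_time, out$gid), ]
}
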