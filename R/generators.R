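# Synthetic network generators. All randomness flows through the counter
# RNG, so the same seed always yields a byte-identical model.

# One randomly branched cell: an HH soma plus n_dend passive dendrites, each
# attached uniformly at random to an already-placed section (soma or
# dendrite) whose depth is below depth_max. Cells of one type share a stream
# key, hence a branching pattern.
random_branched_cell <- function(type, seed, n_dend = 2L, nseg_per_dend = 2L,
                                 soma_nseg = 1L, depth_max = 3L,
                                 dend_length = 100, dend_diam = 1) {
  key <- make_stream_key(seed, type, "branching")
  secs <- list(section_spec(1L, length = 20, diam = 20, nseg = soma_nseg))
  depth <- 0L
  for (d in seq_len(n_dend)) {
    elig <- which(depth < depth_max)
    u <- counter_rng(key, d - 1L)
    pick <- elig[1L + min(floor(u * length(elig)), length(elig) - 1L)]
    secs[[d + 1L]] <- section_spec(d + 1L, length = dend_length,
                                   diam = dend_diam, nseg = nseg_per_dend,
                                   parent_section = secs[[pick]]$id)
    depth <- c(depth, depth[pick] + 1L)
  }
  build_cell(secs)
}

#' Ring-network benchmark generator
#'
#' Builds `n_types * cells_per_type` cells; each type has its own random
#' dendritic branching pattern (seed-deterministic), all cells of a type are
#' topologically identical, and every cell has the same node count
#' (`soma_nseg + n_dend * nseg_per_dend`). Cells are wired into rings of
#' `ring_size` consecutive cells: cell k excites cell k+1 (mod ring) through
#' an exponential synapse on the soma with fixed weight and delay, so a
#' stimulated ring carries a self-sustained wave of spikes in ring order.
#' Somata carry Hodgkin-Huxley channels; dendrites are passive.
#'
#' @param n_types number of morphological types.
#' @param cells_per_type cells per type (identical within a type).
#' @param n_dend,nseg_per_dend,soma_nseg,depth_max cell geometry knobs.
#' @param ring_size cells per ring; must divide the total cell count
#'   (default: one ring of all cells).
#' @param seed generator seed (drives branching and stimulus streams).
#' @param syn_weight uS; @param syn_delay ms (>= dt).
#' @param stim if `TRUE`, each ring gets one stimulus source firing once at
#'   `stim_start` into its first cell.
#' @param stim_start ms (> 0).
#' @param n_groups cell groups (logical ranks) for the partition contract.
#' @param count_only if `TRUE`, return counts (total cells / nodes) without
#'   instantiating the network.
#' @return an `nc_model`, or a list of counts when `count_only`.
#' @export
ring_network <- function(n_types, cells_per_type, n_dend = 2L,
                         nseg_per_dend = 2L, soma_nseg = 1L, depth_max = 3L,
                         ring_size = NULL, seed = 1L, syn_weight = 0.05,
                         syn_delay = 1, stim = TRUE, stim_start = 1,
                         n_groups = 1L, count_only = FALSE) {
  if (n_types < 1 || cells_per_type < 1 || n_dend < 1 || nseg_per_dend < 1)
    nc_stop("nc_configuration_error", "ring_network: all counts must be >= 1")
  total <- n_types * cells_per_type
  if (is.null(ring_size)) ring_size <- total
  if (total %% ring_size != 0)
    nc_stop("nc_configuration_error",
            "ring_size %d does not divide total cell count %d", ring_size, total)
  nodes_per_cell <- soma_nseg + n_dend * nseg_per_dend
  if (count_only) {
    # node count is independent of the branching pattern; confirm on one type
    probe <- random_branched_cell(1L, seed, n_dend, nseg_per_dend, soma_nseg,
                                  depth_max)
    stopifnot(probe$n_nodes == nodes_per_cell)
    return(list(total_cells = total, nodes_per_cell = nodes_per_cell,
                total_nodes = total * nodes_per_cell))
  }
  type_cells <- lapply(seq_len(n_types), function(t)
    random_branched_cell(t, seed, n_dend, nseg_per_dend, soma_nseg, depth_max))
  cells <- rep(type_cells, each = cells_per_type)
  types <- rep(seq_len(n_types), each = cells_per_type)
  model <- network_model(cells, gids = seq_len(total) - 1L, types = types,
                         n_groups = n_groups)
  syn_of_cell <- integer(total)
  for (k in seq_len(total)) {
    gid <- k - 1L
    for (sn in seq_len(soma_nseg))
      model <- insert_mechanism(model, "hh", gid, sn)
    for (dn in (soma_nseg + 1L):nodes_per_cell)
      model <- insert_mechanism(model, "pas", gid, dn,
                                params = list(g = 1e-3, e = -65))
    model <- insert_mechanism(model, "expsyn", gid, 1L)
    syn_of_cell[k] <- model$meta$last_insertion
    model <- add_presyn(model, gid, node = 1L, threshold = -20)
  }
  n_rings <- total %/% ring_size
  for (b in seq_len(n_rings)) {
    idx <- (b - 1L) * ring_size + seq_len(ring_size)
    for (j in seq_along(idx)) {
      nxt <- idx[if (j == ring_size) 1L else j + 1L]
      model <- add_netcon(model, src_gid = idx[j] - 1L,
                          syn_id = syn_of_cell[nxt],
                          weight = syn_weight, delay = syn_delay)
    }
    if (stim) {
      sgid <- total + b - 1L
      model <- add_netstim(model, sgid, start = stim_start, interval = 1,
                           number = 1L, noise = 0, seed = seed)
      model <- add_netcon(model, sgid, syn_of_cell[idx[1]],
                          weight = syn_weight, delay = syn_delay)
    }
  }
  model$meta$generator <- list(name = "ring", n_types = n_types,
                               cells_per_type = cells_per_type, seed = seed)
  model
}
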