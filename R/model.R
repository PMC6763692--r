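#' Assemble a flattened network model from cells
#'
#' Concatenates per-cell topologies into flat node arrays (the layout the
#' solver and mechanism pools operate on) and attaches empty mechanism /
#' connectivity tables. Cells are coupled only through events, never through
#' the matrix, so any partition of cells into groups simulates identically.
#'
#' @param cells list of `nc_cell` objects.
#' @param gids unique integer global ids, one per cell (default `0:(n-1)`).
#' @param types integer type label per cell (cells of one type must be
#'   topologically identical for interleaved ordering).
#' @param n_groups number of cell groups; cells are assigned round-robin in
#'   gid order.
#' @return an `nc_model`.
#' @export
network_model <- function(cells, gids = NULL, types = NULL, n_groups = 1L) {
  ncell <- length(cells)
  if (is.null(gids)) gids <- seq_len(ncell) - 1L
  gids <- as.integer(gids)
  if (anyDuplicated(gids)) nc_stop("nc_topology_error", "gids must be unique")
  if (length(gids) != ncell) nc_stop("nc_topology_error", "one gid per cell required")
  if (is.null(types)) types <- rep(1L, ncell)
  n_groups <- max(1L, as.integer(n_groups))
  nn <- vapply(cells, `[[`, integer(1), "n_nodes")
  offset <- c(0L, cumsum(nn))[seq_len(ncell)]
  parent <- integer(0); area <- numeric(0); cmn <- numeric(0); gax <- numeric(0)
  cell_nodes <- vector("list", ncell)
  cell_of_node <- integer(sum(nn))
  for (k in seq_len(ncell)) {
    ce <- cells[[k]]
    idx <- offset[k] + seq_len(ce$n_nodes)
    parent <- c(parent, ifelse(ce$parent == 0L, 0L, ce$parent + offset[k]))
    area <- c(area, ce$area); cmn <- c(cmn, ce$cm_node); gax <- c(gax, ce$g_axial)
    cell_nodes[[k]] <- as.integer(idx)
    cell_of_node[idx] <- k
  }
  model <- structure(list(
    n_nodes = sum(nn),
    parent = as.integer(parent),
    area = area, cm_node = cmn, g_axial = gax,
    cell_of_node = cell_of_node,
    cells = tibble::tibble(gid = gids, type = as.integer(types),
                           group = ((seq_len(ncell) - 1L) %% n_groups) + 1L,
                           n_nodes = nn, offset = offset),
    cell_nodes = cell_nodes,
    insertions = list(),
    netcons = tibble::tibble(src_gid = integer(), syn_id = integer(),
                             weight = numeric(), delay = numeric()),
    presyns = tibble::tibble(gid = integer(), watch_node = integer(),
                             threshold = numeric()),
    netstims = tibble::tibble(gid = integer(), start = numeric(),
                              interval = numeric(), number = integer(),
                              noise = numeric(), seed = integer()),
    meta = list(permutation = "none")
  ), class = "nc_model")
  diag <- validate_tree(model$parent, n_roots = ncell)
  if (nrow(diag) > 0)
    nc_stop("nc_topology_error", "network_model: %s", diag$message[1])
  model
}

# Global node index of a cell-local node.
node_of <- function(model, gid, local) {
  k <- match(gid, model$cells$gid)
  if (is.na(k)) nc_stop("nc_wiring_error", "unknown gid %s", gid)
  model$cell_nodes[[k]][local]
}

#' Insert a mechanism instance on a node
#'
#' Density mechanisms contribute current per membrane area (converted to nA
#' via the node area); point mechanisms contribute absolute nA. Parameters
#' not supplied take the registered defaults.
#'
#' @param model an `nc_model`.
#' @param mech registered mechanism name.
#' @param gid cell gid; `node` is the cell-local node index.
#' @param node cell-local node index (1-based).
#' @param params named numeric overrides of the mechanism defaults.
#' @return the model with the insertion added; the insertion id is in
#'   `model$meta$last_insertion`.
#' @export
insert_mechanism <- function(model, mech, gid, node = 1L, params = list()) {
  spec <- get_mechanism(mech)
  if (spec$kind == "artificial")
    nc_stop("nc_wiring_error", "artificial mechanisms are added with add_netstim()")
  gnode <- node_of(model, gid, node)
  if (is.na(gnode)) nc_stop("nc_wiring_error", "gid %s has no node %d", gid, node)
  p <- spec$params
  for (nm in names(params)) {
    if (!nm %in% names(p))
      nc_stop("nc_parameter_error", "%s: unknown parameter '%s'", mech, nm)
    p[[nm]] <- params[[nm]]
  }
  id <- length(model$insertions) + 1L
  model$insertions[[id]] <- list(id = id, mech = mech, node = gnode,
                                 gid = as.integer(gid), params = p)
  model$meta$last_insertion <- id
  model
}

#' Add a spike-threshold watcher (PreSyn) to a cell
#'
#' A spike `(gid, t)` is recorded when the watched node's voltage reaches
#' `threshold` from below; the watcher rearms only after the voltage falls
#' back below threshold.
#'
#' @param model an `nc_model`.
#' @param gid cell gid.
#' @param node cell-local node to watch.
#' @param threshold mV (crossing fires on `v >= threshold`).
#' @export
add_presyn <- function(model, gid, node = 1L, threshold = -20) {
  if (gid %in% model$presyns$gid)
    nc_stop("nc_wiring_error", "gid %s already has a spike watcher", gid)
  model$presyns <- rbind(model$presyns, tibble::tibble(
    gid = as.integer(gid), watch_node = as.integer(node_of(model, gid, node)),
    threshold = threshold))
  model
}

#' Add a stochastic stimulus source (artificial cell)
#'
#' An event-only cell: it owns no membrane, only a deterministic or
#' exponential event train computed from the counter-based RNG stream keyed
#' by `(seed, gid)`. Its spikes fan out through NetCons like any cell's.
#'
#' @param model an `nc_model`.
#' @param gid unused gid for the source.
#' @param start first event time, ms (> 0).
#' @param interval mean inter-event interval, ms (> 0).
#' @param number number of events.
#' @param noise 0 (regular) to 1 (Poisson).
#' @param seed stream seed.
#' @export
add_netstim <- function(model, gid, start, interval, number, noise = 0, seed = 1L) {
  if (interval <= 0)
    nc_stop("nc_parameter_error", "netstim: interval must be > 0")
  if (number < 0) nc_stop("nc_parameter_error", "netstim: number must be >= 0")
  if (gid %in% model$cells$gid || gid %in% model$netstims$gid)
    nc_stop("nc_wiring_error", "gid %s already in use", gid)
  model$netstims <- rbind(model$netstims, tibble::tibble(
    gid = as.integer(gid), start = start, interval = interval,
    number = as.integer(number), noise = noise, seed = as.integer(seed)))
  model
}

#' Connect a spike source to a synapse instance
#'
#' @param model an `nc_model`.
#' @param src_gid gid of the firing cell or netstim.
#' @param syn_id insertion id of a mechanism with a `net_receive` kernel.
#' @param weight uS, added to the synaptic conductance at delivery.
#' @param delay ms, must be at least one time step.
#' @export
add_netcon <- function(model, src_gid, syn_id, weight, delay) {
  if (syn_id < 1 || syn_id > length(model$insertions))
    nc_stop("nc_wiring_error", "netcon target %s does not exist", syn_id)
  tspec <- get_mechanism(model$insertions[[syn_id]]$mech)
  if (!isTRUE(tspec$has_net_receive))
    nc_stop("nc_wiring_error", "netcon target '%s' has no net_receive", tspec$name)
  if (!(src_gid %in% model$cells$gid || src_gid %in% model$netstims$gid))
    nc_stop("nc_wiring_error", "netcon source gid %s unknown", src_gid)
  model$netcons <- rbind(model$netcons, tibble::tibble(
    src_gid = as.integer(src_gid), syn_id = as.integer(syn_id),
    weight = weight, delay = delay))
  model
}

# Stable content digest of the structural model (topology + wiring), used to
# match checkpoints and archives against the model they came from.
model_digest <- function(model) {
  ins <- vapply(model$insertions, function(x)
    sprintf("%s@%d:%s", x$mech, x$node,
            paste(sprintf("%.17g", unlist(x$params)), collapse = ",")), character(1))
  desc <- c(sprintf("%d", model$parent), sprintf("%.17g", model$area),
            sprintf("%.17g", model$g_axial), sprintf("%.17g", model$cm_node),
            sprintf("%d", model$cells$gid), sprintf("%d", model$cells$group),
            ins,
            sprintf("%d>%d:%.17g@%.17g", model$netcons$src_gid,
                    model$netcons$syn_id, model$netcons$weight, model$netcons$delay),
            sprintf("%d|%d|%.17g", model$presyns$gid, model$presyns$watch_node,
                    model$presyns$threshold),
            sprintf("%d|%.17g|%.17g|%d|%.17g|%d", model$netstims$gid,
                    model$netstims$start, model$netstims$interval,
                    model$netstims$number, model$netstims$noise, model$netstims$seed))
  fnv1a64_cpp(charToRaw(paste(desc, collapse = ";")))
}
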