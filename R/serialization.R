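# On-disk archives: a directory with a JSON manifest plus flat little-endian
# binary datasets per cell group. No absolute addresses are stored: every
# cross-reference is an integer offset labelled with a semantic tag in the
# manifest, and unknown tags are fatal on read. Output bytes are a pure
# function of the model/state, so archives are content-hashable.

.nc_known_tags <- c("voltage_offset", "area_offset", "point_process_index",
                    "netcon_target", "presyn_index", "peer_voltage_offset")

.nc_model_tags <- list(nodes = "voltage_offset", parent = "voltage_offset",
                       ins_node = "voltage_offset", gap_peer = "peer_voltage_offset",
                       netcon_tgt = "point_process_index",
                       presyn_watch = "voltage_offset", presyn_row = "presyn_index")

write_i32 <- function(path, x) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}
write_f64 <- function(path, x) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
}
read_i32 <- function(path) {
  if (!file.exists(path)) nc_stop("nc_archive_error", "missing dataset %s", path)
  readBin(path, integer(), n = file.size(path) / 4L, size = 4L, endian = "little")
}
read_f64 <- function(path) {
  if (!file.exists(path)) nc_stop("nc_archive_error", "missing dataset %s", path)
  readBin(path, numeric(), n = file.size(path) / 8L, size = 8L, endian = "little")
}

registry_digest <- function() {
  d <- list_mechanisms()
  specs <- lapply(d$name, get_mechanism)
  desc <- vapply(specs, function(s)
    paste(s$name, s$kind, paste(names(s$params), collapse = ","),
          paste(names(s$states), collapse = ","), sep = "|"), character(1))
  fnv1a64_cpp(charToRaw(paste(desc[order(d$type_id)], collapse = ";")))
}

#' Write a model archive
#'
#' Serializes the model group-by-group (each cell group's datasets are
#' assembled and flushed independently, so peak writer memory is bounded by
#' the largest group, not the model). Deterministic: the same model always
#' produces byte-identical files.
#'
#' @param model an `nc_model`.
#' @param path directory to create (must not be an existing non-archive).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  for (ins in model$insertions)
    spec <- get_mechanism(ins$mech)  # unknown mechanism -> schema error
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  groups <- sort(unique(model$cells$group))
  gdirs <- sprintf("group_%03d", groups)
  ins_mech <- vapply(model$insertions, `[[`, character(1), "mech")
  ins_gid <- vapply(model$insertions, function(x) as.integer(x$gid), integer(1))
  nc_grp <- if (nrow(model$netcons) > 0)
    model$cells$group[match(ins_gid[model$netcons$syn_id], model$cells$gid)]
  else integer(0)

  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gd <- file.path(path, gdirs[gi])
    dir.create(gd, showWarnings = FALSE)
    ks <- which(model$cells$group == g)
    nodes <- unlist(model$cell_nodes[ks], use.names = FALSE)
    write_i32(file.path(gd, "cell_index.bin"), ks)
    write_i32(file.path(gd, "gids.bin"), model$cells$gid[ks])
    write_i32(file.path(gd, "types.bin"), model$cells$type[ks])
    write_i32(file.path(gd, "nn.bin"), model$cells$n_nodes[ks])
    write_i32(file.path(gd, "off.bin"), model$cells$offset[ks])
    write_i32(file.path(gd, "nodes.bin"), nodes)
    write_i32(file.path(gd, "parent.bin"), model$parent[nodes])
    write_f64(file.path(gd, "area.bin"), model$area[nodes])
    write_f64(file.path(gd, "cm.bin"), model$cm_node[nodes])
    write_f64(file.path(gd, "gax.bin"), model$g_axial[nodes])

    gids_g <- model$cells$gid[ks]
    ii <- which(ins_gid %in% gids_g)
    write_i32(file.path(gd, "ins_id.bin"), ii)
    write_i32(file.path(gd, "ins_gid.bin"), ins_gid[ii])
    write_i32(file.path(gd, "ins_node.bin"),
              vapply(model$insertions[ii], function(x) as.integer(x$node), integer(1)))
    jsonlite::write_json(as.list(ins_mech[ii]), file.path(gd, "ins_mech.json"),
                         auto_unbox = TRUE)
    write_f64(file.path(gd, "ins_params.bin"),
              unlist(lapply(model$insertions[ii], function(x)
                as.numeric(unlist(x$params[names(get_mechanism(x$mech)$params)]))),
                use.names = FALSE))

    ni <- which(nc_grp == g)
    write_i32(file.path(gd, "nc_id.bin"), ni)
    write_i32(file.path(gd, "nc_src.bin"), model$netcons$src_gid[ni])
    write_i32(file.path(gd, "nc_tgt.bin"), model$netcons$syn_id[ni])
    write_f64(file.path(gd, "nc_w.bin"), model$netcons$weight[ni])
    write_f64(file.path(gd, "nc_delay.bin"), model$netcons$delay[ni])

    pi_ <- which(model$presyns$gid %in% gids_g)
    write_i32(file.path(gd, "presyn_row.bin"), pi_)
    write_i32(file.path(gd, "presyn_gid.bin"), model$presyns$gid[pi_])
    write_i32(file.path(gd, "presyn_watch.bin"),
              ifelse(is.na(model$presyns$watch_node[pi_]), -1L,
                     model$presyns$watch_node[pi_]))
    write_f64(file.path(gd, "presyn_thr.bin"), model$presyns$threshold[pi_])
  }

  ns <- model$netstims
  write_i32(file.path(path, "netstim_gid.bin"), ns$gid)
  write_f64(file.path(path, "netstim_par.bin"),
            c(ns$start, ns$interval, as.numeric(ns$number), ns$noise,
              as.numeric(ns$seed)))

  manifest <- list(
    format = "neurocable-model", version = 1L, index_base = 1L,
    units = list(v = "mV", t = "ms", conductance = "uS", current = "nA",
                 capacitance = "nF", length = "um"),
    n_nodes = model$n_nodes, n_cells = nrow(model$cells),
    n_insertions = length(model$insertions),
    n_netcons = nrow(model$netcons), n_presyns = nrow(model$presyns),
    n_netstims = nrow(model$netstims),
    groups = lapply(seq_along(groups), function(gi) list(
      id = groups[gi], dir = gdirs[gi],
      n_cells = sum(model$cells$group == groups[gi]))),
    mechanisms = lapply(list_mechanisms()$name, function(nm) {
      s <- get_mechanism(nm)
      list(name = s$name, kind = s$kind, params = as.list(names(s$params)))
    }),
    registry_digest = registry_digest(),
    model_digest = model_digest(model),
    tags = .nc_model_tags)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path, format) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    nc_stop("nc_archive_error", "no manifest at %s", path)
  mf <- jsonlite::read_json(mf_path)
  if (!identical(mf$format, format))
    nc_stop("nc_archive_error", "archive format '%s', expected '%s'",
            mf$format, format)
  if (!identical(as.integer(mf$version), 1L))
    nc_stop("nc_archive_error", "unsupported archive version %s", mf$version)
  mf
}

#' Read a model archive
#'
#' Validates the manifest (format, version, semantic tags, mechanism-registry
#' digest) and reassembles the model; the decoded model simulates
#' identically to the original.
#'
#' @param path archive directory written by [write_model()].
#' @return an `nc_model`.
#' @export
read_model <- function(path) {
  mf <- read_manifest(path, "neurocable-model")
  for (nm in names(mf$tags))
    if (!mf$tags[[nm]] %in% .nc_known_tags)
      nc_stop("nc_archive_error", "unknown semantic tag '%s' for dataset '%s'",
              mf$tags[[nm]], nm)
  if (!identical(mf$registry_digest, registry_digest()))
    nc_stop("nc_archive_error",
            "archive mechanism registry digest %s does not match this session (%s)",
            mf$registry_digest, registry_digest())
  n <- as.integer(mf$n_nodes)
  ncell <- as.integer(mf$n_cells)
  parent <- integer(n); area <- numeric(n); cmn <- numeric(n); gax <- numeric(n)
  cell_of_node <- integer(n)
  gid <- integer(ncell); type <- integer(ncell); grp <- integer(ncell)
  nnv <- integer(ncell); offv <- integer(ncell)
  cell_nodes <- vector("list", ncell)
  insertions <- vector("list", as.integer(mf$n_insertions))
  ncn <- as.integer(mf$n_netcons)
  nc_src <- integer(ncn); nc_tgt <- integer(ncn)
  nc_w <- numeric(ncn); nc_dl <- numeric(ncn)
  nps <- as.integer(mf$n_presyns)
  ps_gid <- integer(nps); ps_watch <- integer(nps); ps_thr <- numeric(nps)

  for (gr in mf$groups) {
    gd <- file.path(path, gr$dir)
    ks <- read_i32(file.path(gd, "cell_index.bin"))
    gid[ks] <- read_i32(file.path(gd, "gids.bin"))
    type[ks] <- read_i32(file.path(gd, "types.bin"))
    grp[ks] <- as.integer(gr$id)
    nn_g <- read_i32(file.path(gd, "nn.bin")); nnv[ks] <- nn_g
    offv[ks] <- read_i32(file.path(gd, "off.bin"))
    nodes <- read_i32(file.path(gd, "nodes.bin"))
    if (length(nodes) != sum(nn_g))
      nc_stop("nc_archive_error", "truncated dataset %s", file.path(gd, "nodes.bin"))
    parent[nodes] <- read_i32(file.path(gd, "parent.bin"))
    area[nodes] <- read_f64(file.path(gd, "area.bin"))
    cmn[nodes] <- read_f64(file.path(gd, "cm.bin"))
    gax[nodes] <- read_f64(file.path(gd, "gax.bin"))
    pos <- c(0L, cumsum(nn_g))
    for (j in seq_along(ks)) {
      ix <- nodes[(pos[j] + 1L):pos[j + 1L]]
      cell_nodes[[ks[j]]] <- ix
      cell_of_node[ix] <- ks[j]
    }
    ii <- read_i32(file.path(gd, "ins_id.bin"))
    if (length(ii) > 0) {
      im <- unlist(jsonlite::read_json(file.path(gd, "ins_mech.json")))
      ig <- read_i32(file.path(gd, "ins_gid.bin"))
      ino <- read_i32(file.path(gd, "ins_node.bin"))
      ip <- read_f64(file.path(gd, "ins_params.bin"))
      off <- 0L
      for (j in seq_along(ii)) {
        spec <- get_mechanism(im[j])
        np <- length(spec$params)
        pv <- ip[off + seq_len(np)]; off <- off + np
        insertions[[ii[j]]] <- list(id = ii[j], mech = im[j], node = ino[j],
                                    gid = ig[j],
                                    params = stats::setNames(as.list(pv),
                                                             names(spec$params)))
      }
    }
    ni <- read_i32(file.path(gd, "nc_id.bin"))
    nc_src[ni] <- read_i32(file.path(gd, "nc_src.bin"))
    nc_tgt[ni] <- read_i32(file.path(gd, "nc_tgt.bin"))
    nc_w[ni] <- read_f64(file.path(gd, "nc_w.bin"))
    nc_dl[ni] <- read_f64(file.path(gd, "nc_delay.bin"))
    pr <- read_i32(file.path(gd, "presyn_row.bin"))
    ps_gid[pr] <- read_i32(file.path(gd, "presyn_gid.bin"))
    ps_watch[pr] <- read_i32(file.path(gd, "presyn_watch.bin"))
    ps_thr[pr] <- read_f64(file.path(gd, "presyn_thr.bin"))
  }

  nst <- as.integer(mf$n_netstims)
  ns_gid <- read_i32(file.path(path, "netstim_gid.bin"))
  np <- read_f64(file.path(path, "netstim_par.bin"))
  ns <- tibble::tibble(gid = ns_gid,
                       start = np[seq_len(nst)],
                       interval = np[nst + seq_len(nst)],
                       number = as.integer(np[2 * nst + seq_len(nst)]),
                       noise = np[3 * nst + seq_len(nst)],
                       seed = as.integer(np[4 * nst + seq_len(nst)]))

  model <- structure(list(
    n_nodes = n, parent = parent, area = area, cm_node = cmn, g_axial = gax,
    cell_of_node = cell_of_node,
    cells = tibble::tibble(gid = gid, type = type, group = grp,
                           n_nodes = nnv, offset = offv),
    cell_nodes = cell_nodes, insertions = insertions,
    netcons = tibble::tibble(src_gid = nc_src, syn_id = nc_tgt,
                             weight = nc_w, delay = nc_dl),
    presyns = tibble::tibble(gid = ps_gid,
                             watch_node = ifelse(ps_watch < 0, NA_integer_, ps_watch),
                             threshold = ps_thr),
    netstims = ns,
    meta = list(permutation = "none")
  ), class = "nc_model")
  if (!identical(model_digest(model), mf$model_digest))
    nc_stop("nc_archive_error", "decoded model digest does not match manifest")
  model
}

#' Save a checkpoint
#'
#' Stores the full in-memory state of the simulator at a step boundary:
#' voltages, mechanism states, watcher arming, stream counters, and the
#' pending events. Undelivered per-netcon delivery events are collapsed back
#' into their original source events, so each source spike is stored exactly
#' once as `(gid, spike_time)` no matter how many deliveries it still owes;
#' restore regenerates the deliveries by re-running the fan-out.
#'
#' @param state an `nc_state` at a step boundary.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  if (isTRUE(state$in_step))
    nc_stop("nc_state_error", "checkpoint requested mid-step")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  t_now <- sim_time(state)
  pend <- collapse_pending(state)
  write_f64(file.path(path, "v.bin"), state$v)
  write_i32(file.path(path, "armed.bin"), as.integer(state$ps_armed))
  write_f64(file.path(path, "scalars.bin"), c(state$dt, state$op_count))
  write_i32(file.path(path, "pend_gid.bin"), pend$gid)
  write_f64(file.path(path, "pend_t.bin"), pend$spike_time)
  pool_meta <- lapply(seq_along(state$pools), function(pid) {
    pool <- state$pools[[pid]]
    for (s in names(pool$states))
      write_f64(file.path(path, sprintf("pool_%03d_%s.bin", pid, s)),
                pool$states[[s]])
    list(mech = pool$mech, group = pool$group, count = pool$count,
         states = as.list(names(pool$states)))
  })
  netstim_next <- vapply(seq_along(state$netstim_times), function(j)
    sum(state$netstim_times[[j]] <= t_now + .nc_tol), integer(1))
  manifest <- list(format = "neurocable-checkpoint", version = 1L,
                   step_index = state$step_index,
                   model_digest = model_digest(state$model),
                   n_nodes = state$model$n_nodes,
                   n_pending = nrow(pend),
                   netstim_next = as.list(netstim_next),
                   pools = pool_meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a checkpoint into a model
#'
#' Rebuilds simulator state from the archive and re-issues pending
#' deliveries from the collapsed source events (deliveries already due at or
#' before the checkpoint time are dropped). Continuing the run reproduces
#' the uninterrupted simulation bit-identically; alternatively a different
#' stimulus stream may be supplied to explore divergent continuations.
#'
#' @param path checkpoint directory.
#' @param model the `nc_model` the checkpoint was taken from.
#' @param netstim_seed optional replacement seed for the stimulus streams;
#'   only events after the checkpoint time are affected.
#' @return an `nc_state` ready to [run()].
#' @export
restore_checkpoint <- function(path, model, netstim_seed = NULL) {
  mf <- read_manifest(path, "neurocable-checkpoint")
  if (!identical(mf$model_digest, model_digest(model)))
    nc_stop("nc_integrity_error", "checkpoint does not match this model")
  sc <- read_f64(file.path(path, "scalars.bin"))
  st <- init_state(model, dt = sc[1])
  st$step_index <- as.integer(mf$step_index)
  st$op_count <- sc[2]
  t_now <- sim_time(st)
  v <- read_f64(file.path(path, "v.bin"))
  if (length(v) != model$n_nodes)
    nc_stop("nc_integrity_error", "checkpoint node count %d != model %d",
            length(v), model$n_nodes)
  st$v <- v
  st$ps_armed <- read_i32(file.path(path, "armed.bin")) == 1L
  if (length(mf$pools) != length(st$pools))
    nc_stop("nc_integrity_error", "checkpoint pool layout does not match model")
  for (pid in seq_along(st$pools)) {
    pm <- mf$pools[[pid]]
    pool <- st$pools[[pid]]
    if (!identical(pm$mech, pool$mech) || !identical(as.integer(pm$count), pool$count))
      nc_stop("nc_integrity_error", "checkpoint pool %d (%s) does not match model",
              pid, pm$mech)
    for (s in names(pool$states))
      pool$states[[s]] <- read_f64(file.path(path, sprintf("pool_%03d_%s.bin", pid, s)))
    st$pools[[pid]] <- pool
  }
  if (!is.null(netstim_seed) && nrow(model$netstims) > 0) {
    st$netstim_times <- lapply(seq_len(nrow(model$netstims)), function(j) {
      r <- model$netstims[j, ]
      netstim_events(r$start, r$interval, r$number, r$noise,
                     make_stream_key(netstim_seed, r$gid, "netstim"))
    })
  }
  st$last_pull <- t_now
  pg <- read_i32(file.path(path, "pend_gid.bin"))
  pt <- read_f64(file.path(path, "pend_t.bin"))
  for (k in seq_along(pg)) {
    ncs <- st$netcons_by_src[[as.character(pg[k])]]
    if (is.null(ncs)) next
    nc <- model$netcons[ncs, ]
    due <- pt[k] + nc$delay
    keep <- due > t_now + .nc_tol
    st$q_time <- c(st$q_time, due[keep])
    st$q_src <- c(st$q_src, nc$src_gid[keep])
    st$q_nc <- c(st$q_nc, ncs[keep])
    st$q_srct <- c(st$q_srct, rep(pt[k], sum(keep)))
  }
  st
}
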