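#' Declare an unbranched cable section
#'
#' A section is an unbranched cable with uniform geometry and passive
#' parameters; a cell is a rooted tree of sections. Discretization splits a
#' section into `nseg` compartments (nodes), each carrying one membrane
#' potential unknown at its center.
#'
#' @param id integer section id, unique within a cell.
#' @param length section length, um (> 0).
#' @param diam diameter, um (> 0).
#' @param nseg number of compartments (>= 1).
#' @param Ra axial resistivity, ohm cm (> 0).
#' @param cm specific membrane capacitance, uF/cm^2 (> 0).
#' @param parent_section id of a previously declared section, or `NA` for the
#'   root section (exactly one per cell).
#' @param parent_x normalized attachment position on the parent section in
#'   `[0, 1]`; the child's first node attaches to the parent node containing
#'   that position (rounding down).
#' @return a `section_spec` list.
#' @export
section_spec <- function(id, length, diam, nseg = 1L, Ra = 100, cm = 1,
                         parent_section = NA, parent_x = 1) {
  nseg <- as.integer(nseg)
  if (!is.finite(length) || length <= 0 || !is.finite(diam) || diam <= 0 ||
      is.na(nseg) || nseg < 1 || !is.finite(Ra) || Ra <= 0 ||
      !is.finite(cm) || cm <= 0)
    nc_stop("nc_geometry_error",
            "section %s: length, diam, Ra, cm must be > 0 and nseg >= 1", id)
  if (!is.na(parent_section) && identical(parent_section, id))
    nc_stop("nc_topology_error", "section %s is its own parent", id)
  if (parent_x < 0 || parent_x > 1)
    nc_stop("nc_geometry_error", "section %s: parent_x must be in [0,1]", id)
  structure(list(id = id, length = length, diam = diam, nseg = nseg,
                 Ra = Ra, cm = cm, parent_section = parent_section,
                 parent_x = parent_x),
            class = "section_spec")
}

#' Discretize a section into compartment geometry
#'
#' Each of the `nseg` nodes covers `dx = length/nseg` um of cable. Units are
#' fixed so that uS * mV = nA and nF * mV/ms = nA with no per-step conversion:
#' membrane area `pi * diam * dx` (um^2), node capacitance
#' `cm * area * 1e-5` (nF), and axial conductance between adjacent nodes
#' `1e2 * pi * diam^2 / (4 * Ra * dx)` (uS).
#'
#' @param spec a [section_spec()].
#' @return tibble with one row per node: `dx`, `area` (um^2), `cm_node` (nF),
#'   `g_axial` (uS, conductance toward the previous node; used for the first
#'   node's attachment to its parent section as well).
#' @examples
#' discretize_section(section_spec(1, length = 20, diam = 20, nseg = 1))
#' @export
discretize_section <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  dx <- spec$length / spec$nseg
  area1 <- pi * spec$diam * dx
  g <- 1e2 * pi * spec$diam^2 / (4 * spec$Ra * dx)
  tibble::tibble(
    dx = rep(dx, spec$nseg),
    area = rep(area1, spec$nseg),
    cm_node = rep(spec$cm * area1 * 1e-5, spec$nseg),
    g_axial = rep(g, spec$nseg)
  )
}

#' Build a cell topology from section declarations
#'
#' Assigns node indices section by section in declaration order, so every
#' node's parent has a smaller index (root = node 1, parent sentinel 0). A
#' child section's first node attaches to the parent section's node nearest
#' its `parent_x` (rounding down); within a section node k's parent is node
#' k - 1.
#'
#' @param sections list of [section_spec()]; parents must be declared before
#'   children and exactly one section must have `parent_section = NA`.
#' @return an `nc_cell`: `n_nodes`, `parent` (1-based, 0 = root), `area`,
#'   `cm_node`, `g_axial` (0 at the root), `section_of_node`.
#' @export
build_cell <- function(sections) {
  if (length(sections) == 0)
    nc_stop("nc_topology_error", "build_cell: no sections")
  ids <- vapply(sections, `[[`, numeric(1), "id")
  if (anyDuplicated(ids))
    nc_stop("nc_topology_error", "build_cell: duplicate section ids")
  roots <- vapply(sections, function(s) is.na(s$parent_section), logical(1))
  if (sum(roots) != 1)
    nc_stop("nc_topology_error", "build_cell: expected exactly one root section, found %d",
            sum(roots))
  if (!roots[1])
    nc_stop("nc_topology_error", "build_cell: first section must be the root")

  first_node <- integer(length(sections))
  parent <- integer(0); area <- numeric(0); cmn <- numeric(0)
  gax <- numeric(0); secof <- integer(0)
  for (k in seq_along(sections)) {
    s <- sections[[k]]
    geo <- discretize_section(s)
    base <- length(parent)
    first_node[k] <- base + 1L
    if (is.na(s$parent_section)) {
      pfirst <- 0L
      g0 <- 0
    } else {
      pk <- match(s$parent_section, ids[seq_len(k - 1L)])
      if (is.na(pk))
        nc_stop("nc_topology_error",
                "section %s: parent %s not declared earlier", s$id, s$parent_section)
      pspec <- sections[[pk]]
      off <- min(floor(s$parent_x * pspec$nseg), pspec$nseg - 1L)
      pfirst <- first_node[pk] + as.integer(off)
      g0 <- geo$g_axial[1]
    }
    parent <- c(parent, pfirst, base + seq_len(s$nseg - 1L))
    area <- c(area, geo$area)
    cmn <- c(cmn, geo$cm_node)
    gax <- c(gax, g0, geo$g_axial[-1])
    secof <- c(secof, rep(as.integer(s$id), s$nseg))
  }
  cell <- structure(list(n_nodes = length(parent), parent = parent,
                         area = area, cm_node = cmn, g_axial = gax,
                         section_of_node = secof),
                    class = "nc_cell")
  diag <- validate_tree(parent)
  if (nrow(diag) > 0)
    nc_stop("nc_topology_error", "build_cell: invalid tree: %s", diag$message[1])
  cell
}

#' Diagnose a parent-index tree
#'
#' Pure check of the parent-before-child contract: reports the root count (a
#' diagnostic if different from `n_roots`), any node whose parent index is not
#' smaller than itself, and unreachable nodes. Valid trees return an empty
#' tibble.
#'
#' @param parent integer vector, 1-based with 0 marking roots.
#' @param n_roots expected number of roots (1 for a cell, number of cells for
#'   a flattened network).
#' @return tibble with columns `type`, `node`, `message`; zero rows iff valid.
#' @examples
#' validate_tree(c(0L, 1L, 1L))          # valid Y
#' validate_tree(c(0L, 3L, 1L))          # ordering violation at node 2
#' @export
validate_tree <- function(parent, n_roots = 1L) {
  parent <- as.integer(parent)
  n <- length(parent)
  out <- list()
  rc <- sum(parent == 0L)
  if (rc != n_roots)
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "root_count", node = NA_integer_,
      message = sprintf("%d roots found, expected %d", rc, n_roots))
  bad <- which(parent != 0L & (parent >= seq_len(n) | parent < 0L))
  for (i in bad)
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "ordering", node = i,
      message = sprintf("node %d has parent %d >= %d", i, parent[i], i))
  reach <- parent == 0L
  ok <- parent >= 0L & parent < seq_len(n)
  for (i in seq_len(n))
    if (!reach[i] && ok[i] && parent[i] > 0L && reach[parent[i]]) reach[i] <- TRUE
  un <- which(!reach & !(seq_len(n) %in% bad))
  for (i in un)
    out[[length(out) + 1L]] <- tibble::tibble(
      type = "unreachable", node = i,
      message = sprintf("node %d is not reachable from a root", i))
  if (length(out) == 0)
    tibble::tibble(type = character(), node = integer(), message = character())
  else do.call(rbind, out)
}
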