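#' Construct and validate an AOP graph
#'
#' An adverse outcome pathway (AOP) is represented as a directed acyclic
#' graph whose nodes are the dose root, molecular initiating events (MIE),
#' acute- and chronic-phase key events (KE), biomarkers (BM), and a single
#' adverse outcome (AO). Edges point from cause to effect. The graph supplies
#' parent sets and a stable topological order to every model in the package.
#'
#' Validation enforces: exactly one `DOSE` and one `AO` node; `DOSE` has no
#' parents and `AO` no children; phases consistent with roles (`MIE`,
#' `ACUTE_KE` and `BM` are acute, `CHRONIC_KE` and `AO` chronic, `DOSE` has
#' phase `"none"`); no cycles; every non-dose node reachable from `DOSE`.
#'
#' @param nodes data frame with columns `name`, `role` (one of `DOSE`, `MIE`,
#'   `ACUTE_KE`, `CHRONIC_KE`, `BM`, `AO`) and optionally `phase` (derived
#'   from the role when absent).
#' @param edges two-column data frame or matrix of `(parent, child)` pairs.
#' @return An object of class `aop_graph` with elements `nodes`, `edges`,
#'   `parents` (list, in edge input order), `topo` (topological order),
#'   `bio_nodes` (all nodes except `DOSE`).
#' @seealso [canonical_aop()], [read_aop()], [parents()], [reachable_to_ao()]
#' @export
aop_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  roles <- c("DOSE", "MIE", "ACUTE_KE", "CHRONIC_KE", "BM", "AO")
  if (!all(c("name", "role") %in% names(nodes))) {
    qaop_stop("qaop_role_error", "nodes must have 'name' and 'role' columns")
  }
  if (anyDuplicated(nodes$name)) {
    qaop_stop("qaop_role_error", "duplicated node names")
  }
  if (!all(nodes$role %in% roles)) {
    qaop_stop("qaop_role_error", "unknown role(s): %s",
              paste(setdiff(nodes$role, roles), collapse = ", "))
  }
  phase_of <- c(DOSE = "none", MIE = "acute", ACUTE_KE = "acute", BM = "acute",
                CHRONIC_KE = "chronic", AO = "chronic")
  if (is.null(nodes$phase)) {
    nodes$phase <- unname(phase_of[nodes$role])
  } else if (!all(nodes$phase == phase_of[nodes$role])) {
    qaop_stop("qaop_role_error", "node phase inconsistent with role")
  }
  if (sum(nodes$role == "DOSE") != 1L) {
    qaop_stop("qaop_role_error", "graph must contain exactly one DOSE node")
  }
  if (sum(nodes$role == "AO") != 1L) {
    qaop_stop("qaop_role_error", "graph must contain exactly one AO node")
  }

  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges <- stats::setNames(as.data.frame(edges[, 1:2], stringsAsFactors = FALSE),
                           c("parent", "child"))
  unknown <- setdiff(unique(c(edges$parent, edges$child)), nodes$name)
  if (length(unknown)) {
    qaop_stop("qaop_unknown_node_error", "edge endpoint(s) not in node list: %s",
              paste(unknown, collapse = ", "))
  }
  dose <- nodes$name[nodes$role == "DOSE"]
  ao <- nodes$name[nodes$role == "AO"]

  parents <- lapply(nodes$name, function(v) edges$parent[edges$child == v])
  names(parents) <- nodes$name

  topo <- topo_sort_kahn(nodes$name, edges)   # errors on cycles

  if (any(edges$child == dose)) {
    qaop_stop("qaop_role_error", "DOSE node must not have parents")
  }
  if (any(edges$parent == ao)) {
    qaop_stop("qaop_role_error", "AO node must not have children")
  }

  # every non-dose node reachable from DOSE
  reach <- dose
  repeat {
    nxt <- unique(c(reach, edges$child[edges$parent %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!all(nodes$name %in% reach)) {
    qaop_stop("qaop_role_error", "node(s) not reachable from DOSE: %s",
              paste(setdiff(nodes$name, reach), collapse = ", "))
  }

  structure(list(
    nodes = nodes, edges = edges, parents = parents, topo = topo,
    dose_node = dose, ao_node = ao,
    bio_nodes = nodes$name[nodes$role != "DOSE"]
  ), class = "aop_graph")
}

# Kahn's algorithm with stable tie-break by input node order.
topo_sort_kahn <- function(names, edges) {
  indeg <- stats::setNames(integer(length(names)), names)
  tab <- table(factor(edges$child, levels = names))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- names[indeg == 0L]
  indeg_left <- indeg
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges_left$child[edges_left$parent == v]
    edges_left <- edges_left[edges_left$parent != v, , drop = FALSE]
    for (u in ch) {
      indeg_left[u] <- indeg_left[u] - 1L
      if (indeg_left[u] == 0L) avail <- c(avail, u)
    }
    avail <- names[names %in% avail]   # keep stable input order
  }
  if (length(out) != length(names)) {
    qaop_stop("qaop_cycle_error", "graph contains a cycle involving: %s",
              paste(setdiff(names, out), collapse = ", "))
  }
  out
}

#' Parent set of a node
#'
#' Returns the parents of `node` in the order the defining edges were listed.
#'
#' @param graph an [aop_graph()].
#' @param node node name.
#' @return Character vector of parent names (possibly empty).
#' @export
parents <- function(graph, node) {
  stopifnot(inherits(graph, "aop_graph"))
  if (!node %in% graph$nodes$name) {
    qaop_stop("qaop_unknown_node_error", "unknown node '%s'", node)
  }
  graph$parents[[node]]
}

#' Topological order of the biology nodes
#'
#' @param graph an [aop_graph()].
#' @param include_dose keep the dose root in the ordering?
#' @return Character vector of node names, causes before effects.
#' @export
topo_order <- function(graph, include_dose = TRUE) {
  stopifnot(inherits(graph, "aop_graph"))
  if (include_dose) graph$topo else setdiff(graph$topo, graph$dose_node)
}

#' Nodes with a directed path to the adverse outcome
#'
#' Used by the data-driven pruning step: after edges are dropped, a node is
#' only retained when at least one directed path to the AO remains.
#'
#' @param graph an [aop_graph()].
#' @param active_edges two-column data frame of active `(parent, child)`
#'   edges; must be a subset of `graph$edges`. Defaults to all edges.
#' @return Character vector of node names (in graph order) from which the AO
#'   can be reached using only active edges. The AO itself is always included.
#' @export
reachable_to_ao <- function(graph, active_edges = graph$edges) {
  stopifnot(inherits(graph, "aop_graph"))
  if (is.matrix(active_edges)) {
    active_edges <- as.data.frame(active_edges, stringsAsFactors = FALSE)
  }
  active_edges <- stats::setNames(
    as.data.frame(active_edges, stringsAsFactors = FALSE)[, 1:2, drop = FALSE],
    c("parent", "child"))
  key <- function(e) paste(e$parent, e$child, sep = "\r")
  if (nrow(active_edges) && !all(key(active_edges) %in% key(graph$edges))) {
    qaop_stop("qaop_unknown_node_error",
              "active_edges must be a subset of the graph's edges")
  }
  reach <- graph$ao_node
  repeat {
    nxt <- unique(c(reach, active_edges$parent[active_edges$child %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  graph$nodes$name[graph$nodes$name %in% reach]
}

#' Lag of each node to the adverse outcome
#'
#' Shortest directed path length from each node to the AO. In the dynamic
#' Bayesian network this is the natural conditioning lag tau: a key event
#' observed at exposure `e - tau` can influence the AO at exposure `e`
#' through `tau` slice transitions.
#'
#' @param graph an [aop_graph()].
#' @return Named integer vector; `NA` for nodes with no path to the AO
#'   (never the case in a validated graph), 0 for the AO itself.
#' @export
ao_lag <- function(graph) {
  stopifnot(inherits(graph, "aop_graph"))
  lag <- stats::setNames(rep(NA_integer_, nrow(graph$nodes)), graph$nodes$name)
  lag[graph$ao_node] <- 0L
  frontier <- graph$ao_node
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    frontier <- unique(graph$edges$parent[graph$edges$child %in% frontier])
    frontier <- frontier[is.na(lag[frontier])]
    lag[frontier] <- k
  }
  lag
}

#' The canonical 20-node AOP used throughout the package
#'
#' Two molecular initiating events each produce two receptor ligands
#' (BM1--BM4) that converge on receptor activation (KE1). KE1 drives a
#' signal-transduction cascade BM5 -> BM6 -> BM7 -> BM8, whose product feeds
#' both the chronic-phase branch head KE2 and the acute-phase KE3. KE2 fans
#' out to the chronic key events KE4, KE5 and KE6; KE3 drives the chronic
#' KE7. KE4--KE7 converge on KE8, which causes the adverse outcome. The dose
#' root feeds the two MIEs. This yields 19 biology nodes (12 acute-phase,
#' 7 chronic-phase counting the AO) and lags to the AO of 1 for KE8, 2 for
#' KE4--KE7, and 3 for KE2 and KE3.
#'
#' @return An [aop_graph()].
#' @export
canonical_aop <- function() {
  nodes <- data.frame(
    name = c("DOSE", "MIE1", "MIE2", paste0("BM", 1:8), "KE1", "KE3",
             "KE2", paste0("KE", 4:8), "AO"),
    role = c("DOSE", "MIE", "MIE", rep("BM", 8), "ACUTE_KE", "ACUTE_KE",
             rep("CHRONIC_KE", 6), "AO"),
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    c("DOSE", "MIE1"), c("DOSE", "MIE2"),
    c("MIE1", "BM1"), c("MIE1", "BM2"),
    c("MIE2", "BM3"), c("MIE2", "BM4"),
    c("BM1", "KE1"), c("BM2", "KE1"), c("BM3", "KE1"), c("BM4", "KE1"),
    c("KE1", "BM5"), c("BM5", "BM6"), c("BM6", "BM7"), c("BM7", "BM8"),
    c("BM8", "KE2"), c("BM8", "KE3"),
    c("KE2", "KE4"), c("KE2", "KE5"), c("KE2", "KE6"),
    c("KE3", "KE7"),
    c("KE4", "KE8"), c("KE5", "KE8"), c("KE6", "KE8"), c("KE7", "KE8"),
    c("KE8", "AO")
  )
  aop_graph(nodes, edges)
}

#' Read or write an AOP graph as JSON
#'
#' The on-disk dialect is `{"nodes": [{"name", "role", "phase"}, ...],
#' "edges": [["parent", "child"], ...]}`. `write_aop()` emits the same
#' dialect, so a save/load round trip reproduces an identical graph.
#'
#' @param path file path.
#' @return `read_aop()` returns a validated [aop_graph()]; `write_aop()`
#'   returns `path` invisibly.
#' @export
read_aop <- function(path) {
  src <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  edges <- src$edges
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  }
  aop_graph(src$nodes, edges)
}

#' @rdname read_aop
#' @param graph an [aop_graph()].
#' @export
write_aop <- function(graph, path) {
  stopifnot(inherits(graph, "aop_graph"))
  obj <- list(nodes = graph$nodes,
              edges = unname(as.matrix(graph$edges)))
  jsonlite::write_json(obj, path, dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

#' @export
print.aop_graph <- function(x, ...) {
  cat(sprintf("AOP graph: %d nodes (%d biology), %d edges\n",
              nrow(x$nodes), length(x$bio_nodes), nrow(x$edges)))
  cat(sprintf("  dose root: %s; adverse outcome: %s\n", x$dose_node, x$ao_node))
  cat(sprintf("  chronic-phase nodes: %s\n",
              paste(x$nodes$name[x$nodes$phase == "chronic"], collapse = ", ")))
  invisible(x)
}

# Internal: chronic-phase biology nodes.
chronic_nodes <- function(graph) {
  graph$nodes$name[graph$nodes$phase == "chronic"]
}

# Internal: biology parents only (dose root stripped), named list.
bio_parents <- function(graph) {
  lapply(graph$parents[graph$bio_nodes],
         function(p) setdiff(p, graph$dose_node))
}
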