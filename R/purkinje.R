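# Fascicular His-Purkinje network.  The tree is grown on the endocardial
# surfaces of a labelled mesh: the His trunk descends the RV septal
# endocardium, crosses to the LV side where the left bundle splits into the
# anterior, septal and posterior fascicles, and the right bundle continues to
# a septal fascicle and a free-running moderator band.  Fascicle trunks
# follow mesh geodesics between UVC targets; peripheral arbors are
# shortest-path trees to seeded target nodes in each fascicle's UVC
# territory, terminating in Purkinje-myocardial junctions (PMJs).

#' Purkinje branch labels
#' @export
BRANCH_LEVELS <- c("HIS", "LEFT_BUNDLE", "LV_ANTERIOR_FASCICLE",
                   "LV_SEPTAL_FASCICLE", "LV_POSTERIOR_FASCICLE",
                   "RIGHT_BUNDLE", "RV_SEPTAL_FASCICLE", "RV_MODERATOR_BAND",
                   "PERIPHERAL")

#' Purkinje tree construction parameters
#'
#' Trunk waypoints and fascicle territories are given in universal
#' ventricular coordinates (apicobasal rho, rotational phi); the defaults
#' place the His bundle high on the septum (rho 0.92 to 0.85), the
#' fascicle plunge sites at rho 0.78 with the anterior/posterior fascicles
#' at phi +/-0.95 rad from the septal centre, and the arbor territories over
#' the mid/apical endocardium.
#'
#' @param min_pmjs_per_fascicle minimum number of junctions per fascicle.
#' @param seed integer seed for the arbor target sampling.
#' @param rho_his,rho_junction,rho_split,rho_mb_takeoff,rho_territory_centre
#'   apicobasal waypoints of the trunks.
#' @param phi_anterior,phi_posterior rotational positions of the LV
#'   anterior/posterior fascicle plunge routes (rad).
#' @param territories named list of per-fascicle territory definitions
#'   (surface tag, rho range, phi range); NULL for the defaults.
#' @param pmj_delay_antero,pmj_delay_retro per-PMJ delays stored on the
#'   tree (ms); NA means inherit from the conduction config at solve time.
#' @param cv_tree tree conduction velocity stored on the tree (m/s).
#' @return list of class `tree_params`.
#' @export
tree_params <- function(min_pmjs_per_fascicle = 40, seed = 1,
                        rho_his = 0.92, rho_junction = 0.85,
                        rho_split = 0.78, rho_mb_takeoff = 0.74,
                        rho_territory_centre = 0.40,
                        phi_anterior = 0.95, phi_posterior = -0.95,
                        territories = NULL,
                        pmj_delay_antero = NA_real_,
                        pmj_delay_retro = NA_real_,
                        cv_tree = 3) {
  if (is.null(territories))
    territories <- list(
      LV_ANTERIOR_FASCICLE  = list(surface = "LV_ENDO",
                                   rho = c(0.12, 0.75), phi = c(0.5, 2.6)),
      LV_SEPTAL_FASCICLE    = list(surface = "LV_ENDO",
                                   rho = c(0.10, 0.65), phi = c(-0.45, 0.45)),
      LV_POSTERIOR_FASCICLE = list(surface = "LV_ENDO",
                                   rho = c(0.12, 0.75), phi = c(-2.6, -0.5)),
      RV_SEPTAL_FASCICLE    = list(surface = "RV_ENDO_SEPTAL",
                                   rho = c(0.10, 0.65), phi = c(-0.6, 0.6)),
      RV_MODERATOR_BAND     = list(surface = "RV_ENDO_FREEWALL",
                                   rho = c(0.08, 0.75), phi = c(-pi, pi)))
  structure(list(min_pmjs_per_fascicle = min_pmjs_per_fascicle, seed = seed,
                 rho_his = rho_his, rho_junction = rho_junction,
                 rho_split = rho_split, rho_mb_takeoff = rho_mb_takeoff,
                 rho_territory_centre = rho_territory_centre,
                 phi_anterior = phi_anterior, phi_posterior = phi_posterior,
                 territories = territories,
                 pmj_delay_antero = pmj_delay_antero,
                 pmj_delay_retro = pmj_delay_retro, cv_tree = cv_tree),
            class = "tree_params")
}

#' Construct a Purkinje tree object
#'
#' @param nodes M x 3 matrix of node positions (mm).
#' @param edges data.frame with columns a, b (node ids), len (mm), branch,
#'   fascicle, blocked.
#' @param root id of the His-origin node.
#' @param pmjs data.frame with columns tree_node, mesh_node, delay_antero,
#'   delay_retro, fascicle.
#' @param anchor integer mesh-node anchor per tree node (NA if free).
#' @param cv_tree conduction velocity (m/s).
#' @return object of class `purkinje_tree`.
#' @export
purkinje_tree <- function(nodes, edges, root = 1L, pmjs = NULL,
                          anchor = NULL, cv_tree = 3) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  if (is.null(pmjs))
    pmjs <- data.frame(tree_node = integer(), mesh_node = integer(),
                       delay_antero = numeric(), delay_retro = numeric(),
                       fascicle = character())
  if (is.null(anchor)) anchor <- rep(NA_integer_, nrow(nodes))
  if (is.null(edges$blocked)) edges$blocked <- FALSE
  if (is.null(edges$fascicle)) edges$fascicle <- edges$branch
  d <- nodes[edges$a, , drop = FALSE] - nodes[edges$b, , drop = FALSE]
  elen <- sqrt(rowSums(d * d))
  if (is.null(edges$len)) edges$len <- elen
  else if (any(abs(edges$len - elen) > 1e-6))
    stop("edge lengths disagree with node positions by more than 1e-6 mm")
  structure(list(nodes = nodes, edges = edges, root = as.integer(root),
                 pmjs = pmjs, anchor = anchor, cv_tree = cv_tree),
            class = "purkinje_tree")
}

#' @export
print.purkinje_tree <- function(x, ...) {
  cat("His-Purkinje tree:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", nrow(x$pmjs), "PMJs,", sum(x$edges$blocked),
      "blocked edges\n")
  tb <- table(x$edges$branch)
  cat("  branches:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate Purkinje tree invariants
#'
#' Connectivity (ignoring lesions), a single root, PMJ tree nodes being
#' leaves, and edge lengths matching node positions.
#' @param tree a `purkinje_tree`.
#' @return TRUE invisibly; stops on violation.
#' @export
validate_tree <- function(tree) {
  g <- igraph::make_graph(rbind(tree$edges$a, tree$edges$b),
                          n = nrow(tree$nodes), directed = FALSE)
  if (igraph::components(g)$no != 1L)
    stop("tree is not connected (before lesions)")
  if (length(tree$root) != 1L) stop("tree must have exactly one root")
  deg <- igraph::degree(g)
  if (nrow(tree$pmjs) && any(deg[tree$pmjs$tree_node] != 1L))
    stop("some PMJ tree nodes are not leaves")
  d <- tree$nodes[tree$edges$a, , drop = FALSE] -
       tree$nodes[tree$edges$b, , drop = FALSE]
  if (any(abs(sqrt(rowSums(d * d)) - tree$edges$len) > 1e-6))
    stop("edge length inconsistent with node positions")
  invisible(TRUE)
}

# --- surface graph machinery -------------------------------------------------

.surface_nodes <- function(mesh, tag) {
  s <- mesh$surface
  if (is.null(s)) stop("mesh has no classified surface")
  sort(unique(as.vector(s$faces[s$tag %in% tag, ])))
}

# induced edge table of the mesh edge graph on a surface node set
.surface_edges <- function(mesh, set) {
  ed <- mesh_edges(mesh)$edges
  inset <- logical(nrow(mesh$nodes)); inset[set] <- TRUE
  ed[inset[ed$i] & inset[ed$j], , drop = FALSE]
}

# distances + shortest-path-tree parents from one source over an edge table
.spt <- function(n, ed, source) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, c(rbind(ed$i, ed$j)))
  d <- igraph::distances(g, v = source, weights = ed$len,
                         algorithm = "dijkstra")[1, ]
  parent <- rep(NA_integer_, n)
  # a node's parent is the lowest-index neighbour on a tight edge
  for (dir in 1:2) {
    u <- if (dir == 1) ed$i else ed$j
    v <- if (dir == 1) ed$j else ed$i
    tight <- which(is.finite(d[u]) & abs(d[u] + ed$len - d[v]) < 1e-9)
    if (length(tight)) {
      o <- order(v[tight], u[tight])
      t1 <- tight[o][!duplicated(v[tight][o])]
      vv <- v[t1]
      upd <- is.na(parent[vv]) | u[t1] < parent[vv]
      parent[vv[upd]] <- u[t1][upd]
    }
  }
  parent[source] <- 0L
  list(dist = d, parent = parent)
}

# walk parents from each target, returning the union path edges (a, b)
.chains <- function(spt, targets) {
  seen <- integer(0)
  ea <- integer(0); eb <- integer(0)
  seen_set <- new.env(hash = TRUE)
  for (t in targets) {
    v <- t
    while (!is.na(spt$parent[v]) && spt$parent[v] > 0L) {
      key <- as.character(v)
      if (!is.null(seen_set[[key]])) break
      seen_set[[key]] <- TRUE
      ea <- c(ea, spt$parent[v]); eb <- c(eb, v)
      v <- spt$parent[v]
    }
  }
  data.frame(a = ea, b = eb)
}

.nearest_uvc <- function(uvc, candidates, rho, phi) {
  d2 <- (uvc$rho[candidates] - rho)^2 + ((uvc$phi[candidates] - phi) / pi)^2
  candidates[order(d2, candidates)[1]]
}

# --- tree construction -------------------------------------------------------

#' Build the fascicular His-Purkinje network on a heart mesh
#'
#' See [tree_params()] for the layout knobs.  Deterministic given the
#' parameter seed.  Tree nodes are anchored to mesh nodes except where a
#' segment runs freely (none in the default construction; the moderator band
#' runs freely but is anchored at both ends).
#'
#' @param mesh a `tet_mesh` with classified surfaces.
#' @param uvc matching `uvc` coordinates.
#' @param params a [tree_params()].
#' @return a `purkinje_tree`.
#' @export
build_tree <- function(mesh, uvc, params = tree_params()) {
  if (is.null(mesh$surface)) stop("mesh has no surface tags")
  set.seed(params$seed)
  n <- nrow(mesh$nodes)

  reg <- new.env(hash = TRUE)   # mesh node id -> tree node id
  tn_anchor <- integer(0)
  tree_id <- function(mesh_node) {
    key <- as.character(mesh_node)
    id <- reg[[key]]
    if (is.null(id)) {
      tn_anchor[[length(tn_anchor) + 1L]] <<- mesh_node
      id <- length(tn_anchor)
      reg[[key]] <- id
    }
    id
  }
  # union-find for cycle-free insertion
  uf <- integer(0)
  uf_find <- function(x) {
    while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }
    x
  }
  ea <- integer(0); eb <- integer(0); ebr <- character(0); efa <- character(0)
  add_edge <- function(ta, tb, branch, fascicle) {
    m <- max(ta, tb)
    if (m > length(uf)) uf[(length(uf) + 1L):m] <<- (length(uf) + 1L):m
    ra <- uf_find(ta); rb <- uf_find(tb)
    if (ra == rb) return(invisible(FALSE))  # already connected: skip
    uf[ra] <<- rb
    ea[[length(ea) + 1L]] <<- ta; eb[[length(eb) + 1L]] <<- tb
    ebr[[length(ebr) + 1L]] <<- branch; efa[[length(efa) + 1L]] <<- fascicle
    invisible(TRUE)
  }
  add_path <- function(mesh_path, branch, fascicle = branch) {
    if (length(mesh_path) < 2) return(invisible(NULL))
    ids <- vapply(mesh_path, tree_id, integer(1))
    for (k in seq_len(length(ids) - 1L))
      add_edge(ids[k], ids[k + 1L], branch, fascicle)
  }

  surf_sets <- list(
    LV_ENDO = .surface_nodes(mesh, "LV_ENDO"),
    RV_ENDO_SEPTAL = .surface_nodes(mesh, "RV_ENDO_SEPTAL"),
    RV_ENDO_FREEWALL = .surface_nodes(mesh, "RV_ENDO_FREEWALL"))
  surf_ed <- lapply(surf_sets, function(set) .surface_edges(mesh, set))
  for (nm in names(surf_sets))
    if (!length(surf_sets[[nm]]))
      stop("no endocardial nodes tagged ", nm)

  path_between <- function(surface, from, to) {
    spt <- .spt(n, surf_ed[[surface]], from)
    if (!is.finite(spt$dist[to]))
      stop("no endocardial path on ", surface, " between requested points")
    ch <- .chains(spt, to)
    # chain is (parent, child) pairs from `to` back to `from`; rebuild order
    v <- to; path <- v
    while (!is.na(spt$parent[v]) && spt$parent[v] > 0L) {
      v <- spt$parent[v]; path <- c(v, path)
    }
    path
  }

  rvs <- surf_sets$RV_ENDO_SEPTAL
  lve <- surf_sets$LV_ENDO
  rvf <- surf_sets$RV_ENDO_FREEWALL

  his_root <- .nearest_uvc(uvc, rvs, params$rho_his, 0)
  junction <- .nearest_uvc(uvc, rvs, params$rho_junction, 0)
  add_path(path_between("RV_ENDO_SEPTAL", his_root, junction), "HIS")
  j_id <- tree_id(junction)

  # left bundle: transseptal crossing then descent to the split point
  lb0 <- .nearest_uvc(uvc, lve, params$rho_junction, 0)
  add_edge(j_id, tree_id(lb0), "LEFT_BUNDLE", "LEFT_BUNDLE")
  split_nd <- .nearest_uvc(uvc, lve, params$rho_split, 0)
  add_path(path_between("LV_ENDO", lb0, split_nd), "LEFT_BUNDLE")

  # right bundle: descent to the moderator-band take-off
  mb_takeoff <- .nearest_uvc(uvc, rvs, params$rho_mb_takeoff, 0)
  add_path(path_between("RV_ENDO_SEPTAL", junction, mb_takeoff),
           "RIGHT_BUNDLE")

  grow_fascicle <- function(fascicle, surface, origin_node, phi_f) {
    terr <- params$territories[[fascicle]]
    set <- surf_sets[[surface]]
    # trunk: along the basal corridor to phi_f, then plunge to the centre
    wp <- .nearest_uvc(uvc, set, uvc$rho[origin_node], phi_f)
    ctr <- .nearest_uvc(uvc, set, params$rho_territory_centre, phi_f)
    p1 <- path_between(surface, origin_node, wp)
    add_path(p1, fascicle)
    p2 <- path_between(surface, wp, ctr)
    add_path(p2, fascicle)
    # arbor: shortest-path tree from the territory centre to seeded targets
    cand <- set[uvc$rho[set] >= terr$rho[1] & uvc$rho[set] <= terr$rho[2] &
                uvc$phi[set] >= terr$phi[1] & uvc$phi[set] <= terr$phi[2]]
    cand <- setdiff(cand, ctr)
    if (!length(cand))
      stop("fascicle territory has no reachable endocardial nodes: ", fascicle)
    k <- min(length(cand), ceiling(1.5 * params$min_pmjs_per_fascicle))
    targets <- sort(sample(cand, k))
    spt <- .spt(n, surf_ed[[surface]], ctr)
    targets <- targets[is.finite(spt$dist[targets])]
    extra <- setdiff(cand[is.finite(spt$dist[cand])], targets)
    add_chains <- function(tgts) {
      ch <- .chains(spt, sort(tgts))
      for (r in seq_len(nrow(ch)))
        add_edge(tree_id(ch$a[r]), tree_id(ch$b[r]), "PERIPHERAL", fascicle)
    }
    # leaves judged against the whole tree built so far, so targets landing
    # on a trunk or on another target's path are not counted
    current_leaves <- function(tgts) {
      ids <- vapply(tgts, tree_id, integer(1))
      deg <- tabulate(c(ea, eb), nbins = length(tn_anchor))
      tgts[deg[ids] == 1L]
    }
    add_chains(targets)
    leaves <- current_leaves(targets)
    while (length(leaves) < params$min_pmjs_per_fascicle && length(extra)) {
      take <- utils::head(extra, params$min_pmjs_per_fascicle - length(leaves))
      extra <- setdiff(extra, take)
      add_chains(take)
      targets <- c(targets, take)
      leaves <- current_leaves(targets)
    }
    if (!length(leaves))
      stop("fascicle territory has no reachable endocardial nodes: ", fascicle)
    data.frame(mesh_node = sort(leaves), fascicle = fascicle)
  }

  split_id_node <- split_nd
  pmj_list <- list(
    grow_fascicle("LV_ANTERIOR_FASCICLE", "LV_ENDO", split_id_node,
                  params$phi_anterior),
    grow_fascicle("LV_SEPTAL_FASCICLE", "LV_ENDO", split_id_node, 0),
    grow_fascicle("LV_POSTERIOR_FASCICLE", "LV_ENDO", split_id_node,
                  params$phi_posterior),
    grow_fascicle("RV_SEPTAL_FASCICLE", "RV_ENDO_SEPTAL", mb_takeoff, 0))

  # moderator band: free-running edge to the RV free wall, then its arbor
  mb_anchor <- .nearest_uvc(uvc, rvf, 0.45, 0.3)
  add_edge(tree_id(mb_takeoff), tree_id(mb_anchor),
           "RV_MODERATOR_BAND", "RV_MODERATOR_BAND")
  pmj_list[[length(pmj_list) + 1L]] <-
    grow_fascicle("RV_MODERATOR_BAND", "RV_ENDO_FREEWALL", mb_anchor, 0.3)

  pmj_df <- do.call(rbind, pmj_list)
  nodes <- mesh$nodes[tn_anchor, , drop = FALSE]
  edges <- data.frame(a = ea, b = eb, branch = ebr, fascicle = efa,
                      blocked = FALSE)
  pmjs <- data.frame(
    tree_node = vapply(pmj_df$mesh_node, tree_id, integer(1)),
    mesh_node = pmj_df$mesh_node,
    delay_antero = params$pmj_delay_antero,
    delay_retro = params$pmj_delay_retro,
    fascicle = pmj_df$fascicle)
  tree <- purkinje_tree(nodes, edges, root = tree_id(his_root), pmjs = pmjs,
                        anchor = tn_anchor, cv_tree = params$cv_tree)
  # PMJ leaves only: drop junctions that ended up on a through-path
  g <- igraph::make_graph(rbind(tree$edges$a, tree$edges$b),
                          n = nrow(tree$nodes), directed = FALSE)
  deg <- igraph::degree(g)
  tree$pmjs <- tree$pmjs[deg[tree$pmjs$tree_node] == 1L, , drop = FALSE]
  rownames(tree$pmjs) <- NULL
  tree
}

# --- lesions -----------------------------------------------------------------

#' Apply a proximal left bundle branch block
#'
#' Marks the single edge joining the His trunk to the left bundle as blocked
#' in both directions; right-bundle conduction is unaffected.  Idempotent.
#'
#' @param tree a `purkinje_tree`.
#' @return the lesioned tree.
#' @export
apply_lbbb <- function(tree) {
  his_nodes <- unique(c(tree$edges$a[tree$edges$branch == "HIS"],
                        tree$edges$b[tree$edges$branch == "HIS"]))
  cand <- which(tree$edges$branch == "LEFT_BUNDLE" &
                (tree$edges$a %in% his_nodes | tree$edges$b %in% his_nodes))
  if (length(cand) != 1L)
    stop("could not identify a unique His-to-left-bundle junction edge (",
         length(cand), " candidates)")
  tree$edges$blocked[cand] <- TRUE
  tree
}

#' Deactivate Purkinje fibres overlapping a scar core
#'
#' Every tree edge whose midpoint lies inside a scar-core element is blocked
#' bidirectionally (point-in-tetrahedron test, boundary ties resolved to the
#' core), and PMJs anchored to mesh nodes fully inside the core (no
#' conducting incident element) are removed.  An empty overlap leaves the
#' tree unchanged.
#'
#' @param tree a `purkinje_tree`.
#' @param scar a `scar_region` (see [map_scar()]).
#' @param mesh,uvc the heart geometry the scar was mapped on.
#' @return the lesioned tree.
#' @export
deactivate_scar_overlap <- function(tree, scar, mesh, uvc) {
  core <- scar$core
  if (!length(core)) return(tree)
  mid <- (tree$nodes[tree$edges$a, , drop = FALSE] +
          tree$nodes[tree$edges$b, , drop = FALSE]) / 2
  inside <- points_in_elements(mid, mesh, core)
  tree$edges$blocked <- tree$edges$blocked | inside
  # remove junctions anchored inside the core
  core_only <- rep(TRUE, nrow(mesh$nodes))
  cond_elems <- setdiff(seq_len(nrow(mesh$tets)), core)
  core_only[unique(as.vector(mesh$tets[cond_elems, , drop = FALSE]))] <- FALSE
  keep <- !core_only[tree$pmjs$mesh_node]
  tree$pmjs <- tree$pmjs[keep, , drop = FALSE]
  rownames(tree$pmjs) <- NULL
  tree
}

#' Test points against a set of tetrahedral elements
#'
#' @param points p x 3 matrix.
#' @param mesh a `tet_mesh`.
#' @param elems element indices to test against.
#' @param tol boundary tolerance (points within `tol` of a face count as
#'   inside).
#' @return logical vector: point lies inside (or on the boundary of) at
#'   least one of the elements.
#' @export
points_in_elements <- function(points, mesh, elems, tol = 1e-9) {
  points <- matrix(points, ncol = 3)
  out <- logical(nrow(points))
  if (!length(elems) || !nrow(points)) return(out)
  tt <- mesh$tets[elems, , drop = FALSE]
  cen <- (mesh$nodes[tt[, 1], , drop = FALSE] +
          mesh$nodes[tt[, 2], , drop = FALSE] +
          mesh$nodes[tt[, 3], , drop = FALSE] +
          mesh$nodes[tt[, 4], , drop = FALSE]) / 4
  # circumscribing reach of an element (max vertex-centroid distance)
  reach <- sqrt(pmax(
    rowSums((mesh$nodes[tt[, 1], , drop = FALSE] - cen)^2),
    rowSums((mesh$nodes[tt[, 2], , drop = FALSE] - cen)^2),
    rowSums((mesh$nodes[tt[, 3], , drop = FALSE] - cen)^2),
    rowSums((mesh$nodes[tt[, 4], , drop = FALSE] - cen)^2)))
  rmax <- max(reach)
  for (p in seq_len(nrow(points))) {
    dx <- abs(cen[, 1] - points[p, 1]); if (all(dx > rmax)) next
    cand <- which(dx <= rmax & abs(cen[, 2] - points[p, 2]) <= rmax &
                  abs(cen[, 3] - points[p, 3]) <= rmax)
    if (!length(cand)) next
    cc <- cen[cand, , drop = FALSE]
    cand <- cand[(cc[, 1] - points[p, 1])^2 + (cc[, 2] - points[p, 2])^2 +
                 (cc[, 3] - points[p, 3])^2 <= reach[cand]^2]
    for (e in cand) {
      v <- mesh$nodes[tt[e, ], , drop = FALSE]
      tot <- det(cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ]))
      s <- numeric(4)
      for (k in 1:4) {
        w <- v; w[k, ] <- points[p, ]
        s[k] <- det(cbind(w[2, ] - w[1, ], w[3, ] - w[1, ], w[4, ] - w[1, ]))
      }
      if (all(sign(tot) * s >= -tol * abs(tot))) { out[p] <- TRUE; break }
    }
  }
  out
}

# --- tree solving and serialization -----------------------------------------

#' Activation times on the tree alone
#'
#' First-arrival times over unblocked tree edges at the tree conduction
#' velocity, from one or more stimulated tree nodes.
#'
#' @param tree a `purkinje_tree`.
#' @param sources integer tree-node vector (onset 0) or
#'   data.frame(node, onset).
#' @param cv_tree conduction velocity (m/s); defaults to the tree's.
#' @return numeric vector of per-tree-node times (ms, Inf if unreached).
#' @export
solve_tree <- function(tree, sources, cv_tree = tree$cv_tree) {
  src <- .as_sources(sources)
  te <- tree$edges[!tree$edges$blocked, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(tree$nodes), directed = FALSE)
  g <- igraph::add_edges(g, c(rbind(te$a, te$b)))
  dmat <- igraph::distances(g, v = src$node, weights = te$len / cv_tree,
                            algorithm = "dijkstra")
  as.numeric(do.call(pmin, lapply(seq_len(nrow(src)),
                                  function(k) src$onset[k] + dmat[k, ])))
}

#' Locate a node at a fractional distance along a branch
#'
#' Orders the nodes of the named branch by tree distance from the root and
#' returns the first node at or beyond `fraction` of the branch's total
#' path length.  Fraction 0 is the branch origin (for the left bundle, the
#' His junction node itself); any positive fraction is strictly distal to
#' the origin, so a proximal left-bundle site always lies beyond the
#' His-to-left-bundle junction edge that a proximal block severs.
#'
#' @param tree a `purkinje_tree`.
#' @param branch a branch label.
#' @param fraction number in [0, 1].
#' @return a tree node id.
#' @export
branch_node_at <- function(tree, branch, fraction = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  be <- tree$edges[tree$edges$branch == branch, , drop = FALSE]
  if (!nrow(be)) stop("no edges with branch label ", branch)
  # path distance from root over the whole (unlesioned) tree
  g <- igraph::make_graph(rbind(tree$edges$a, tree$edges$b),
                          n = nrow(tree$nodes), directed = FALSE)
  d <- igraph::distances(g, v = tree$root, weights = tree$edges$len)[1, ]
  bn <- unique(c(be$a, be$b))
  d0 <- min(d[bn]); d1 <- max(d[bn])
  target <- d0 + fraction * (d1 - d0)
  at_or_past <- bn[d[bn] >= target - 1e-9]
  at_or_past[order(d[at_or_past], at_or_past)][1]
}

#' Write / read a Purkinje tree as plain text
#'
#' Line-oriented format: a header, one node line per tree node (position and
#' mesh anchor), one edge line per edge (ids, branch, fascicle, block flag)
#' and one PMJ line per junction.
#'
#' @param tree a `purkinje_tree`.
#' @param path file path.
#' @return `write_tree` the path invisibly; `read_tree` a `purkinje_tree`.
#' @export
write_tree <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("purkinje_tree %d %d %d %d %.10g", nrow(tree$nodes),
                     nrow(tree$edges), nrow(tree$pmjs), tree$root,
                     tree$cv_tree), con)
  writeLines(sprintf("n %.10g %.10g %.10g %d", tree$nodes[, 1],
                     tree$nodes[, 2], tree$nodes[, 3],
                     ifelse(is.na(tree$anchor), -1L, tree$anchor)), con)
  writeLines(sprintf("e %d %d %.10g %s %s %d", tree$edges$a, tree$edges$b,
                     tree$edges$len, tree$edges$branch, tree$edges$fascicle,
                     as.integer(tree$edges$blocked)), con)
  if (nrow(tree$pmjs))
    writeLines(sprintf("p %d %d %.10g %.10g %s", tree$pmjs$tree_node,
                       tree$pmjs$mesh_node,
                       ifelse(is.na(tree$pmjs$delay_antero), -1,
                              tree$pmjs$delay_antero),
                       ifelse(is.na(tree$pmjs$delay_retro), -1,
                              tree$pmjs$delay_retro),
                       tree$pmjs$fascicle), con)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  ln <- readLines(path)
  hd <- strsplit(ln[1], " ")[[1]]
  if (hd[1] != "purkinje_tree") stop("not a purkinje_tree file: ", path)
  nn <- as.integer(hd[2]); ne <- as.integer(hd[3]); np <- as.integer(hd[4])
  root <- as.integer(hd[5]); cv <- as.numeric(hd[6])
  nl <- do.call(rbind, strsplit(ln[1 + seq_len(nn)], " "))
  nodes <- cbind(as.numeric(nl[, 2]), as.numeric(nl[, 3]),
                 as.numeric(nl[, 4]))
  anchor <- as.integer(nl[, 5]); anchor[anchor < 0] <- NA_integer_
  el <- do.call(rbind, strsplit(ln[1 + nn + seq_len(ne)], " "))
  edges <- data.frame(a = as.integer(el[, 2]), b = as.integer(el[, 3]),
                      len = as.numeric(el[, 4]), branch = el[, 5],
                      fascicle = el[, 6],
                      blocked = el[, 7] == "1")
  pmjs <- NULL
  if (np) {
    pl <- do.call(rbind, strsplit(ln[1 + nn + ne + seq_len(np)], " "))
    da <- as.numeric(pl[, 4]); da[da < 0] <- NA_real_
    dr <- as.numeric(pl[, 5]); dr[dr < 0] <- NA_real_
    pmjs <- data.frame(tree_node = as.integer(pl[, 2]),
                       mesh_node = as.integer(pl[, 3]),
                       delay_antero = da, delay_retro = dr,
                       fascicle = pl[, 6])
  }
  purkinje_tree(nodes, edges, root = root, pmjs = pmjs, anchor = anchor,
                cv_tree = cv)
}
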