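# First-arrival activation solver.  Myocardial conduction is transversely
# isotropic with speeds cv_fibre along and cv_transverse across the local
# fibre; the first-arrival (path) form of the anisotropic Eikonal equation
# assigns an edge of direction d and length L the travel time
#   L * sqrt((d.f)^2/cv_fibre^2 + (1-(d.f)^2)/cv_transverse^2),
# the Riemannian (dual-metric) length consistent with front speeds cv_fibre
# along and cv_transverse across the fibre.  Units: mm, ms; 1 m/s = 1 mm/ms.

UNREACHED <- Inf

#' Conduction configuration
#'
#' @param cv_fibre myocardial conduction velocity along the fibre (m/s).
#' @param cv_transverse myocardial conduction velocity across the fibre (m/s).
#' @param cv_tree His-Purkinje conduction velocity (m/s).
#' @param pmj_delay_antero Purkinje-myocardial junction delay, tree to
#'   myocardium (ms).
#' @param pmj_delay_retro junction delay, myocardium to tree (ms).
#' @param nonconducting integer element indices that transmit nothing
#'   (scar core).
#' @param cv_multiplier per-element conduction-velocity multiplier (scar
#'   border zone); length 1 or one per element.
#' @return object of class `conduction_config`.
#' @export
conduction_config <- function(cv_fibre = 0.6, cv_transverse = 0.24,
                              cv_tree = 3, pmj_delay_antero = 10,
                              pmj_delay_retro = 3,
                              nonconducting = integer(),
                              cv_multiplier = 1) {
  stopifnot(cv_fibre > 0, cv_transverse > 0, cv_tree > 0,
            pmj_delay_antero >= 0, pmj_delay_retro >= 0,
            all(cv_multiplier > 0))
  structure(list(cv_fibre = cv_fibre, cv_transverse = cv_transverse,
                 cv_tree = cv_tree, pmj_delay_antero = pmj_delay_antero,
                 pmj_delay_retro = pmj_delay_retro,
                 nonconducting = as.integer(nonconducting),
                 cv_multiplier = cv_multiplier),
            class = "conduction_config")
}

#' @export
print.conduction_config <- function(x, ...) {
  cat(sprintf(paste0("Conduction config: myocardium %.2f/%.2f m/s ",
                     "(fibre/transverse), tree %.1f m/s, PMJ delays %g/%g ms",
                     " (antero/retro), %d non-conducting elements\n"),
              x$cv_fibre, x$cv_transverse, x$cv_tree, x$pmj_delay_antero,
              x$pmj_delay_retro, length(x$nonconducting)))
  invisible(x)
}

#' Weighted conduction edge table of a mesh
#'
#' Builds the unique-edge table with anisotropic travel times.  Each edge
#' conducts with the mean fibre of its conducting incident elements;
#' non-conducting elements contribute nothing, and an edge all of whose
#' incident elements are non-conducting is omitted.  When a border-zone
#' multiplier is present the edge uses the smallest multiplier among its
#' conducting incident elements.
#'
#' @param mesh a `tet_mesh` with fibres.
#' @param config a [conduction_config()].
#' @return data.frame with columns i, j, len, time (ms).
#' @export
conduction_graph <- function(mesh, config) {
  if (is.null(mesh$fibre)) stop("mesh has no fibre field; run assign_fibres()")
  em <- mesh_edges(mesh)
  ed <- em$edges
  keep_inst <- !(em$inst_elem %in% config$nonconducting)
  ie <- em$inst_edge[keep_inst]
  el <- em$inst_elem[keep_inst]
  fib <- mesh$fibre[el, , drop = FALSE]
  fsum <- rowsum(fib, group = ie)
  edge_ids <- as.integer(rownames(fsum))
  fn <- sqrt(rowSums(fsum * fsum))
  degen <- fn < 1e-8
  if (any(degen)) {
    # antiparallel incident fibres: fall back to the first incident element
    first <- !duplicated(ie)
    ffirst <- fib[first, , drop = FALSE][match(edge_ids, ie[first]), ,
                                         drop = FALSE]
    fsum[degen, ] <- ffirst[degen, ]
    fn <- sqrt(rowSums(fsum * fsum))
  }
  fhat <- fsum / fn
  i <- ed$i[edge_ids]; j <- ed$j[edge_ids]; len <- ed$len[edge_ids]
  d <- (mesh$nodes[j, , drop = FALSE] - mesh$nodes[i, , drop = FALSE]) / len
  ca <- rowSums(d * fhat)  # cos(angle to fibre)
  ca2 <- pmin(ca * ca, 1)
  slow <- sqrt(ca2 / config$cv_fibre^2 + (1 - ca2) / config$cv_transverse^2)
  mult <- config$cv_multiplier
  if (length(mult) > 1 && any(mult != 1)) {
    mscale <- vapply(split(mult[el], ie), min, numeric(1))
    slow <- slow / mscale[match(edge_ids, as.integer(names(mscale)))]
  } else if (length(mult) == 1 && mult != 1) {
    slow <- slow / mult
  }
  out <- data.frame(i = i, j = j, len = len, time = len * slow)
  aux <- .aux_edges(mesh, config)
  if (!is.null(aux)) out <- rbind(out, aux)
  out
}

# Augmented lattice diagonals (see the generator): an occurrence conducts
# only if all six tets of its cell conduct, so augmentation can never leak
# across a non-conducting (scar-core) boundary; its fibre is the cell mean.
.aux_edges <- function(mesh, config) {
  aux <- mesh$meta$aux
  if (is.null(aux)) return(NULL)
  ce <- aux$cell_elems
  cond <- rep(TRUE, nrow(mesh$tets))
  cond[config$nonconducting] <- FALSE
  cell_ok <- cond[ce[, 1]] & cond[ce[, 2]] & cond[ce[, 3]] &
             cond[ce[, 4]] & cond[ce[, 5]] & cond[ce[, 6]]
  occ <- aux$occ[cell_ok[aux$occ$cell], , drop = FALSE]
  if (!nrow(occ)) return(NULL)
  fs_cell <- mesh$fibre[ce[, 1], , drop = FALSE]
  for (k in 2:6) fs_cell <- fs_cell + mesh$fibre[ce[, k], , drop = FALSE]
  mult <- config$cv_multiplier
  if (length(mult) > 1) {
    mult_cell <- pmin(mult[ce[, 1]], mult[ce[, 2]], mult[ce[, 3]],
                      mult[ce[, 4]], mult[ce[, 5]], mult[ce[, 6]])
  } else mult_cell <- rep(mult, nrow(ce))
  key <- as.double(occ$i) * (nrow(mesh$nodes) + 1) + occ$j
  uk <- !duplicated(key)
  grp <- match(key, key[uk])
  fsum <- rowsum(fs_cell[occ$cell, , drop = FALSE], group = grp)
  ids <- as.integer(rownames(fsum))
  o <- order(ids); fsum <- fsum[o, , drop = FALSE]
  msc <- vapply(split(mult_cell[occ$cell], grp), min, numeric(1))
  msc <- msc[order(as.integer(names(msc)))]
  i <- occ$i[uk]; j <- occ$j[uk]
  fn <- sqrt(rowSums(fsum * fsum))
  fn[fn < 1e-12] <- 1
  fhat <- fsum / fn
  d <- mesh$nodes[j, , drop = FALSE] - mesh$nodes[i, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  d <- d / len
  ca2 <- pmin(rowSums(d * fhat)^2, 1)
  slow <- sqrt(ca2 / config$cv_fibre^2 +
               (1 - ca2) / config$cv_transverse^2) / msc
  data.frame(i = i, j = j, len = len, time = len * slow)
}

# per-PMJ delays with NA meaning "inherit from the conduction config"
.pmj_delays <- function(pm, config) {
  da <- pm$delay_antero
  dr <- pm$delay_retro
  if (is.null(da)) da <- rep(NA_real_, nrow(pm))
  if (is.null(dr)) dr <- rep(NA_real_, nrow(pm))
  list(antero = ifelse(is.na(da), config$pmj_delay_antero, da),
       retro = ifelse(is.na(dr), config$pmj_delay_retro, dr))
}

.conducting_nodes <- function(mesh, config) {
  if (!length(config$nonconducting)) return(seq_len(nrow(mesh$nodes)))
  cond <- setdiff(seq_len(nrow(mesh$tets)), config$nonconducting)
  sort(unique(as.vector(mesh$tets[cond, , drop = FALSE])))
}

.as_sources <- function(sources) {
  if (is.data.frame(sources)) {
    stopifnot(all(c("node", "onset") %in% names(sources)))
    sources
  } else data.frame(node = as.integer(sources),
                    onset = rep(0, length(sources)))
}

#' Activation map container
#'
#' Per-node activation times in ms with `Inf` as the unactivated sentinel,
#' optional tree-node times, and the stimulus record.
#' @param node_time numeric vector, mesh-node activation times (ms).
#' @param tree_time numeric vector or NULL, tree-node activation times.
#' @param stimuli data.frame recording the stimulus sites and onsets.
#' @return object of class `activation_map`.
#' @export
activation_map <- function(node_time, tree_time = NULL, stimuli = NULL) {
  structure(list(node_time = node_time, tree_time = tree_time,
                 stimuli = stimuli), class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  r <- x$node_time[is.finite(x$node_time)]
  cat("Activation map:", length(x$node_time), "mesh nodes")
  if (!is.null(x$tree_time)) cat(",", length(x$tree_time), "tree nodes")
  cat("\n")
  if (length(r))
    cat(sprintf("  reached %d/%d, times %.1f to %.1f ms\n", length(r),
                length(x$node_time), min(r), max(r)))
  else cat("  no node reached\n")
  invisible(x)
}

#' Solve myocardial activation from mesh stimuli
#'
#' First-arrival times on the conduction edge graph from one or more
#' stimulated mesh nodes.  Sources lying in fully non-conducting tissue are
#' dropped with a warning; if none remain the map is all-unreached.
#'
#' @param mesh a `tet_mesh` with fibres.
#' @param config a [conduction_config()].
#' @param sources integer node vector (onset 0) or data.frame(node, onset).
#' @return an [activation_map()].
#' @export
solve_myocardium <- function(mesh, config, sources) {
  src <- .as_sources(sources)
  if (!nrow(src)) stop("empty source set")
  ok <- src$node %in% .conducting_nodes(mesh, config)
  if (!all(ok)) {
    warning(sum(!ok), " stimulus node(s) inside non-conducting tissue ",
            "were dropped")
    src <- src[ok, , drop = FALSE]
  }
  n <- nrow(mesh$nodes)
  if (!nrow(src)) {
    warning("all stimuli inside non-conducting tissue: map is unreached")
    return(activation_map(rep(UNREACHED, n), stimuli = src))
  }
  ed <- conduction_graph(mesh, config)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, c(rbind(ed$i, ed$j)))
  dmat <- igraph::distances(g, v = src$node, weights = ed$time,
                            algorithm = "dijkstra")
  tt <- do.call(pmin, lapply(seq_len(nrow(src)),
                             function(k) src$onset[k] + dmat[k, ]))
  activation_map(as.numeric(tt), stimuli = src)
}

#' Directed arc table of the coupled tree-myocardium graph
#'
#' The union graph on which the coupled solve runs: mesh conduction edges
#' (both directions), unblocked tree edges (both directions, at the tree
#' conduction velocity), and the directed Purkinje-myocardial junction arcs
#' (tree-to-mesh with the anterograde delay, mesh-to-tree with the
#' retrograde delay).  Tree nodes are numbered after the mesh nodes.
#'
#' @param mesh a `tet_mesh` with fibres.
#' @param tree a `purkinje_tree`.
#' @param config a [conduction_config()].
#' @param mesh_graph optional precomputed [conduction_graph()] table for
#'   this mesh/config (reused across protocols by the cohort runner).
#' @return list with `arcs` (data.frame from, to, w), `n_mesh`, `n_tree`.
#' @export
union_arcs <- function(mesh, tree, config, mesh_graph = NULL) {
  n <- nrow(mesh$nodes)
  med <- if (is.null(mesh_graph)) conduction_graph(mesh, config)
         else mesh_graph
  te <- tree$edges[!tree$edges$blocked, , drop = FALSE]
  tw <- te$len / config$cv_tree
  pm <- tree$pmjs
  cond <- .conducting_nodes(mesh, config)
  pm <- pm[pm$mesh_node %in% cond, , drop = FALSE]
  da <- .pmj_delays(pm, config)
  arcs <- data.frame(
    from = c(med$i, med$j, n + te$a, n + te$b, n + pm$tree_node, pm$mesh_node),
    to   = c(med$j, med$i, n + te$b, n + te$a, pm$mesh_node, n + pm$tree_node),
    w    = c(med$time, med$time, tw, tw, da$antero, da$retro))
  list(arcs = arcs, n_mesh = n, n_tree = nrow(tree$nodes))
}

.union_igraph <- function(ua) {
  g <- igraph::make_empty_graph(n = ua$n_mesh + ua$n_tree, directed = TRUE)
  g <- igraph::add_edges(g, c(rbind(ua$arcs$from, ua$arcs$to)))
  list(g = g, w = ua$arcs$w, n_mesh = ua$n_mesh, n_tree = ua$n_tree)
}

.coupled_stimuli <- function(stimuli, n_mesh) {
  stopifnot(is.data.frame(stimuli), all(c("kind", "node") %in% names(stimuli)))
  if (is.null(stimuli$onset)) stimuli$onset <- 0
  v <- ifelse(stimuli$kind == "tree", n_mesh + stimuli$node, stimuli$node)
  data.frame(v = v, onset = stimuli$onset)
}

#' Solve coupled His-Purkinje / myocardium activation
#'
#' Computes first-arrival activation of the myocardium and the Purkinje tree
#' under bidirectional junction coupling.  The default method runs one
#' shortest-path solve on the union graph, which is the fixed point of the
#' alternating tree/myocardium iteration; `method = "alternating"` runs that
#' iteration explicitly (monotone, converging in at most #PMJ + 2 rounds)
#' and is retained as a cross-check.
#'
#' @param mesh a `tet_mesh` with fibres.
#' @param tree a `purkinje_tree`.
#' @param config a [conduction_config()].
#' @param stimuli data.frame with columns kind ("tree"/"mesh"), node, and
#'   optionally onset (ms).
#' @param method "union" or "alternating".
#' @param graph optional prebuilt graph from [union_arcs()] (passed through
#'   `.union_igraph`); used by the cohort runner to reuse graphs across
#'   protocols.
#' @return an [activation_map()] with mesh and tree times.
#' @export
solve_coupled <- function(mesh, tree, config, stimuli,
                          method = c("union", "alternating"), graph = NULL) {
  method <- match.arg(method)
  n <- nrow(mesh$nodes)
  stim <- .coupled_stimuli(stimuli, n)
  if (!nrow(stim)) stop("empty stimulus set")
  mesh_stim <- stim$v[stim$v <= n]
  cond <- .conducting_nodes(mesh, config)
  bad <- setdiff(mesh_stim, cond)
  if (length(bad)) {
    warning(length(bad), " mesh stimulus node(s) inside non-conducting ",
            "tissue were dropped")
    stim <- stim[!(stim$v %in% bad), , drop = FALSE]
  }
  if (!nrow(stim)) {
    warning("all stimuli inside non-conducting tissue: map is unreached")
    return(activation_map(rep(UNREACHED, n),
                          rep(UNREACHED, nrow(tree$nodes)), stimuli))
  }
  if (method == "alternating")
    return(.solve_alternating(mesh, tree, config, stim, stimuli))
  ug <- if (is.null(graph)) .union_igraph(union_arcs(mesh, tree, config))
        else graph
  dmat <- igraph::distances(ug$g, v = stim$v, weights = ug$w, mode = "out",
                            algorithm = "dijkstra")
  tt <- do.call(pmin, lapply(seq_len(nrow(stim)),
                             function(k) stim$onset[k] + dmat[k, ]))
  activation_map(as.numeric(tt[seq_len(n)]),
                 as.numeric(tt[n + seq_len(ug$n_tree)]), stimuli)
}

# Alternating fixed-point: tree solve, anterograde PMJ transfer, myocardial
# solve, retrograde transfer, repeated until no time improves.  First-arrival
# times only ever decrease, and each round finalizes at least one junction
# crossing, so #PMJ + 2 rounds suffice.
.solve_alternating <- function(mesh, tree, config, stim, stimuli) {
  n <- nrow(mesh$nodes); m <- nrow(tree$nodes)
  med <- conduction_graph(mesh, config)
  te <- tree$edges[!tree$edges$blocked, , drop = FALSE]
  pm <- tree$pmjs[tree$pmjs$mesh_node %in% .conducting_nodes(mesh, config), ,
                  drop = FALSE]
  dl <- .pmj_delays(pm, config)
  seeded <- function(nv, edges_i, edges_j, w, seeds) {
    # seeds: data.frame(v, t); returns distance-from-seeds vector
    fin <- seeds[is.finite(seeds$t), , drop = FALSE]
    if (!nrow(fin)) return(rep(UNREACHED, nv))
    g <- igraph::make_empty_graph(n = nv + 1, directed = FALSE)
    g <- igraph::add_edges(g, c(rbind(c(edges_i, rep(nv + 1, nrow(fin))),
                                      c(edges_j, fin$v))))
    igraph::distances(g, v = nv + 1, weights = c(w, fin$t),
                      algorithm = "dijkstra")[1, seq_len(nv)]
  }
  t_mesh <- rep(UNREACHED, n); t_tree <- rep(UNREACHED, m)
  ms <- stim[stim$v <= n, , drop = FALSE]
  ts <- stim[stim$v > n, , drop = FALSE]
  t_mesh[ms$v] <- pmin(t_mesh[ms$v], ms$onset)
  t_tree[ts$v - n] <- pmin(t_tree[ts$v - n], ts$onset)
  max_iter <- nrow(pm) + 2
  for (iter in seq_len(max_iter)) {
    prev_mesh <- t_mesh; prev_tree <- t_tree
    t_tree <- pmin(t_tree, seeded(m, te$a, te$b, te$len / config$cv_tree,
                                  data.frame(v = seq_len(m), t = t_tree)))
    t_mesh_seed <- t_mesh
    tr <- tapply(t_tree[pm$tree_node] + dl$antero, pm$mesh_node, min)
    idx <- as.integer(names(tr))
    t_mesh_seed[idx] <- pmin(t_mesh_seed[idx], as.numeric(tr))
    t_mesh <- pmin(t_mesh, seeded(n, med$i, med$j, med$time,
                                  data.frame(v = seq_len(n), t = t_mesh_seed)))
    back <- tapply(t_mesh[pm$mesh_node] + dl$retro, pm$tree_node, min)
    idx <- as.integer(names(back))
    t_tree[idx] <- pmin(t_tree[idx], as.numeric(back))
    if (any(t_mesh > prev_mesh + 1e-12) || any(t_tree > prev_tree + 1e-12))
      stop("internal error: activation time increased during coupling")
    if (max(abs(ifelse(is.finite(prev_mesh) & is.finite(t_mesh),
                       prev_mesh - t_mesh, 0))) <= 1e-9 &&
        max(abs(ifelse(is.finite(prev_tree) & is.finite(t_tree),
                       prev_tree - t_tree, 0))) <= 1e-9 &&
        identical(is.finite(prev_mesh), is.finite(t_mesh)) &&
        identical(is.finite(prev_tree), is.finite(t_tree))) {
      out <- activation_map(t_mesh, t_tree, stimuli)
      attr(out, "iterations") <- iter
      return(out)
    }
  }
  stop("coupled solve did not converge within #PMJ + 2 iterations ",
       "(this violates the monotone-convergence argument; please report)")
}
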