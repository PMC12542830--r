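# Synthetic biventricular geometry: truncated nested ellipsoids sharing a
# septal wall, meshed on a regular lattice with Kuhn (6-tet) cube subdivision.
# Units are mm throughout; node indices are 1-based (R convention); openCARP
# files are written 0-based as that format requires.

#' Element region labels
#' @export
REGION_LEVELS <- c("LV_MYO", "RV_MYO", "SEPTUM", "EXCLUDED_VALVE", "EXCLUDED_OUTFLOW")

#' Boundary surface tags
#' @export
SURFACE_LEVELS <- c("LV_ENDO", "RV_ENDO_FREEWALL", "RV_ENDO_SEPTAL",
                    "LV_EPI", "RV_EPI", "BASE")

#' Cohort specification for synthetic heart generation
#'
#' Defines the number of hearts, the seed, the sampling distributions of the
#' shape parameters (normal, mean/sd in mm unless stated) and the target mesh
#' edge length. The defaults emulate a cohort of healthy adult ventricles:
#' LV cavity short-axis radius ~22 mm, LV cavity long-axis ~50 mm, LV free
#' wall ~9 mm, septum ~10 mm, RV free wall ~4 mm, basal truncation at 45% of
#' the cavity long axis above the equator. Identical seeds yield bit-identical
#' cohorts.
#'
#' @param n_hearts number of hearts in the cohort.
#' @param seed integer seed controlling shape sampling and tree growth.
#' @param target_edge_length target mesh edge length in mm. The lattice
#'   spacing is set to 0.75 x this value so that the median edge of the Kuhn
#'   subdivision (axis edges plus face and body diagonals) matches the target.
#' @param shape named list overriding entries of the default shape-parameter
#'   distributions; each entry is `c(mean, sd)`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hearts = 19L, seed = 1L, target_edge_length = 2,
                        shape = list()) {
  stopifnot(n_hearts >= 1, target_edge_length > 0)
  def <- list(
    lv_cavity_radius = c(22, 1.8),   # LV endocardial short-axis semi-axis
    lv_cavity_long   = c(50, 3.5),   # LV endocardial long-axis semi-axis
    lv_wall          = c(9, 0.7),    # LV free-wall thickness
    septal_wall      = c(10, 0.8),   # septal thickness
    rv_wall          = c(4, 0.35),   # RV free-wall thickness
    base_frac        = c(0.45, 0.04),# base plane height / lv_cavity_long
    rv_offset        = c(10, 1.0),   # RV ellipsoid centre x-offset
    rv_radius_x      = c(32, 2.0),   # RV endocardial semi-axis (x)
    rv_radius_y      = c(30, 1.8),   # RV endocardial semi-axis (y)
    rv_long          = c(50, 3.0)    # RV endocardial semi-axis (z)
  )
  unknown <- setdiff(names(shape), names(def))
  if (length(unknown))
    stop("unknown shape parameter(s): ", paste(unknown, collapse = ", "))
  def[names(shape)] <- shape
  structure(list(n_hearts = as.integer(n_hearts), seed = as.integer(seed),
                 target_edge_length = target_edge_length, shape = def),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic biventricular cohort spec\n")
  cat("  hearts:", x$n_hearts, " seed:", x$seed,
      " target edge length:", x$target_edge_length, "mm\n")
  invisible(x)
}

#' Sample the per-heart shape parameters of a cohort
#'
#' All hearts are sampled in one pass from the cohort seed, so that heart
#' `index` is fully determined by `(seed, index)`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per heart.
#' @export
sample_cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_hearts
  out <- lapply(spec$shape, function(ms) stats::rnorm(n, ms[1], ms[2]))
  df <- as.data.frame(out)
  df$heart <- seq_len(n)
  df
}

.check_shape <- function(p) {
  msg <- NULL
  if (p$lv_wall <= 0 || p$septal_wall <= 0 || p$rv_wall <= 0)
    msg <- "sampled wall thickness is non-positive"
  else if (p$lv_wall >= p$lv_cavity_radius)
    msg <- sprintf("LV wall thickness (%.1f mm) >= LV cavity radius (%.1f mm)",
                   p$lv_wall, p$lv_cavity_radius)
  else if (p$septal_wall >= p$lv_cavity_radius)
    msg <- sprintf("septal thickness (%.1f mm) >= LV cavity radius (%.1f mm)",
                   p$septal_wall, p$lv_cavity_radius)
  else if (p$rv_offset + p$rv_radius_x <= p$lv_cavity_radius + p$septal_wall)
    msg <- "RV ellipsoid does not reach beyond the septal surface (no RV cavity)"
  if (!is.null(msg))
    stop("degenerate shape sample for this heart: ", msg,
         ". Adjust the cohort shape distributions (see cohort_spec()).",
         call. = FALSE)
  invisible(TRUE)
}

# quadratic ellipsoid form ((p-c)/axes)^2 summed; vectorized over rows of p
.ellq <- function(x, y, z, cx, cy, cz, ax, ay, az) {
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 + ((z - cz) / az)^2
}

# Region predicates for a parameter set; operate on coordinate vectors.
.heart_fields <- function(p) {
  a0 <- p$lv_cavity_radius; c0 <- p$lv_cavity_long
  a1 <- a0 + p$lv_wall;     c1 <- c0 + p$lv_wall
  as_ <- a0 + p$septal_wall; cs <- c0 + p$septal_wall
  rx <- p$rv_offset; rz <- 2
  rax <- p$rv_radius_x; ray <- p$rv_radius_y; raz <- p$rv_long
  z_base <- p$base_frac * c0
  list(
    a0 = a0, c0 = c0, a1 = a1, c1 = c1, z_base = z_base, z_apex = -c1,
    rx = rx, rz = rz, rax = rax, ray = ray, raz = raz, rv_wall = p$rv_wall,
    in_lv_endo = function(x, y, z) .ellq(x, y, z, 0, 0, 0, a0, a0, c0) <= 1,
    in_lv_sept = function(x, y, z) .ellq(x, y, z, 0, 0, 0, as_, as_, cs) <= 1,
    in_lv_epi  = function(x, y, z) .ellq(x, y, z, 0, 0, 0, a1, a1, c1) <= 1,
    in_rv_endo = function(x, y, z)
      .ellq(x, y, z, rx, 0, rz, rax, ray, raz) <= 1,
    in_rv_epi  = function(x, y, z)
      .ellq(x, y, z, rx, 0, rz, rax + p$rv_wall, ray + p$rv_wall,
            raz + p$rv_wall) <= 1
  )
}

# chamber of points: "LV", "RV" or NA (not tissue); z_base cut applied
.point_chamber <- function(f, x, y, z) {
  le <- f$in_lv_endo(x, y, z); ls <- f$in_lv_sept(x, y, z)
  lp <- f$in_lv_epi(x, y, z)
  re <- f$in_rv_endo(x, y, z); rp <- f$in_rv_epi(x, y, z)
  rv_cav <- re & !ls
  lv <- (lp | (ls & re)) & !le & !rv_cav
  rv <- rp & !re & !lp
  out <- rep(NA_character_, length(x))
  out[rv] <- "RV"
  out[lv] <- "LV"        # LV wins shared points (septal weld)
  out[z > f$z_base] <- NA_character_
  out
}

# Kuhn subdivision: 6 tets per cube, all sharing the (0,0,0)-(1,1,1) diagonal.
# Corner offsets of the 6 tets, as indices into the 8 cube corners ordered
# (i, j, k) binary with i fastest: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
# 5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
.KUHN <- rbind(
  c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

# Complementary lattice diagonals absent from the Kuhn subdivision (the
# other diagonal of each cube face, and the three other body diagonals).
# The Kuhn direction set alone is asymmetric, which would make graph
# first-arrival times overestimate badly (up to sqrt(2)) along directions
# opposing its diagonals; the conduction solver therefore augments the edge
# graph with these cell diagonals wherever a lattice cell is complete.
.AUX_PAIRS <- rbind(
  c(2, 3), c(6, 7), c(2, 5), c(4, 7), c(3, 5), c(4, 6),  # anti-face
  c(2, 7), c(3, 6), c(4, 5))                              # anti-body

# Build the auxiliary-diagonal table for cells whose 6 tets were all kept.
# corners: kept-cell corner matrix in *final* node ids; elems: matrix of the
# 6 element ids per complete cell (same row order).
.lattice_aux <- function(corners, elems) {
  if (!nrow(corners)) return(NULL)
  occ_i <- as.vector(corners[, .AUX_PAIRS[, 1]])
  occ_j <- as.vector(corners[, .AUX_PAIRS[, 2]])
  occ_cell <- rep.int(seq_len(nrow(corners)), nrow(.AUX_PAIRS))
  list(occ = data.frame(i = pmin(occ_i, occ_j), j = pmax(occ_i, occ_j),
                        cell = occ_cell),
       cell_elems = elems)
}

#' Signed volumes of tetrahedra
#' @param nodes numeric matrix n x 3 of node positions.
#' @param tets integer matrix m x 4 of node indices.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Orient all tets positive by swapping the last two vertices where needed.
.orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
  }
  tets
}

#' Construct a labelled tetrahedral mesh object
#'
#' @param nodes n x 3 numeric matrix (mm).
#' @param tets m x 4 integer matrix of 1-based node indices.
#' @param region character vector, one of `REGION_LEVELS` per element.
#' @param chamber character vector ("LV"/"RV") per element; septal elements
#'   belong to the LV chamber.
#' @param fibre m x 3 matrix of unit fibre vectors, or NULL.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region, chamber = NULL, fibre = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4,
            length(region) == nrow(tets))
  structure(list(nodes = nodes, tets = tets,
                 region = as.character(region),
                 chamber = if (is.null(chamber)) rep("LV", nrow(tets))
                           else as.character(chamber),
                 fibre = fibre, surface = NULL, meta = list()),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "elements\n")
  tb <- table(x$region)
  cat("  regions:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$surface))
    cat("  boundary facets:", nrow(x$surface$faces), "\n")
  invisible(x)
}

#' @export
summary.tet_mesh <- function(object, ...) {
  v <- tet_volumes(object$nodes, object$tets)
  ed <- mesh_edges(object)$edges
  cat("Tetrahedral mesh summary\n")
  cat(sprintf("  nodes: %d  elements: %d  volume: %.1f cm^3\n",
              nrow(object$nodes), nrow(object$tets), sum(v) / 1000))
  cat(sprintf("  edge length (mm): min %.2f  median %.2f  max %.2f\n",
              min(ed$len), stats::median(ed$len), max(ed$len)))
  invisible(object)
}

#' Element centroids
#' @param mesh a `tet_mesh`.
#' @return m x 3 matrix.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

#' Unique edge table of a tetrahedral mesh
#'
#' Returns the unique node pairs spanned by the elements (for linear tets the
#' six element edges per tet already include every within-element diagonal),
#' together with Euclidean lengths and the mapping from per-element edge
#' instances to unique edges (used to aggregate per-element fibres onto
#' edges). The result is cached on the mesh in the calling frame's object
#' only if assigned back; callers that need it repeatedly should keep it.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `edges` (data.frame i, j, len), `inst_edge` (integer
#'   vector, unique-edge id of each of the 6*m instances) and `inst_elem`
#'   (element id of each instance).
#' @export
mesh_edges <- function(mesh) {
  if (!is.null(mesh$meta$edges)) return(mesh$meta$edges)
  tt <- mesh$tets
  pairs <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
                 tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  inst_elem <- rep.int(seq_len(nrow(tt)), 6L)
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  key <- as.double(lo) * (nrow(mesh$nodes) + 1) + as.double(hi)
  uk <- !duplicated(key)
  inst_edge <- match(key, key[uk])
  i <- lo[uk]; j <- hi[uk]
  d <- mesh$nodes[i, , drop = FALSE] - mesh$nodes[j, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  list(edges = data.frame(i = i, j = j, len = len),
       inst_edge = inst_edge, inst_elem = inst_elem)
}

# Extract boundary faces (appearing in exactly one tet) with the owning
# element and the opposite vertex, and classify them into surface tags.
.surface_faces <- function(nodes, tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  opp <- c(tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  elem <- rep.int(seq_len(m), 4L)
  s1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  s3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  s2 <- faces[, 1] + faces[, 2] + faces[, 3] - s1 - s3
  n1 <- as.double(nrow(nodes) + 1)
  key <- (as.double(s1) * n1 + s2) * n1 + s3
  uk <- unique(key)
  idx <- match(key, uk)
  cnt <- tabulate(idx)
  bnd <- cnt[idx] == 1L
  list(faces = faces[bnd, , drop = FALSE], opp = opp[bnd],
       elem = elem[bnd])
}

.classify_surface <- function(nodes, faces, opp, elem, chamber, f, h) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  c_ <- nodes[faces[, 3], , drop = FALSE]
  cen <- (a + b + c_) / 3
  u <- b - a; v <- c_ - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  # orient away from the opposite vertex
  ov <- cen - nodes[opp, , drop = FALSE]
  flip <- rowSums(nrm * ov) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm <- nrm / sqrt(rowSums(nrm * nrm))
  ch <- chamber[elem]
  tag <- rep(NA_character_, nrow(faces))
  # The meshed boundary is a staircase lying within one cell of the analytic
  # surfaces, so a single probe point can land in the analytic-but-unmeshed
  # tissue band.  Probe at several distances along the outward normal and
  # tag by the first cavity hit; anything else facing outward is epicardium.
  lv_cav_hit <- rep(FALSE, nrow(cen))
  rv_cav_hit <- rep(FALSE, nrow(cen))
  for (t in c(0.3, 0.9, 1.8) * h) {
    tp <- cen + t * nrm
    lv_cav_hit <- lv_cav_hit | f$in_lv_endo(tp[, 1], tp[, 2], tp[, 3])
    rv_cav_hit <- rv_cav_hit |
      (f$in_rv_endo(tp[, 1], tp[, 2], tp[, 3]) &
       !f$in_lv_sept(tp[, 1], tp[, 2], tp[, 3]))
  }
  base <- abs(cen[, 3] - f$z_base) < 1e-9 & nrm[, 3] > 0.5
  tag[base] <- "BASE"
  sel <- !base & lv_cav_hit
  tag[sel] <- "LV_ENDO"
  sel <- !base & !lv_cav_hit & rv_cav_hit
  tag[sel & ch == "LV"] <- "RV_ENDO_SEPTAL"
  tag[sel & ch == "RV"] <- "RV_ENDO_FREEWALL"
  # Facets whose probes hit neither cavity: staircase corners can point the
  # outward normal tangentially, so fall back to comparing the approximate
  # radial distances to the bounding analytic surfaces of the chamber.
  miss <- !base & !lv_cav_hit & !rv_cav_hit
  ray_dist <- function(p, cx, cy, cz, ax, ay, az) {
    q <- sqrt(.ellq(p[, 1], p[, 2], p[, 3], cx, cy, cz, ax, ay, az))
    r <- sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2 + (p[, 3] - cz)^2)
    r * abs(1 - 1 / pmax(q, 1e-9))
  }
  if (any(miss & ch == "LV")) {
    i <- which(miss & ch == "LV")
    p <- cen[i, , drop = FALSE]
    d_endo <- ray_dist(p, 0, 0, 0, f$a0, f$a0, f$c0)
    d_epi <- ray_dist(p, 0, 0, 0, f$a1, f$a1, f$c1)
    tag[i] <- ifelse(d_endo < d_epi, "LV_ENDO", "LV_EPI")
  }
  if (any(miss & ch == "RV")) {
    i <- which(miss & ch == "RV")
    p <- cen[i, , drop = FALSE]
    d_endo <- ray_dist(p, f$rx, 0, f$rz, f$rax, f$ray, f$raz)
    d_epi <- ray_dist(p, f$rx, 0, f$rz, f$rax + f$rv_wall,
                      f$ray + f$rv_wall, f$raz + f$rv_wall)
    tag[i] <- ifelse(d_endo < d_epi, "RV_ENDO_FREEWALL", "RV_EPI")
  }
  list(faces = faces, elem = elem, tag = tag, normal = nrm, centroid = cen)
}

#' Universal ventricular coordinates container
#'
#' Per-node apicobasal `rho` in [0,1] (0 apex, 1 base), transmural `tau` in
#' [0,1] (0 endocardium, 1 epicardium; across the septum 0 is the LV
#' endocardial side and 1 the RV septal-endocardial side), rotational `phi`
#' in (-pi, pi] with the septal centre at 0 and the branch cut (+/- pi) on
#' the LV lateral free wall, and ventricle label "LV"/"RV" (septal nodes are
#' LV).
#'
#' @param rho,tau,phi numeric vectors, one value per node.
#' @param ventricle character vector per node.
#' @return object of class `uvc`.
#' @export
uvc_coords <- function(rho, tau, phi, ventricle) {
  stopifnot(length(rho) == length(tau), length(tau) == length(phi),
            length(phi) == length(ventricle))
  structure(list(rho = rho, tau = tau, phi = phi,
                 ventricle = as.character(ventricle)), class = "uvc")
}

#' @export
print.uvc <- function(x, ...) {
  cat("Universal ventricular coordinates for", length(x$rho), "nodes\n")
  cat(sprintf("  rho [%.2f, %.2f]  tau [%.2f, %.2f]  LV nodes: %d, RV nodes: %d\n",
              min(x$rho), max(x$rho), min(x$tau), max(x$tau),
              sum(x$ventricle == "LV"), sum(x$ventricle == "RV")))
  invisible(x)
}

# Geodesic wall-depth transmural coordinate.  Each surface distance field is
# computed with its own single-supersource Dijkstra: the surface node sets can
# legitimately share nodes (e.g. the ring where the septal and free-wall
# endocardium meet, or a locally one-cell-thick RV wall), so joint
# zero-weight supersources would short-circuit each other.
.transmural_depth <- function(mesh, vent) {
  ed <- mesh_edges(mesh)$edges
  surf <- mesh$surface
  nodes_of <- function(tags)
    unique(as.vector(surf$faces[surf$tag %in% tags, ]))
  n <- nrow(mesh$nodes)
  sets <- list(lv0 = nodes_of("LV_ENDO"),
               lv1 = nodes_of(c("LV_EPI", "RV_ENDO_SEPTAL")),
               rv0 = nodes_of("RV_ENDO_FREEWALL"),
               rv1 = nodes_of("RV_EPI"))
  g0 <- igraph::make_empty_graph(n = n + 1, directed = FALSE)
  g0 <- igraph::add_edges(g0, c(rbind(ed$i, ed$j)))
  ss <- n + 1L
  d <- lapply(sets, function(set) {
    g <- igraph::add_edges(g0, c(rbind(rep(ss, length(set)), set)))
    w <- c(ed$len, rep(0, length(set)))
    igraph::distances(g, v = ss, weights = w,
                      algorithm = "dijkstra")[1, seq_len(n)]
  })
  tau <- numeric(n)
  lv <- vent == "LV"
  tau[lv] <- d$lv0[lv] / pmax(d$lv0[lv] + d$lv1[lv], 1e-12)
  tau[!lv] <- d$rv0[!lv] / pmax(d$rv0[!lv] + d$rv1[!lv], 1e-12)
  tau
}

#' Generate one synthetic heart of a cohort
#'
#' Builds a two-chamber geometry from truncated nested ellipsoids sharing a
#' septal wall, labels elements (LV/RV myocardium, septum, excluded
#' valve-ring and RV outflow regions), tags the boundary surfaces, assigns
#' universal ventricular coordinates and a rule-based transmural helix fibre
#' field. Regeneration with the same `(seed, index)` is bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @param index heart index, 1-based, `1 <= index <= n_hearts`.
#' @param alpha_endo,alpha_epi helix angles (degrees) passed to
#'   [assign_fibres()].
#' @return list with elements `mesh` (a `tet_mesh` with surface tags and
#'   fibres) and `uvc` (a `uvc` object).
#' @export
generate_heart <- function(spec, index, alpha_endo = 60, alpha_epi = -60) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!(index >= 1 && index <= spec$n_hearts))
    stop("index must be in 1..n_hearts (", spec$n_hearts, "), got ", index)
  pars <- sample_cohort_params(spec)
  p <- as.list(pars[index, ])
  .check_shape(p)
  f <- .heart_fields(p)
  h <- 0.75 * spec$target_edge_length

  # lattice aligned so that z_base is exactly a grid plane
  xr <- c(-(f$a1 + h), f$rx + f$rax + p$rv_wall + h)
  yr <- c(-(max(f$a1, f$ray + p$rv_wall) + h), max(f$a1, f$ray + p$rv_wall) + h)
  zlo <- f$z_apex - h
  nz <- ceiling((f$z_base - zlo) / h)
  zs <- f$z_base - (nz:0) * h
  xs <- seq(xr[1], xr[2] + h, by = h)
  ys <- seq(yr[1], yr[2] + h, by = h)
  nx <- length(xs); ny <- length(ys); nzp <- length(zs)
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)

  # node tissue flags for cell prefiltering
  gx <- rep(xs, times = ny * nzp)
  gy <- rep(rep(ys, each = nx), times = nzp)
  gz <- rep(zs, each = nx * ny)
  node_tis <- !is.na(.point_chamber(f, gx, gy, gz))

  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nzp - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nzp - 1L)
  ck <- rep(seq_len(nzp - 1L), each = (nx - 1L) * (ny - 1L))
  corner <- function(di, dj, dk) nid(ci + di, cj + dj, ck + dk)
  corners <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
                   corner(0L, 1L, 0L), corner(1L, 1L, 0L),
                   corner(0L, 0L, 1L), corner(1L, 0L, 1L),
                   corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  keep_cell <- rowSums(matrix(node_tis[corners], nrow = nrow(corners))) > 0
  corners <- corners[keep_cell, , drop = FALSE]

  tets <- do.call(rbind, lapply(seq_len(6), function(t)
    corners[, .KUHN[t, ], drop = FALSE]))
  cell_of <- rep.int(seq_len(nrow(corners)), 6L)
  cenx <- (gx[tets[, 1]] + gx[tets[, 2]] + gx[tets[, 3]] + gx[tets[, 4]]) / 4
  ceny <- (gy[tets[, 1]] + gy[tets[, 2]] + gy[tets[, 3]] + gy[tets[, 4]]) / 4
  cenz <- (gz[tets[, 1]] + gz[tets[, 2]] + gz[tets[, 3]] + gz[tets[, 4]]) / 4
  ch <- .point_chamber(f, cenx, ceny, cenz)
  keep <- !is.na(ch)
  tets <- tets[keep, , drop = FALSE]
  ch <- ch[keep]
  cell_of <- cell_of[keep]
  cen <- cbind(cenx[keep], ceny[keep], cenz[keep])

  used <- sort(unique(as.vector(tets)))
  remap <- integer(nx * ny * nzp)
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  nodes <- cbind(gx[used], gy[used], gz[used])
  tets <- .orient_tets(nodes, tets)
  # complete lattice cells feed the solver's diagonal augmentation
  cnt <- tabulate(cell_of, nbins = nrow(corners))
  complete <- which(cnt == 6L)
  aux <- NULL
  if (length(complete)) {
    elems <- matrix(order(cell_of)[cell_of[order(cell_of)] %in% complete],
                    ncol = 6, byrow = TRUE)
    aux <- .lattice_aux(matrix(remap[corners[complete, , drop = FALSE]],
                               ncol = 8), elems)
  }

  region <- ifelse(ch == "RV", "RV_MYO", "LV_MYO")
  mesh <- tet_mesh(nodes, tets, region, chamber = ch)
  sf <- .surface_faces(nodes, tets)
  mesh$surface <- .classify_surface(nodes, sf$faces, sf$opp, sf$elem,
                                    mesh$chamber, f, h)
  # septum: LV elements within the angular/apicobasal footprint of the
  # RV-facing septal endocardium
  sept_cen <- mesh$surface$centroid[mesh$surface$tag == "RV_ENDO_SEPTAL", ,
                                    drop = FALSE]
  if (nrow(sept_cen)) {
    phi_sept <- atan2(sept_cen[, 2], sept_cen[, 1])
    phi_e <- atan2(cen[, 2], cen[, 1])
    region[ch == "LV" & phi_e >= min(phi_sept) & phi_e <= max(phi_sept) &
             cen[, 3] >= min(sept_cen[, 3])] <- "SEPTUM"
  }
  # excluded regions: valve ring at the base, supero-anterior RV outflow
  region[cen[, 3] > f$z_base - 4] <- "EXCLUDED_VALVE"
  region[ch == "RV" & cen[, 2] > 10 & cen[, 3] > f$z_base - 14 &
           region != "EXCLUDED_VALVE"] <- "EXCLUDED_OUTFLOW"
  mesh$region <- region
  mesh$meta$params <- p
  mesh$meta$fields <- f[c("a0", "c0", "a1", "c1", "z_base", "z_apex",
                          "rx", "rz", "rax", "ray", "raz", "rv_wall")]
  mesh$meta$aux <- aux
  mesh$meta$edges <- mesh_edges(mesh)

  # UVC: analytic rho/phi, geodesic wall-depth tau, chamber-based ventricle
  node_ch <- rep("RV", nrow(nodes))
  lv_nodes <- unique(as.vector(tets[ch == "LV", ]))
  node_ch[lv_nodes] <- "LV"
  rho <- pmin(pmax((nodes[, 3] - f$z_apex) / (f$z_base - f$z_apex), 0), 1)
  phi <- atan2(nodes[, 2], nodes[, 1])
  phi[phi <= -pi] <- pi
  tau <- .transmural_depth(mesh, node_ch)
  uvc <- uvc_coords(rho, tau, phi, node_ch)

  mesh <- assign_fibres(mesh, uvc, alpha_endo = alpha_endo,
                        alpha_epi = alpha_epi)
  list(mesh = mesh, uvc = uvc, params = p)
}

#' Rectangular slab mesh (validation fixture)
#'
#' A homogeneous slab with a uniform fibre field, used for conduction-speed
#' recovery experiments. All elements are labelled LV_MYO.
#'
#' @param dims slab extents (mm), length 3.
#' @param edge_length target edge length (mm); lattice spacing is 0.75 x it,
#'   as for hearts.
#' @param fibre fibre direction (need not be unit).
#' @return a `tet_mesh`.
#' @export
slab_mesh <- function(dims = c(40, 20, 10), edge_length = 2,
                      fibre = c(1, 0, 0)) {
  h <- 0.75 * edge_length
  xs <- seq(0, dims[1], by = h); ys <- seq(0, dims[2], by = h)
  zs <- seq(0, dims[3], by = h)
  nx <- length(xs); ny <- length(ys); nzp <- length(zs)
  gx <- rep(xs, times = ny * nzp)
  gy <- rep(rep(ys, each = nx), times = nzp)
  gz <- rep(zs, each = nx * ny)
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nzp - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nzp - 1L)
  ck <- rep(seq_len(nzp - 1L), each = (nx - 1L) * (ny - 1L))
  corner <- function(di, dj, dk) nid(ci + di, cj + dj, ck + dk)
  corners <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
                   corner(0L, 1L, 0L), corner(1L, 1L, 0L),
                   corner(0L, 0L, 1L), corner(1L, 0L, 1L),
                   corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  tets <- do.call(rbind, lapply(seq_len(6), function(t)
    corners[, .KUHN[t, ], drop = FALSE]))
  nodes <- cbind(gx, gy, gz)
  tets <- .orient_tets(nodes, tets)
  fib <- matrix(rep(fibre / sqrt(sum(fibre^2)), each = nrow(tets)), ncol = 3)
  mesh <- tet_mesh(nodes, tets, region = rep("LV_MYO", nrow(tets)),
                   chamber = rep("LV", nrow(tets)), fibre = fib)
  ncell <- nrow(corners)
  mesh$meta$aux <- .lattice_aux(corners,
                               matrix(seq_len(6L * ncell),
                                      ncol = 6)[, , drop = FALSE])
  mesh$meta$edges <- mesh_edges(mesh)
  mesh
}

#' Assign a rule-based transmural helix fibre field
#'
#' The helix angle varies linearly in the transmural coordinate from
#' `alpha_endo` at the endocardium to `alpha_epi` at the epicardium and the
#' fibre is laid in the local circumferential-longitudinal tangent plane of
#' the wall. The construction rule is a standard simplified stand-in; its
#' parameters are exposed.
#'
#' @param mesh a `tet_mesh`.
#' @param uvc a `uvc` object for the mesh nodes.
#' @param alpha_endo,alpha_epi helix angles in degrees (defaults +60/-60).
#' @return the mesh with per-element unit `fibre` vectors.
#' @export
assign_fibres <- function(mesh, uvc, alpha_endo = 60, alpha_epi = -60) {
  if (is.null(uvc) || !inherits(uvc, "uvc"))
    stop("assign_fibres requires universal ventricular coordinates; ",
         "generate them (generate_heart) or supply them explicitly")
  cen <- element_centroids(mesh)
  tau_e <- (uvc$tau[mesh$tets[, 1]] + uvc$tau[mesh$tets[, 2]] +
            uvc$tau[mesh$tets[, 3]] + uvc$tau[mesh$tets[, 4]]) / 4
  fm <- mesh$meta$fields
  lv <- mesh$chamber == "LV"
  # transmural normal from the bounding (epi) ellipsoid gradient per chamber
  nrm <- matrix(0, nrow(cen), 3)
  if (is.null(fm)) {
    # imported mesh without construction fields: radial about the z axis
    nrm <- cbind(cen[, 1], cen[, 2], 0)
  } else {
    nrm[lv, ] <- cbind(cen[lv, 1] / fm$a1^2, cen[lv, 2] / fm$a1^2,
                       cen[lv, 3] / fm$c1^2)
    rax1 <- fm$rax + fm$rv_wall; ray1 <- fm$ray + fm$rv_wall
    raz1 <- fm$raz + fm$rv_wall
    nrm[!lv, ] <- cbind((cen[!lv, 1] - fm$rx) / rax1^2,
                        cen[!lv, 2] / ray1^2,
                        (cen[!lv, 3] - fm$rz) / raz1^2)
  }
  nn <- sqrt(rowSums(nrm * nrm))
  bad <- nn < 1e-9
  nrm[bad, ] <- matrix(rep(c(1, 0, 0), sum(bad)), ncol = 3, byrow = TRUE)
  nrm <- nrm / sqrt(rowSums(nrm * nrm))
  # circumferential = z x normal; longitudinal = normal x circumferential
  circ <- cbind(-nrm[, 2], nrm[, 1], 0)
  cn <- sqrt(rowSums(circ * circ))
  deg <- cn < 1e-9
  circ[deg, ] <- matrix(rep(c(0, 1, 0), sum(deg)), ncol = 3, byrow = TRUE)
  circ <- circ / sqrt(rowSums(circ * circ))
  lon <- cbind(nrm[, 2] * circ[, 3] - nrm[, 3] * circ[, 2],
               nrm[, 3] * circ[, 1] - nrm[, 1] * circ[, 3],
               nrm[, 1] * circ[, 2] - nrm[, 2] * circ[, 1])
  alpha <- ((1 - tau_e) * alpha_endo + tau_e * alpha_epi) * pi / 180
  fib <- cos(alpha) * circ + sin(alpha) * lon
  fib <- fib / sqrt(rowSums(fib * fib))
  mesh$fibre <- fib
  mesh$meta$helix <- c(alpha_endo = alpha_endo, alpha_epi = alpha_epi)
  mesh
}

#' Local circumferential/longitudinal frame of elements
#'
#' Returns the frame used by [assign_fibres()] (unit circumferential,
#' longitudinal and transmural-normal vectors per element), for projecting
#' fibre fields back onto helix angles.
#'
#' @param mesh a `tet_mesh` generated by this package.
#' @return list of three m x 3 matrices `circ`, `lon`, `normal`.
#' @export
element_frames <- function(mesh) {
  fib <- mesh$fibre
  mesh$fibre <- NULL
  # reuse assign_fibres machinery at alpha = 0 to recover circ, and 90 for lon
  uvc0 <- uvc_coords(rep(0, nrow(mesh$nodes)), rep(0, nrow(mesh$nodes)),
                     rep(0, nrow(mesh$nodes)),
                     rep("LV", nrow(mesh$nodes)))
  m0 <- assign_fibres(mesh, uvc0, alpha_endo = 0, alpha_epi = 0)
  m90 <- assign_fibres(mesh, uvc0, alpha_endo = 90, alpha_epi = 90)
  circ <- m0$fibre; lon <- m90$fibre
  nrm <- cbind(circ[, 2] * lon[, 3] - circ[, 3] * lon[, 2],
               circ[, 3] * lon[, 1] - circ[, 1] * lon[, 3],
               circ[, 1] * lon[, 2] - circ[, 2] * lon[, 1])
  list(circ = circ, lon = lon, normal = nrm)
}

#' Validate mesh invariants
#'
#' Checks positive signed volumes, unit fibre norms, that every node belongs
#' to at least one element, and (for labelled hearts) that septal elements
#' are reachable from both the LV and RV-septal endocardial surfaces through
#' the element adjacency implied by shared nodes.
#'
#' @param mesh a `tet_mesh`.
#' @return TRUE invisibly; stops with a message on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0)) stop("mesh has ", sum(v <= 0), " non-positive tetrahedra")
  if (!is.null(mesh$fibre)) {
    nn <- sqrt(rowSums(mesh$fibre^2))
    if (any(abs(nn - 1) > 1e-9)) stop("non-unit fibre vectors present")
  }
  if (length(setdiff(seq_len(nrow(mesh$nodes)), unique(as.vector(mesh$tets)))))
    stop("mesh has orphan nodes")
  if (!is.null(mesh$surface) && any(mesh$region == "SEPTUM")) {
    ed <- mesh_edges(mesh)$edges
    g <- igraph::make_graph(rbind(ed$i, ed$j), n = nrow(mesh$nodes),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
    surf <- mesh$surface
    lv_endo <- unique(as.vector(surf$faces[surf$tag == "LV_ENDO", ]))
    rv_sep <- unique(as.vector(surf$faces[surf$tag == "RV_ENDO_SEPTAL", ]))
    sept_nodes <- unique(as.vector(mesh$tets[mesh$region == "SEPTUM", ]))
    if (!all(comp[sept_nodes] %in% comp[lv_endo]) ||
        !all(comp[sept_nodes] %in% comp[rv_sep]))
      stop("septal elements not reachable from both endocardial surfaces")
  }
  invisible(TRUE)
}
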