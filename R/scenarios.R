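# Substrates and pacing protocols.
#
# Substrates: INTACT conduction, proximal LBBB (the His-to-left-bundle
# connection cut bidirectionally), and SEPTAL_SCAR (a UVC-mapped transmural
# septal core simulated as non-conducting, with overlapping Purkinje
# deactivated).  Protocols: BASELINE_JUNCTIONAL (His-root stimulation under
# AV block), proximal/distal left bundle pacing (PLBBP at 10% of the left
# bundle, DLBBP at the posterior-fascicle origin) and leadless RV septal
# pacing at the outflow-tract septum, mid-septum and apical septum
# (RVOT-S / MS / AS).

#' Substrate labels
#' @export
SUBSTRATE_LEVELS <- c("INTACT", "LBBB", "SEPTAL_SCAR")

#' Protocol labels
#' @export
PROTOCOL_LEVELS <- c("BASELINE_JUNCTIONAL", "PLBBP", "DLBBP",
                     "RVOT_S", "MS", "AS")

#' Pacing site specification
#'
#' Tree sites are located by branch label and fractional distance along the
#' branch; mesh sites by a UVC target on a tagged endocardial surface.
#'
#' @param kind "TREE_NODE" or "MESH_NODE".
#' @param branch,fraction tree locator (branch label, fraction in [0,1]).
#' @param rho,phi,surface mesh locator (UVC target and surface tag).
#' @param onset stimulus onset (ms).
#' @return object of class `pacing_site`.
#' @export
pacing_site <- function(kind = c("TREE_NODE", "MESH_NODE"), branch = NULL,
                        fraction = 0, rho = NULL, phi = 0,
                        surface = "RV_ENDO_SEPTAL", onset = 0) {
  kind <- match.arg(kind)
  if (kind == "TREE_NODE" && is.null(branch))
    stop("TREE_NODE site needs a branch label")
  if (kind == "MESH_NODE" && is.null(rho))
    stop("MESH_NODE site needs a UVC target (rho)")
  structure(list(kind = kind, branch = branch, fraction = fraction,
                 rho = rho, phi = phi, surface = surface, onset = onset),
            class = "pacing_site")
}

#' Default pacing site of a protocol
#'
#' PLBBP paces at 10% of the left bundle; DLBBP at the origin of the left
#' posterior fascicle; RVOT-S, MS and AS on the RV septal endocardium at
#' apicobasal 0.90, 0.50 and 0.15 (septal centre); the junctional baseline
#' stimulates the His root.
#'
#' @param protocol one of `PROTOCOL_LEVELS`.
#' @param sites optional named list of overrides.
#' @return a [pacing_site()].
#' @export
protocol_site <- function(protocol, sites = NULL) {
  if (!is.null(sites) && !is.null(sites[[protocol]]))
    return(sites[[protocol]])
  switch(protocol,
    BASELINE_JUNCTIONAL = pacing_site("TREE_NODE", branch = "HIS",
                                      fraction = 0),
    PLBBP = pacing_site("TREE_NODE", branch = "LEFT_BUNDLE", fraction = 0.1),
    DLBBP = pacing_site("TREE_NODE", branch = "LV_POSTERIOR_FASCICLE",
                        fraction = 0),
    RVOT_S = pacing_site("MESH_NODE", rho = 0.90),
    MS = pacing_site("MESH_NODE", rho = 0.50),
    AS = pacing_site("MESH_NODE", rho = 0.15),
    stop("unknown protocol: ", protocol))
}

#' Resolve a pacing site to a concrete stimulus node
#'
#' Mesh sites resolve to the tagged surface node nearest the UVC target
#' (ties broken by lowest node index); tree sites to the node at the given
#' fraction along the named branch.  For the His branch, fraction 0 is the
#' His root.
#'
#' @param mesh,uvc,tree the heart model.
#' @param site a [pacing_site()].
#' @param scar optional `scar_region`; resolving a mesh site inside the
#'   scar core is an error (the site is clinically infeasible there).
#' @return list(kind, node, onset) with kind "tree"/"mesh".
#' @export
resolve_site <- function(mesh, uvc, tree, site, scar = NULL) {
  stopifnot(inherits(site, "pacing_site"))
  if (site$kind == "TREE_NODE") {
    node <- if (site$branch == "HIS" && site$fraction == 0) tree$root
            else branch_node_at(tree, site$branch, site$fraction)
    return(list(kind = "tree", node = node, onset = site$onset))
  }
  cand <- .surface_nodes(mesh, site$surface)
  if (!length(cand)) stop("no surface nodes tagged ", site$surface)
  node <- .nearest_uvc(uvc, cand, site$rho, site$phi)
  if (!is.null(scar) && length(scar$core)) {
    cond <- setdiff(seq_len(nrow(mesh$tets)), scar$core)
    if (!(node %in% unique(as.vector(mesh$tets[cond, , drop = FALSE]))))
      stop("resolved pacing site lies inside the scar core; ",
           "relocate the site (adjust rho/phi) as an implanter would")
  }
  list(kind = "mesh", node = node, onset = site$onset)
}

#' Septal scar specification in UVC space
#'
#' The core is the set of elements whose UVC centroid falls in the given
#' apicobasal, rotational and transmural ranges (the rotational range is
#' centred on the septum); the border zone is the same predicate dilated by
#' `border_margin` in rho/phi, conducting at `border_cv_multiplier` times
#' the native velocities.  The default core spans rho 0.10-0.68 over the
#' full septal angle and reaches from the LV septal endocardium to
#' transmural depth 0.85, leaving a thin RV subendocardial rim so that RV
#' septal pacing sites remain capturable.
#'
#' @param rho,phi,tau core ranges (length-2 numerics).
#' @param border_margin dilation of rho and phi for the border zone.
#' @param border_cv_multiplier border-zone conduction-velocity multiplier
#'   (1 = native).
#' @return object of class `scar_spec`.
#' @export
scar_spec <- function(rho = c(0.10, 0.68), phi = c(-1.3, 1.3),
                      tau = c(0, 0.85), border_margin = 0.07,
                      border_cv_multiplier = 1) {
  structure(list(rho = rho, phi = phi, tau = tau,
                 border_margin = border_margin,
                 border_cv_multiplier = border_cv_multiplier),
            class = "scar_spec")
}

#' Map a scar specification onto a heart
#'
#' Labels every element whose UVC centroid satisfies the core predicate as
#' CORE, the dilated-predicate remainder as BORDER, everything else
#' HEALTHY.  Deterministic; a predicate selecting no elements yields an
#' empty region with a warning.
#'
#' @param mesh,uvc the heart.
#' @param spec a [scar_spec()] (or an explicit integer element set, taken
#'   as the core).
#' @return object of class `scar_region` with `core`, `border` (element
#'   indices), `zone` (per-element factor) and `cv_multiplier`.
#' @export
map_scar <- function(mesh, uvc, spec) {
  m <- nrow(mesh$tets)
  if (is.numeric(spec)) {
    core <- sort(as.integer(spec)); border <- integer(0); mult <- 1
  } else {
    stopifnot(inherits(spec, "scar_spec"))
    cen <- element_centroids(mesh)
    rho_e <- (uvc$rho[mesh$tets[, 1]] + uvc$rho[mesh$tets[, 2]] +
              uvc$rho[mesh$tets[, 3]] + uvc$rho[mesh$tets[, 4]]) / 4
    tau_e <- (uvc$tau[mesh$tets[, 1]] + uvc$tau[mesh$tets[, 2]] +
              uvc$tau[mesh$tets[, 3]] + uvc$tau[mesh$tets[, 4]]) / 4
    phi_e <- atan2(cen[, 2], cen[, 1])
    lv <- mesh$chamber == "LV"
    inrange <- function(x, r) x >= r[1] & x <= r[2]
    in_core <- lv & inrange(rho_e, spec$rho) & inrange(phi_e, spec$phi) &
      inrange(tau_e, spec$tau)
    mg <- spec$border_margin
    in_border <- lv & inrange(rho_e, spec$rho + c(-mg, mg)) &
      inrange(phi_e, spec$phi + c(-mg * 3, mg * 3)) &
      inrange(tau_e, spec$tau + c(0, mg)) & !in_core
    core <- which(in_core); border <- which(in_border)
    mult <- spec$border_cv_multiplier
  }
  if (!length(core)) warning("scar predicate selected no elements")
  zone <- rep("HEALTHY", m)
  zone[border] <- "BORDER"
  zone[core] <- "CORE"
  structure(list(core = core, border = border, zone = zone,
                 cv_multiplier = mult), class = "scar_region")
}

#' @export
print.scar_region <- function(x, ...) {
  cat(sprintf("Scar region: %d core, %d border elements (border CV x%.2f)\n",
              length(x$core), length(x$border), x$cv_multiplier))
  invisible(x)
}

#' Conduction configuration of a substrate
#'
#' Applies a scar region to a base conduction configuration: core elements
#' become non-conducting, border elements get the border CV multiplier.
#'
#' @param config a [conduction_config()].
#' @param scar a `scar_region` or NULL.
#' @param n_elem number of mesh elements.
#' @return a [conduction_config()].
#' @export
substrate_config <- function(config, scar, n_elem) {
  if (is.null(scar) || !length(scar$core)) return(config)
  config$nonconducting <- scar$core
  if (scar$cv_multiplier != 1) {
    mult <- rep(1, n_elem)
    mult[scar$border] <- scar$cv_multiplier
    config$cv_multiplier <- mult
  }
  config
}

#' Scenario matrix
#'
#' The full default matrix crosses the three substrates with the junctional
#' baseline and the five pacing protocols (18 scenarios); every pacing
#' scenario carries complete AV block, and the baseline stimulates the His
#' root (AV node blocked, His intact).
#'
#' @param substrates subset of `SUBSTRATE_LEVELS`.
#' @param protocols subset of `PROTOCOL_LEVELS`.
#' @return data.frame of class `scenario_matrix` with substrate, protocol,
#'   av_block.
#' @export
build_scenario_matrix <- function(substrates = SUBSTRATE_LEVELS,
                                  protocols = PROTOCOL_LEVELS) {
  bad <- setdiff(substrates, SUBSTRATE_LEVELS)
  if (length(bad)) stop("unknown substrate(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(protocols, PROTOCOL_LEVELS)
  if (length(bad)) stop("unknown protocol(s): ", paste(bad, collapse = ", "))
  out <- expand.grid(protocol = protocols, substrate = substrates,
                     stringsAsFactors = FALSE)[, c("substrate", "protocol")]
  out$av_block <- TRUE
  class(out) <- c("scenario_matrix", "data.frame")
  out
}

#' Run one scenario on one heart
#'
#' Applies the substrate (LBBB cut and/or scar mapping with Purkinje
#' deactivation), resolves the protocol's pacing site and runs the coupled
#' activation solve.
#'
#' @param heart list(mesh, uvc) from [generate_heart()].
#' @param tree the heart's intact `purkinje_tree`.
#' @param substrate,protocol scenario coordinates.
#' @param config base [conduction_config()].
#' @param scar optional prebuilt `scar_region` (required for SEPTAL_SCAR).
#' @param sites optional site overrides (see [protocol_site()]).
#' @param graph optional prebuilt union graph for this substrate.
#' @return list(act, stimulus, tree, config).
#' @export
run_scenario <- function(heart, tree, substrate, protocol, config,
                         scar = NULL, sites = NULL, graph = NULL) {
  mesh <- heart$mesh; uvc <- heart$uvc
  cfg <- config
  tr <- tree
  if (substrate == "LBBB") tr <- apply_lbbb(tr)
  if (substrate == "SEPTAL_SCAR") {
    if (is.null(scar)) stop("SEPTAL_SCAR substrate needs a scar region")
    tr <- deactivate_scar_overlap(tr, scar, mesh, uvc)
    cfg <- substrate_config(cfg, scar, nrow(mesh$tets))
  }
  site <- protocol_site(protocol, sites)
  stim <- resolve_site(mesh, uvc, tr, site,
                       scar = if (substrate == "SEPTAL_SCAR") scar)
  act <- solve_coupled(mesh, tr, cfg,
                       data.frame(kind = stim$kind, node = stim$node,
                                  onset = stim$onset), graph = graph)
  list(act = act, stimulus = stim, tree = tr, config = cfg)
}
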