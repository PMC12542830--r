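# Dyssynchrony measures on an activation map.
#
# VEU (ventricular electrical uncoupling): mean LV epicardial minus mean RV
# epicardial activation time; positive means the LV activates later.
# Absolute VEU is |VEU|, taken per heart before any cohort averaging.
# LVDI: standard deviation of activation times within the LV (population SD
# by default).  BIVAT-90: shortest interval containing activation of 90% of
# the biventricular nodes.  Nodes around the AV valves and outflow tracts
# are excluded from every region.

#' Metric regions of a labelled heart mesh
#'
#' Node sets used by the dyssynchrony measures: LV and RV epicardial nodes,
#' all LV myocardial nodes (septum included), and all biventricular nodes,
#' each minus the exclusion mask.  A node is excluded when every element it
#' belongs to is an excluded (valve-ring or outflow) element.
#'
#' @param mesh a `tet_mesh` with classified surfaces.
#' @param uvc matching `uvc` coordinates (ventricle labels).
#' @param scar optional `scar_region`: nodes fully inside the
#'   non-conducting core are not viable myocardium and are excluded from
#'   every region (they can never activate).
#' @return object of class `metric_regions` with integer node sets `lv_epi`,
#'   `rv_epi`, `lv_all`, `biv`, `excluded`.
#' @export
metric_regions <- function(mesh, uvc, scar = NULL) {
  n <- nrow(mesh$nodes)
  excl_elem <- mesh$region %in% c("EXCLUDED_VALVE", "EXCLUDED_OUTFLOW")
  if (!is.null(scar) && length(scar$core))
    excl_elem[scar$core] <- TRUE
  touched <- unique(as.vector(mesh$tets[!excl_elem, , drop = FALSE]))
  excluded <- setdiff(seq_len(n), touched)
  s <- mesh$surface
  nodes_of <- function(tag) unique(as.vector(s$faces[s$tag %in% tag, ]))
  keep <- function(v) sort(setdiff(v, excluded))
  structure(list(
    lv_epi = keep(nodes_of("LV_EPI")),
    rv_epi = keep(nodes_of("RV_EPI")),
    lv_all = keep(which(uvc$ventricle == "LV")),
    biv = keep(seq_len(n)),
    excluded = sort(excluded)), class = "metric_regions")
}

#' @export
print.metric_regions <- function(x, ...) {
  cat(sprintf(paste0("Metric regions: lv_epi %d, rv_epi %d, lv_all %d, ",
                     "biv %d nodes (%d excluded)\n"),
              length(x$lv_epi), length(x$rv_epi), length(x$lv_all),
              length(x$biv), length(x$excluded)))
  invisible(x)
}

#' Write / read metric regions as CSV
#'
#' One row per node with 0/1 membership flags for each region, so that the
#' dyssynchrony measures can be recomputed on externally produced
#' activation maps.
#'
#' @param regions a [metric_regions()].
#' @param path CSV file.
#' @param n_nodes total node count (written files carry it implicitly).
#' @return `write_metric_regions` the path; `read_metric_regions` a
#'   `metric_regions`.
#' @export
write_metric_regions <- function(regions, path,
                                 n_nodes = max(regions$biv,
                                               regions$excluded, 0L)) {
  flag <- function(set) as.integer(seq_len(n_nodes) %in% set)
  utils::write.csv(data.frame(node_id = seq_len(n_nodes),
                              lv_epi = flag(regions$lv_epi),
                              rv_epi = flag(regions$rv_epi),
                              lv_all = flag(regions$lv_all),
                              biv = flag(regions$biv)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metric_regions
#' @export
read_metric_regions <- function(path) {
  df <- utils::read.csv(path)
  structure(list(lv_epi = df$node_id[df$lv_epi == 1],
                 rv_epi = df$node_id[df$rv_epi == 1],
                 lv_all = df$node_id[df$lv_all == 1],
                 biv = df$node_id[df$biv == 1],
                 excluded = df$node_id[df$biv != 1]),
            class = "metric_regions")
}

.region_times <- function(act, nodes, what) {
  if (!length(nodes)) stop("empty region: ", what)
  tt <- act$node_time[nodes]
  nu <- sum(!is.finite(tt))
  if (nu > 0)
    stop(nu, " unreached node(s) in region ", what,
         "; refusing to compute the metric")
  tt
}

#' Ventricular electrical uncoupling (ms)
#'
#' Mean LV epicardial activation time minus mean RV epicardial activation
#' time; positive values mean the LV takes longer to activate.
#'
#' @param act an [activation_map()].
#' @param regions a [metric_regions()].
#' @return VEU in ms.
#' @export
veu <- function(act, regions) {
  mean(.region_times(act, regions$lv_epi, "lv_epi")) -
    mean(.region_times(act, regions$rv_epi, "rv_epi"))
}

#' Absolute ventricular electrical uncoupling (ms)
#'
#' |VEU| of this heart's map.  Cohort summaries must apply this per heart
#' before averaging.
#' @inheritParams veu
#' @return |VEU| in ms.
#' @export
abs_veu <- function(act, regions) abs(veu(act, regions))

#' Left ventricular dyssynchrony index (ms)
#'
#' Standard deviation of activation times over all LV myocardial nodes.
#'
#' @inheritParams veu
#' @param type "population" (N denominator, default) or "sample" (N-1).
#' @return LVDI in ms.
#' @export
lvdi <- function(act, regions, type = c("population", "sample")) {
  type <- match.arg(type)
  tt <- .region_times(act, regions$lv_all, "lv_all")
  if (type == "sample") return(stats::sd(tt))
  sqrt(mean((tt - mean(tt))^2))
}

#' Shortest interval activating 90% of both ventricles (ms)
#'
#' Sliding-window minimum over the sorted biventricular activation times:
#' with N node times and m = ceiling(0.9 N), the smallest t[k+m-1] - t[k].
#' `method = "quantile"` instead returns the 90th percentile minus the
#' minimum (a common simplification); the windowed reading honours
#' "shortest interval" literally and is the default.  With
#' `weights = "volume"` nodes are weighted by their share of incident
#' element volume and the window covers 90% of the myocardial volume.
#'
#' @inheritParams veu
#' @param fraction fraction of the ventricles to cover (default 0.9).
#' @param method "window" or "quantile".
#' @param weights "node" (unweighted) or "volume"; volume weighting needs
#'   `mesh`.
#' @param mesh the mesh (only for volume weighting).
#' @return BIVAT interval in ms.
#' @export
bivat90 <- function(act, regions, fraction = 0.9,
                    method = c("window", "quantile"),
                    weights = c("node", "volume"), mesh = NULL) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  tt <- .region_times(act, regions$biv, "biv")
  n <- length(tt)
  if (n * fraction < 1) stop("region too small for the requested fraction")
  if (weights == "node") {
    st <- sort(tt)
    if (method == "quantile")
      return(as.numeric(stats::quantile(st, fraction, type = 1) - st[1]))
    m <- ceiling(fraction * n)
    return(min(st[m:n] - st[seq_len(n - m + 1)]))
  }
  if (is.null(mesh)) stop("volume weighting requires the mesh")
  vol <- tet_volumes(mesh$nodes, mesh$tets) / 4
  w <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    agg <- rowsum(vol, mesh$tets[, k])
    idx <- as.integer(rownames(agg))
    w[idx] <- w[idx] + agg[, 1]
  }
  w <- w[regions$biv]
  o <- order(tt)
  st <- tt[o]; sw <- w[o]
  cw <- cumsum(sw)
  need <- fraction * cw[n]
  if (method == "quantile")
    return(st[which(cw >= need)[1]] - st[1])
  # two-pointer minimal window with cumulative weight >= need
  best <- Inf; lo <- 1L
  for (hi in seq_len(n)) {
    while (cw[hi] - (if (lo > 1L) cw[lo - 1L] else 0) >= need) {
      best <- min(best, st[hi] - st[lo])
      lo <- lo + 1L
    }
  }
  if (!is.finite(best)) best <- st[n] - st[1]
  best
}

#' All four dyssynchrony measures of one activation map
#'
#' @inheritParams veu
#' @param ... passed to [lvdi()] and [bivat90()].
#' @return object of class `metric_set`: veu, abs_veu, lvdi, bivat90 (ms)
#'   and n_unreached (over the biventricular region).
#' @export
compute_metrics <- function(act, regions, ...) {
  nu <- sum(!is.finite(act$node_time[regions$biv]))
  v <- veu(act, regions)
  structure(list(veu = v, abs_veu = abs(v),
                 lvdi = lvdi(act, regions),
                 bivat90 = bivat90(act, regions, ...),
                 n_unreached = nu), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("VEU %.1f ms | |VEU| %.1f ms | LVDI %.1f ms | ",
                     "BIVAT-90 %.1f ms (%d unreached)\n"),
              x$veu, x$abs_veu, x$lvdi, x$bivat90, x$n_unreached))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(veu = x$veu, abs_veu = x$abs_veu, lvdi = x$lvdi,
             bivat90 = x$bivat90, n_unreached = x$n_unreached)
}
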