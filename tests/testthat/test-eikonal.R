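test_that("isotropic point source recovers straight-line times on a slab", {
  v <- 0.5
  mesh <- slab_mesh(dims = c(30, 12, 9), edge_length = 2, fibre = c(1, 0, 0))
  cfg <- conduction_config(cv_fibre = v, cv_transverse = v)
  src <- which(mesh$nodes[, 1] == 0 & mesh$nodes[, 2] == 0 &
               mesh$nodes[, 3] == 0)
  act <- solve_myocardium(mesh, cfg, src)
  r <- sqrt(rowSums(sweep(mesh$nodes, 2, mesh$nodes[src, ])^2))
  # graph metrization can only overestimate the continuum time, and along
  # lattice axis directions it is exact
  expect_true(all(act$node_time >= r / v - 1e-9))
  axis_nodes <- which(mesh$nodes[, 2] == 0 & mesh$nodes[, 3] == 0)
  expect_equal(act$node_time[axis_nodes], r[axis_nodes] / v,
               tolerance = 1e-12)
  # the augmented lattice direction set realises the 26-neighbourhood
  # chamfer metric, whose worst-direction overestimate is
  # sqrt(1 + (sqrt(2)-1)^2 + (sqrt(3)-sqrt(2))^2) = 1.1281
  interior <- r > 8
  bound <- sqrt(1 + (sqrt(2) - 1)^2 + (sqrt(3) - sqrt(2))^2)
  expect_lt(max(act$node_time[interior] / (r[interior] / v)), bound + 1e-6)
})

test_that("planar waves recover the configured fibre and transverse speeds", {
  for (case in list(list(fib = c(1, 0, 0), cv = 0.6),
                    list(fib = c(0, 0, 1), cv = 0.24))) {
    mesh <- slab_mesh(dims = c(40, 20, 10), edge_length = 2,
                      fibre = case$fib)
    cfg <- conduction_config()
    src <- which(mesh$nodes[, 1] == 0)
    act <- solve_myocardium(mesh, cfg, src)
    sel <- mesh$nodes[, 1] > 5 & mesh$nodes[, 1] < 35
    fit <- stats::lm(act$node_time[sel] ~ mesh$nodes[sel, 1])
    speed <- 1 / stats::coef(fit)[[2]]
    expect_lt(abs(speed - case$cv) / case$cv, 0.05)
  }
})

test_that("myocardial solve equals a brute-force Dijkstra exactly", {
  mesh <- slab_mesh(dims = c(12, 9, 6), edge_length = 3,
                    fibre = c(1, 1, 0.3))
  cfg <- conduction_config(cv_fibre = 0.7, cv_transverse = 0.2)
  ed <- conduction_graph(mesh, cfg)
  for (src in c(1L, 50L)) {
    act <- solve_myocardium(mesh, cfg, src)
    d <- brute_dijkstra(nrow(mesh$nodes), c(ed$i, ed$j), c(ed$j, ed$i),
                        rep(ed$time, 2), src)
    expect_equal(act$node_time, d, tolerance = 1e-12)
  }
})

test_that("anisotropic times converge to isotropic as the ratio vanishes", {
  mesh <- slab_mesh(dims = c(15, 9, 6), edge_length = 2.5,
                    fibre = c(1, 0.5, 0))
  src <- 1L
  iso <- solve_myocardium(mesh, conduction_config(cv_fibre = 0.6,
                                                  cv_transverse = 0.6),
                          src)$node_time
  dev <- sapply(c(0.3, 0.5, 0.59, 0.6), function(ct) {
    a <- solve_myocardium(mesh, conduction_config(cv_fibre = 0.6,
                                                  cv_transverse = ct),
                          src)$node_time
    max(abs(a - iso) / pmax(iso, 1e-9))
  })
  expect_true(all(diff(dev) <= 1e-12))
  expect_lt(dev[4], 1e-6)
})

test_that("non-conducting elements are opaque and removable equivalently", {
  mesh <- slab_mesh(dims = c(20, 10, 8), edge_length = 2.5,
                    fibre = c(1, 0, 0))
  mesh$meta$aux <- NULL  # compare on the structural edge graph
  cen <- element_centroids(mesh)
  core <- which(cen[, 1] > 8 & cen[, 1] < 12)
  cfg <- conduction_config(nonconducting = core)
  src <- which(mesh$nodes[, 1] == 0)
  act <- solve_myocardium(mesh, cfg, src)
  # nodes fully inside the core are never reached
  core_only <- setdiff(seq_len(nrow(mesh$nodes)),
                       unique(as.vector(mesh$tets[-core, ])))
  expect_true(all(!is.finite(act$node_time[core_only])))
  # deleting the core elements entirely gives identical times elsewhere
  keep <- setdiff(seq_len(nrow(mesh$tets)), core)
  used <- sort(unique(as.vector(mesh$tets[keep, ])))
  remap <- match(seq_len(nrow(mesh$nodes)), used)
  mesh2 <- tet_mesh(mesh$nodes[used, ], matrix(remap[mesh$tets[keep, ]],
                                               ncol = 4),
                    region = mesh$region[keep], chamber = mesh$chamber[keep],
                    fibre = mesh$fibre[keep, ])
  act2 <- solve_myocardium(mesh2, conduction_config(), remap[src])
  shared <- which(!is.na(remap) & is.finite(act$node_time))
  expect_equal(act$node_time[shared], act2$node_time[remap[shared]],
               tolerance = 1e-12)
})

test_that("stimuli inside scar are dropped with warnings, all-in-scar unreaches", {
  mesh <- slab_mesh(dims = c(12, 9, 6), edge_length = 3, fibre = c(1, 0, 0))
  cen <- element_centroids(mesh)
  core <- which(cen[, 1] < 5)
  cfg <- conduction_config(nonconducting = core)
  core_only <- setdiff(seq_len(nrow(mesh$nodes)),
                       unique(as.vector(mesh$tets[-core, ])))
  expect_error(solve_myocardium(mesh, cfg, integer(0)), "empty")
  expect_warning(
    expect_warning(act <- solve_myocardium(mesh, cfg, core_only[1]),
                   "non-conducting"),
    "unreached")
  expect_true(all(!is.finite(act$node_time)))
})

test_that("coupled solve equals brute-force Dijkstra on the union graph", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    ua <- union_arcs(inst$mesh, inst$tree, inst$config)
    stim <- pacedys:::.coupled_stimuli(inst$stim, ua$n_mesh)
    d <- brute_dijkstra(ua$n_mesh + ua$n_tree, ua$arcs$from, ua$arcs$to,
                        ua$arcs$w, stim$v, stim$onset)
    act <- suppressWarnings(
      solve_coupled(inst$mesh, inst$tree, inst$config, inst$stim))
    expect_equal(c(act$node_time, act$tree_time), unname(d),
                 tolerance = 1e-12)
  }
})

test_that("alternating coupling matches the union solve and converges fast", {
  for (seed in 21:26) {
    inst <- random_instance(seed)
    a1 <- suppressWarnings(
      solve_coupled(inst$mesh, inst$tree, inst$config, inst$stim))
    a2 <- suppressWarnings(
      solve_coupled(inst$mesh, inst$tree, inst$config, inst$stim,
                    method = "alternating"))
    expect_equal(a1$node_time, a2$node_time, tolerance = 1e-9)
    expect_equal(a1$tree_time, a2$tree_time, tolerance = 1e-9)
    expect_lte(attr(a2, "iterations"), nrow(inst$tree$pmjs) + 2)
  }
})

test_that("His-root stimulation with zero PMJ delay reaches the myocardium at tree time", {
  mesh <- slab_mesh(dims = c(12, 9, 6), edge_length = 3, fibre = c(1, 0, 0))
  # two-segment cable ending in one PMJ at a known mesh node
  nodes <- rbind(c(0, 0, 10), c(0, 0, 8), c(0, 0, 6))
  anchor_node <- which.min(colSums((t(mesh$nodes) - c(0, 0, 6))^2))
  edges <- data.frame(a = c(1, 2), b = c(2, 3), branch = "HIS",
                      fascicle = "HIS", blocked = FALSE)
  pmjs <- data.frame(tree_node = 3L, mesh_node = anchor_node,
                     delay_antero = NA_real_, delay_retro = NA_real_,
                     fascicle = "HIS")
  tree <- purkinje_tree(nodes, edges, root = 1L, pmjs = pmjs, cv_tree = 2)
  cfg <- conduction_config(cv_tree = 2, pmj_delay_antero = 0,
                           pmj_delay_retro = 0)
  act <- solve_coupled(mesh, tree, cfg,
                       data.frame(kind = "tree", node = 1L, onset = 0))
  expect_equal(min(act$node_time), 4 / 2, tolerance = 1e-12)
  expect_equal(act$node_time[anchor_node], 2, tolerance = 1e-12)
  # with a delay, the myocardium starts delay later
  cfg2 <- conduction_config(cv_tree = 2, pmj_delay_antero = 7)
  act2 <- solve_coupled(mesh, tree, cfg2,
                        data.frame(kind = "tree", node = 1L, onset = 0))
  expect_equal(min(act2$node_time), 9, tolerance = 1e-12)
})
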