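test_that("the tree carries five fascicles under the two bundles", {
  tr <- coarse_heart()$tree
  fas <- unique(tr$edges$fascicle[tr$edges$branch %in%
                                    c("PERIPHERAL", BRANCH_LEVELS[3:5],
                                      "RV_SEPTAL_FASCICLE",
                                      "RV_MODERATOR_BAND")])
  expect_setequal(intersect(fas, BRANCH_LEVELS),
                  c("LV_ANTERIOR_FASCICLE", "LV_SEPTAL_FASCICLE",
                    "LV_POSTERIOR_FASCICLE", "RV_SEPTAL_FASCICLE",
                    "RV_MODERATOR_BAND"))
  expect_true(all(c("HIS", "LEFT_BUNDLE", "RIGHT_BUNDLE") %in%
                    tr$edges$branch))
  expect_true(validate_tree(tr))
  # left bundle feeds the three LV fascicles, right bundle the two RV ones
  lv_f <- unique(tr$pmjs$fascicle[grepl("^LV_", tr$pmjs$fascicle)])
  rv_f <- unique(tr$pmjs$fascicle[grepl("^RV_", tr$pmjs$fascicle)])
  expect_length(lv_f, 3)
  expect_length(rv_f, 2)
})

test_that("the PMJ count contract holds for a requested minimum", {
  h <- coarse_heart()
  tr <- build_tree(h$mesh, h$uvc,
                   tree_params(min_pmjs_per_fascicle = 10, seed = 5))
  counts <- table(tr$pmjs$fascicle)
  expect_length(counts, 5)
  expect_true(all(counts >= 10))
})

test_that("tree build is deterministic under a fixed seed", {
  h <- coarse_heart()
  t1 <- build_tree(h$mesh, h$uvc, tree_params(seed = 23))
  t2 <- build_tree(h$mesh, h$uvc, tree_params(seed = 23))
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$edges, t2$edges)
  expect_identical(t1$pmjs, t2$pmjs)
})

test_that("root-to-node conduction times equal path length over velocity", {
  tr <- coarse_heart()$tree
  tt <- solve_tree(tr, tr$root)
  # independent recomputation with the naive Dijkstra oracle
  ed <- tr$edges
  d <- brute_dijkstra(nrow(tr$nodes), c(ed$a, ed$b), c(ed$b, ed$a),
                      rep(ed$len, 2) / tr$cv_tree, tr$root)
  expect_equal(tt, d, tolerance = 1e-12)
  # spot check: a leaf's time is its unique path length / cv
  leaf <- tr$pmjs$tree_node[1]
  g <- igraph::make_graph(rbind(ed$a, ed$b), n = nrow(tr$nodes),
                          directed = FALSE)
  p <- igraph::shortest_paths(g, tr$root, leaf, weights = ed$len)$vpath[[1]]
  seglen <- sqrt(rowSums((tr$nodes[p[-1], , drop = FALSE] -
                          tr$nodes[p[-length(p)], , drop = FALSE])^2))
  expect_equal(tt[leaf], sum(seglen) / tr$cv_tree, tolerance = 1e-9)
})

test_that("proximal LBBB cuts exactly the His-left bundle junction, both ways", {
  tr0 <- coarse_heart()$tree
  tr <- apply_lbbb(tr0)
  expect_equal(sum(tr$edges$blocked) - sum(tr0$edges$blocked), 1)
  cut <- which(tr$edges$blocked & !tr0$edges$blocked)
  expect_equal(tr$edges$branch[cut], "LEFT_BUNDLE")
  # anterograde: root reaches all RV-fascicle nodes, no LV-fascicle node
  tt <- solve_tree(tr, tr$root)
  lv_nodes <- unique(c(tr$edges$a[grepl("^LV_", tr$edges$fascicle)],
                       tr$edges$b[grepl("^LV_", tr$edges$fascicle)]))
  rv_nodes <- unique(c(tr$edges$a[grepl("^RV_", tr$edges$fascicle)],
                       tr$edges$b[grepl("^RV_", tr$edges$fascicle)]))
  expect_true(all(!is.finite(tt[setdiff(lv_nodes, rv_nodes)])))
  expect_true(all(is.finite(tt[rv_nodes])))
  # retrograde: a distal LV-fascicle stimulus cannot reach the His root
  dist_lv <- tr$pmjs$tree_node[tr$pmjs$fascicle == "LV_POSTERIOR_FASCICLE"][1]
  tt2 <- solve_tree(tr, dist_lv)
  expect_false(is.finite(tt2[tr$root]))
  expect_true(all(is.finite(tt2[setdiff(lv_nodes, rv_nodes)])))
  # idempotence
  tr_twice <- apply_lbbb(tr)
  expect_identical(tr_twice$edges$blocked, tr$edges$blocked)
})

test_that("scar overlap deactivation blocks exactly the midpoint-in-core edges", {
  h <- coarse_heart()
  # empty scar: unchanged
  empty <- suppressWarnings(map_scar(h$mesh, h$uvc,
                                     scar_spec(rho = c(2, 3))))
  expect_identical(deactivate_scar_overlap(h$tree, empty, h$mesh, h$uvc),
                   h$tree)
  # full-septum fully transmural scar: His, left and right bundles blocked
  full <- map_scar(h$mesh, h$uvc,
                   scar_spec(rho = c(0, 1), phi = c(-1.35, 1.35),
                             tau = c(0, 1)))
  trf <- deactivate_scar_overlap(h$tree, full, h$mesh, h$uvc)
  expect_true(all(trf$edges$blocked[trf$edges$branch == "HIS"]))
  expect_true(all(trf$edges$blocked[trf$edges$branch == "LEFT_BUNDLE"]))
  expect_true(all(trf$edges$blocked[trf$edges$branch == "RIGHT_BUNDLE"]))
  # blocked set equals the independent midpoint-in-core enumeration
  oracle <- brute_edges_in_core(h$tree, h$mesh, full$core)
  expect_identical(trf$edges$blocked, oracle)
  # default scar spares the trunks above it and the anterior plunge route
  # is only blocked when the scar's angular extent covers it
  deflt <- map_scar(h$mesh, h$uvc, scar_spec())
  trd <- deactivate_scar_overlap(h$tree, deflt, h$mesh, h$uvc)
  expect_false(any(trd$edges$blocked[trd$edges$branch == "HIS"]))
  expect_true(any(trd$edges$blocked[trd$edges$fascicle ==
                                      "LV_ANTERIOR_FASCICLE"]))
  sparing <- map_scar(h$mesh, h$uvc, scar_spec(phi = c(-1.3, 0.45)))
  trs <- deactivate_scar_overlap(h$tree, sparing, h$mesh, h$uvc)
  expect_false(any(trs$edges$blocked[trs$edges$fascicle ==
                                       "LV_ANTERIOR_FASCICLE"]))
  expect_true(any(trs$edges$blocked[trs$edges$fascicle ==
                                      "LV_POSTERIOR_FASCICLE"]))
})

test_that("adding lesions never speeds up tree conduction", {
  set.seed(42)
  for (rep in 1:5) {
    inst <- random_instance(100 + rep)
    tr <- inst$tree
    tr$edges$blocked <- FALSE
    t0 <- solve_tree(tr, tr$root)
    open <- which(!tr$edges$blocked)
    for (b in sample(open, min(3, length(open)))) {
      tr$edges$blocked[b] <- TRUE
      t1 <- solve_tree(tr, tr$root)
      expect_true(all(t1 >= t0 - 1e-12))
      t0 <- t1
    }
  }
})

test_that("pacing sites resolve along branches as specified", {
  h <- coarse_heart()
  tr <- h$tree
  # fraction 0 of the left bundle is the His-left-bundle junction node
  s0 <- resolve_site(h$mesh, h$uvc, tr,
                     pacing_site("TREE_NODE", branch = "LEFT_BUNDLE",
                                 fraction = 0))
  his_nodes <- unique(c(tr$edges$a[tr$edges$branch == "HIS"],
                        tr$edges$b[tr$edges$branch == "HIS"]))
  lb_nodes <- unique(c(tr$edges$a[tr$edges$branch == "LEFT_BUNDLE"],
                       tr$edges$b[tr$edges$branch == "LEFT_BUNDLE"]))
  expect_true(s0$node %in% intersect(his_nodes, lb_nodes))
  # any positive fraction lies strictly beyond the junction edge
  s1 <- resolve_site(h$mesh, h$uvc, tr,
                     pacing_site("TREE_NODE", branch = "LEFT_BUNDLE",
                                 fraction = 0.1))
  expect_false(s1$node %in% his_nodes)
  # the distal LBBP default sits on the posterior fascicle
  sd <- resolve_site(h$mesh, h$uvc, tr, protocol_site("DLBBP"))
  pf <- unique(c(tr$edges$a[tr$edges$fascicle == "LV_POSTERIOR_FASCICLE"],
                 tr$edges$b[tr$edges$fascicle == "LV_POSTERIOR_FASCICLE"]))
  expect_true(sd$node %in% pf)
})
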