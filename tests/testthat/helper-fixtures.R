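# Shared fixtures, memoized for the whole test session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# coarse heart for structural tests (fast; ~3.5 mm edges)
coarse_heart <- function() memo("coarse_heart", function() {
  spec <- cohort_spec(n_hearts = 2, seed = 7, target_edge_length = 3.5)
  h <- generate_heart(spec, 1)
  h$tree <- build_tree(h$mesh, h$uvc, tree_params(seed = 17))
  h$regions <- metric_regions(h$mesh, h$uvc)
  h
})

# second coarse heart (cohort comparisons)
coarse_heart2 <- function() memo("coarse_heart2", function() {
  spec <- cohort_spec(n_hearts = 2, seed = 7, target_edge_length = 3.5)
  generate_heart(spec, 2)
})

# production-resolution heart (used for the edge-length statistics)
fine_heart <- function() memo("fine_heart", function() {
  spec <- cohort_spec(n_hearts = 19, seed = 1, target_edge_length = 2)
  generate_heart(spec, 1)
})

# a random small coupled instance: tiny slab + random tree + PMJs
random_instance <- function(seed) {
  set.seed(seed)
  fib <- stats::rnorm(3); fib <- fib / sqrt(sum(fib^2))
  mesh <- slab_mesh(dims = c(12, 9, 6), edge_length = 3, fibre = fib)
  n <- nrow(mesh$nodes)
  m <- sample(8:25, 1)
  pts <- cbind(stats::runif(m, 0, 12), stats::runif(m, 0, 9),
               stats::runif(m, 7, 15))
  parent <- c(NA, vapply(2:m, function(i) sample(i - 1, 1), integer(1)))
  edges <- data.frame(a = parent[-1], b = 2:m,
                      branch = "PERIPHERAL", fascicle = "PERIPHERAL",
                      blocked = FALSE)
  leaves <- setdiff(2:m, parent[-1])
  k <- min(length(leaves), sample(2:6, 1))
  pmj_leaves <- sample(leaves, k)
  pmjs <- data.frame(tree_node = pmj_leaves,
                     mesh_node = sample(n, k),
                     delay_antero = NA_real_, delay_retro = NA_real_,
                     fascicle = "PERIPHERAL")
  tree <- purkinje_tree(pts, edges, root = 1L, pmjs = pmjs,
                        cv_tree = stats::runif(1, 2, 4))
  # block a few random tree edges (never all)
  nb <- sample(0:2, 1)
  if (nb > 0) tree$edges$blocked[sample(nrow(tree$edges), nb)] <- TRUE
  noncond <- integer(0)
  if (stats::runif(1) < 0.5)
    noncond <- sample(nrow(mesh$tets), ceiling(nrow(mesh$tets) * 0.05))
  config <- conduction_config(
    cv_fibre = stats::runif(1, 0.4, 0.8),
    cv_transverse = stats::runif(1, 0.15, 0.3),
    cv_tree = tree$cv_tree,
    pmj_delay_antero = stats::runif(1, 0, 12),
    pmj_delay_retro = stats::runif(1, 0, 6),
    nonconducting = noncond)
  # stimulate a random tree node plus (sometimes) a conducting mesh node
  stim <- data.frame(kind = "tree", node = sample(m, 1),
                     onset = stats::runif(1, 0, 5))
  cond <- setdiff(seq_len(nrow(mesh$tets)), noncond)
  cond_nodes <- unique(as.vector(mesh$tets[cond, , drop = FALSE]))
  if (stats::runif(1) < 0.6)
    stim <- rbind(stim, data.frame(kind = "mesh",
                                   node = sample(cond_nodes, 1),
                                   onset = stats::runif(1, 0, 5)))
  list(mesh = mesh, tree = tree, config = config, stim = stim)
}

# fake metric regions from explicit node sets
fake_regions <- function(lv_epi, rv_epi, lv_all = lv_epi,
                         biv = sort(unique(c(lv_epi, rv_epi, lv_all)))) {
  structure(list(lv_epi = lv_epi, rv_epi = rv_epi, lv_all = lv_all,
                 biv = biv, excluded = integer(0)),
            class = "metric_regions")
}

act_of <- function(times) activation_map(times)
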