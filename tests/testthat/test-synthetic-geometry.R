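test_that("heart generation is bit-identical for the same (seed, index)", {
  spec <- cohort_spec(n_hearts = 2, seed = 1, target_edge_length = 4)
  h1 <- generate_heart(spec, 1)
  h2 <- generate_heart(spec, 1)
  expect_identical(h1$mesh$nodes, h2$mesh$nodes)
  expect_identical(h1$mesh$tets, h2$mesh$tets)
  expect_identical(h1$mesh$fibre, h2$mesh$fibre)
  expect_identical(h1$uvc, h2$uvc)
  # byte equality of serialized output
  f1 <- tempfile(); f2 <- tempfile()
  write_mesh(h1$mesh, f1, "carp")
  write_mesh(h2$mesh, f2, "carp")
  expect_identical(readLines(paste0(f1, ".pts")),
                   readLines(paste0(f2, ".pts")))
  expect_identical(readLines(paste0(f1, ".elem")),
                   readLines(paste0(f2, ".elem")))
})

test_that("generated meshes satisfy the geometric invariants", {
  h <- coarse_heart()
  expect_true(validate_mesh(h$mesh))
  v <- tet_volumes(h$mesh$nodes, h$mesh$tets)
  expect_true(all(v > 0))
  expect_true(all(abs(sqrt(rowSums(h$mesh$fibre^2)) - 1) < 1e-9))
  expect_setequal(unique(h$mesh$chamber), c("LV", "RV"))
  expect_true(all(h$mesh$region %in%
                    c("LV_MYO", "RV_MYO", "SEPTUM", "EXCLUDED_VALVE",
                      "EXCLUDED_OUTFLOW")))
  expect_gt(sum(h$mesh$region == "SEPTUM"), 0)
})

test_that("median edge length tracks the target resolution", {
  h <- fine_heart()  # target 2 mm
  ed <- mesh_edges(h$mesh)$edges
  med <- stats::median(ed$len)
  expect_gt(med, 1.5)
  expect_lt(med, 2.5)
})

test_that("universal ventricular coordinates are consistent", {
  h <- coarse_heart()
  u <- h$uvc; mesh <- h$mesh
  expect_true(all(u$rho >= 0 & u$rho <= 1))
  expect_true(all(u$tau >= 0 & u$tau <= 1))
  expect_true(all(u$phi > -pi & u$phi <= pi))
  expect_true(all(u$ventricle %in% c("LV", "RV")))
  # rho is monotone in the apicobasal direction
  o <- order(mesh$nodes[, 3])
  expect_true(all(diff(u$rho[o]) >= -1e-12))
  # tau is 0 on the endocardium and 1 on the epicardium, per compartment
  s <- mesh$surface
  nodes_of <- function(tg) unique(as.vector(s$faces[s$tag == tg, ]))
  lv_endo <- nodes_of("LV_ENDO")
  expect_true(all(u$tau[lv_endo] == 0))
  lv_epi <- setdiff(nodes_of("LV_EPI"), lv_endo)
  expect_true(all(u$tau[lv_epi] == 1))
  expect_true(all(u$tau[nodes_of("RV_ENDO_SEPTAL")] == 1))
  rv_endo <- nodes_of("RV_ENDO_FREEWALL")
  rv_epi <- nodes_of("RV_EPI")
  pure_endo <- setdiff(rv_endo, rv_epi)
  pure_endo <- pure_endo[u$ventricle[pure_endo] == "RV"]
  expect_true(all(u$tau[pure_endo] == 0))
  pure_epi <- setdiff(rv_epi, rv_endo)
  pure_epi <- pure_epi[u$ventricle[pure_epi] == "RV"]
  expect_true(all(u$tau[pure_epi] == 1))
})

test_that("cohort shape variability matches the configured distributions", {
  spec <- cohort_spec(n_hearts = 200, seed = 3)
  p <- sample_cohort_params(spec)
  # coefficient of variation of the long-axis length is positive
  long_axis <- p$lv_cavity_long * (1 + p$base_frac) + p$lv_wall
  expect_gt(stats::sd(long_axis) / mean(long_axis), 0)
  # directly sampled parameters follow their configured normals
  ks <- stats::ks.test(p$lv_cavity_long, "pnorm",
                       mean = spec$shape$lv_cavity_long[1],
                       sd = spec$shape$lv_cavity_long[2])
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(p$septal_wall, "pnorm",
                        mean = spec$shape$septal_wall[1],
                        sd = spec$shape$septal_wall[2])
  expect_gt(ks2$p.value, 0.01)
})

test_that("degenerate shape samples are rejected with a useful message", {
  spec <- cohort_spec(n_hearts = 1, seed = 1,
                      shape = list(lv_wall = c(30, 1e-6)))
  expect_error(generate_heart(spec, 1), "wall thickness")
  expect_error(generate_heart(cohort_spec(n_hearts = 2), 3), "n_hearts")
})

test_that("fibre field follows the transmural helix rule", {
  h <- coarse_heart()
  mesh <- h$mesh; u <- h$uvc
  fr <- element_frames(mesh)
  tau_e <- (u$tau[mesh$tets[, 1]] + u$tau[mesh$tets[, 2]] +
            u$tau[mesh$tets[, 3]] + u$tau[mesh$tets[, 4]]) / 4
  ang <- atan2(rowSums(mesh$fibre * fr$lon),
               rowSums(mesh$fibre * fr$circ)) * 180 / pi
  # subendocardial elements approach +60 deg, midwall 0, subepicardial -60
  sel <- mesh$chamber == "LV" & mesh$region == "LV_MYO"
  expect_lt(max(abs(ang[sel & tau_e < 0.05] - 60 * (1 - 2 * tau_e[sel & tau_e < 0.05]))), 5)
  mid <- sel & abs(tau_e - 0.5) < 0.02
  expect_lt(max(abs(ang[mid])), 5)
  expect_error(assign_fibres(mesh, NULL), "coordinates")
})
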