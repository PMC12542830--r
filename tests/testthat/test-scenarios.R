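test_that("mesh pacing sites resolve to the nearest UVC target on the septum", {
  h <- coarse_heart()
  s <- resolve_site(h$mesh, h$uvc, h$tree, protocol_site("AS"))
  expect_equal(s$kind, "mesh")
  expect_lt(abs(h$uvc$rho[s$node] - 0.15), 0.05)
  rvs <- unique(as.vector(
    h$mesh$surface$faces[h$mesh$surface$tag == "RV_ENDO_SEPTAL", ]))
  expect_true(s$node %in% rvs)
  sm <- resolve_site(h$mesh, h$uvc, h$tree, protocol_site("MS"))
  expect_lt(abs(h$uvc$rho[sm$node] - 0.50), 0.05)
  sr <- resolve_site(h$mesh, h$uvc, h$tree, protocol_site("RVOT_S"))
  expect_gt(h$uvc$rho[sr$node], 0.8)
})

test_that("a site resolving into the scar core is rejected", {
  h <- coarse_heart()
  # a scar reaching the RV septal endocardium makes mid-septal pacing
  # infeasible
  scar <- map_scar(h$mesh, h$uvc, scar_spec(tau = c(0, 1)))
  expect_error(resolve_site(h$mesh, h$uvc, h$tree, protocol_site("MS"),
                            scar = scar), "scar core")
  # the default scar spares the RV subendocardial rim
  scar2 <- map_scar(h$mesh, h$uvc, scar_spec())
  expect_silent(resolve_site(h$mesh, h$uvc, h$tree, protocol_site("MS"),
                             scar = scar2))
})

test_that("the scenario matrix is the advertised cross product", {
  expect_equal(nrow(build_scenario_matrix()), 18)
  expect_equal(nrow(build_scenario_matrix(substrates = "INTACT")), 6)
  expect_error(build_scenario_matrix(protocols = "HIS_PACING"),
               "unknown protocol")
  m <- build_scenario_matrix()
  expect_true(all(m$av_block))
})

test_that("scar mapping follows its UVC predicate deterministically", {
  h <- coarse_heart()
  sp <- scar_spec(rho = c(0.2, 0.8), phi = c(-1.35, 1.35), tau = c(0, 1))
  scar <- map_scar(h$mesh, h$uvc, sp)
  mesh <- h$mesh; u <- h$uvc
  cen <- element_centroids(mesh)
  rho_e <- (u$rho[mesh$tets[, 1]] + u$rho[mesh$tets[, 2]] +
            u$rho[mesh$tets[, 3]] + u$rho[mesh$tets[, 4]]) / 4
  phi_e <- atan2(cen[, 2], cen[, 1])
  pred <- which(mesh$chamber == "LV" & rho_e >= 0.2 & rho_e <= 0.8 &
                phi_e >= -1.35 & phi_e <= 1.35)
  expect_setequal(scar$core, pred)
  expect_identical(map_scar(h$mesh, h$uvc, sp)$core, scar$core)
  expect_warning(map_scar(h$mesh, h$uvc, scar_spec(rho = c(2, 3))),
                 "no elements")
})

test_that("the same scar spec maps to comparable septal regions across hearts", {
  h1 <- coarse_heart(); h2 <- coarse_heart2()
  sp <- scar_spec()
  s1 <- map_scar(h1$mesh, h1$uvc, sp)
  s2 <- map_scar(h2$mesh, h2$uvc, sp)
  rng <- function(h, s) {
    rho_e <- (h$uvc$rho[h$mesh$tets[, 1]] + h$uvc$rho[h$mesh$tets[, 2]] +
              h$uvc$rho[h$mesh$tets[, 3]] + h$uvc$rho[h$mesh$tets[, 4]]) / 4
    range(rho_e[s$core])
  }
  r1 <- rng(h1, s1); r2 <- rng(h2, s2)
  expect_lt(max(abs(r1 - r2)), 0.05)
  phi_ok <- function(h, s) {
    cen <- element_centroids(h$mesh)[s$core, , drop = FALSE]
    all(abs(atan2(cen[, 2], cen[, 1])) <= 1.35)
  }
  expect_true(phi_ok(h1, s1))
  expect_true(phi_ok(h2, s2))
})

test_that("an empty scar leaves the simulation identical to intact", {
  h <- coarse_heart()
  cfg <- conduction_config()
  empty <- suppressWarnings(map_scar(h$mesh, h$uvc, scar_spec(rho = c(2, 3))))
  a0 <- run_scenario(h, h$tree, "INTACT", "BASELINE_JUNCTIONAL", cfg)
  a1 <- run_scenario(h, h$tree, "SEPTAL_SCAR", "BASELINE_JUNCTIONAL", cfg,
                     scar = empty)
  expect_equal(a0$act$node_time, a1$act$node_time, tolerance = 1e-12)
})

test_that("junctional baseline shows sinus-like activation ordering", {
  h <- coarse_heart()
  act <- solve_coupled(h$mesh, h$tree, conduction_config(),
                       data.frame(kind = "tree", node = h$tree$root,
                                  onset = 0))
  u <- h$uvc
  biv <- h$regions$biv
  lv <- biv[u$ventricle[biv] == "LV"]
  # endocardium before epicardium
  expect_lt(mean(act$node_time[lv[u$tau[lv] < 0.15]]),
            mean(act$node_time[lv[u$tau[lv] > 0.85]]))
  # apex before base on the free walls (excluded ring already removed)
  fw <- lv[abs(u$phi[lv]) > 1.6]
  expect_lt(mean(act$node_time[fw[u$rho[fw] < 0.4]]),
            mean(act$node_time[fw[u$rho[fw] > 0.6]]))
})

test_that("LBBB baseline delays the LV and prolongs total activation", {
  h <- coarse_heart()
  cfg <- conduction_config()
  base <- run_scenario(h, h$tree, "INTACT", "BASELINE_JUNCTIONAL", cfg)
  lbbb <- run_scenario(h, h$tree, "LBBB", "BASELINE_JUNCTIONAL", cfg)
  m0 <- compute_metrics(base$act, h$regions)
  m1 <- compute_metrics(lbbb$act, h$regions)
  expect_gt(m1$veu, 0)
  expect_gt(m1$veu, m0$veu)
  expect_gt(m1$bivat90, m0$bivat90)
})

test_that("intact proximal LBBP uncouples less than mid-septal pacing", {
  h <- coarse_heart()
  cfg <- conduction_config()
  p <- run_scenario(h, h$tree, "INTACT", "PLBBP", cfg)
  m <- run_scenario(h, h$tree, "INTACT", "MS", cfg)
  expect_lt(abs(compute_metrics(p$act, h$regions)$veu),
            abs(compute_metrics(m$act, h$regions)$veu))
})
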