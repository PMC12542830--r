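test_that("VEU is the difference of mean epicardial times with the stated sign", {
  reg <- fake_regions(lv_epi = 1:3, rv_epi = 4:6, lv_all = 1:3, biv = 1:6)
  act <- act_of(c(50, 60, 70, 20, 30, 40))
  expect_equal(veu(act, reg), 30)
  expect_equal(abs_veu(act, reg), 30)
  # identical distributions give zero
  act2 <- act_of(c(20, 30, 40, 20, 30, 40))
  expect_equal(veu(act2, reg), 0)
  # sign flips with the roles
  act3 <- act_of(c(20, 30, 40, 50, 60, 70))
  expect_equal(veu(act3, reg), -30)
  expect_equal(abs_veu(act3, reg), 30)
  # empty or unreached regions refuse
  expect_error(veu(act, fake_regions(integer(0), 4:6)), "empty")
  expect_error(veu(act_of(c(Inf, 60, 70, 20, 30, 40)), reg), "unreached")
})

test_that("LVDI is the population SD of LV times, sample SD on request", {
  reg <- fake_regions(lv_epi = 1:2, rv_epi = 3:4, lv_all = 1:4, biv = 1:4)
  expect_equal(lvdi(act_of(rep(7, 4)), reg), 0)
  expect_equal(lvdi(act_of(c(0, 10, 0, 10)), reg), 5)
  x <- c(3, 9, 14, 30)
  expect_equal(lvdi(act_of(x), reg), sqrt(mean((x - mean(x))^2)))
  expect_equal(lvdi(act_of(x), reg, type = "sample"), sd(x))
})

test_that("BIVAT-90 matches exhaustive window search and handles outliers", {
  reg <- function(n) fake_regions(1:2, 1:2, 1:2, biv = seq_len(n))
  t100 <- 0:99
  expect_equal(bivat90(act_of(t100), reg(100)), 89)
  expect_equal(bivat90(act_of(t100), reg(100)), brute_bivat(t100))
  expect_equal(bivat90(act_of(rep(5, 40)), reg(40)), 0)
  # one straggler is excluded by the window
  tt <- c(seq(0, 10, length.out = 99), 100)
  expect_lte(bivat90(act_of(tt), reg(100)), 10)
  set.seed(31)
  for (rep in 1:20) {
    x <- round(stats::rexp(sample(20:200, 1), 0.05), 2)
    expect_equal(bivat90(act_of(x), reg(length(x))), brute_bivat(x))
  }
  # the quantile variant can only be at least as wide
  x <- stats::rnorm(500, 50, 10)
  expect_gte(bivat90(act_of(x), reg(500), method = "quantile"),
             bivat90(act_of(x), reg(500)))
})

test_that("metrics are translation invariant and scale equivariant", {
  set.seed(8)
  n <- 60
  reg <- fake_regions(lv_epi = 1:15, rv_epi = 16:30, lv_all = 1:30,
                      biv = 1:n)
  x <- stats::runif(n, 0, 80)
  base <- compute_metrics(act_of(x), reg)
  shift <- compute_metrics(act_of(x + 17.3), reg)
  for (f in c("veu", "abs_veu", "lvdi", "bivat90"))
    expect_equal(shift[[f]], base[[f]], tolerance = 1e-12)
  sc <- compute_metrics(act_of(2.5 * x), reg)
  for (f in c("veu", "abs_veu", "lvdi", "bivat90"))
    expect_equal(sc[[f]], 2.5 * base[[f]], tolerance = 1e-12)
})

test_that("per-heart absolute VEU is taken before cohort averaging", {
  reg <- fake_regions(lv_epi = 1:2, rv_epi = 3:4, lv_all = 1:2, biv = 1:4)
  m1 <- compute_metrics(act_of(c(10, 10, 15, 15)), reg)  # veu -5
  m2 <- compute_metrics(act_of(c(15, 15, 10, 10)), reg)  # veu +5
  expect_equal(mean(c(m1$veu, m2$veu)), 0)
  expect_equal(mean(c(m1$abs_veu, m2$abs_veu)), 5)
  expect_equal(compute_metrics(act_of(c(1, 1, 1, 1)), reg)$abs_veu, 0)
})

test_that("metrics ignore perturbations confined to excluded nodes", {
  h <- coarse_heart()
  act <- solve_coupled(h$mesh, h$tree, conduction_config(),
                       data.frame(kind = "tree", node = h$tree$root,
                                  onset = 0))
  reg <- h$regions
  base <- compute_metrics(act, reg)
  act2 <- act
  act2$node_time[reg$excluded] <- act2$node_time[reg$excluded] + 500
  pert <- compute_metrics(act2, reg)
  for (f in c("veu", "abs_veu", "lvdi", "bivat90"))
    expect_equal(pert[[f]], base[[f]], tolerance = 1e-12)
  expect_gt(length(reg$excluded), 0)
})

test_that("metric regions round-trip through their CSV form", {
  h <- coarse_heart()
  f <- tempfile(fileext = ".csv")
  write_metric_regions(h$regions, f, n_nodes = nrow(h$mesh$nodes))
  rt <- read_metric_regions(f)
  for (set in c("lv_epi", "rv_epi", "lv_all", "biv"))
    expect_setequal(rt[[set]], h$regions[[set]])
  act <- act_of(seq_len(nrow(h$mesh$nodes)) / 100)
  expect_equal(compute_metrics(act, rt)$veu,
               compute_metrics(act, h$regions)$veu, tolerance = 1e-12)
})

test_that("volume weighting preserves the invariance properties", {
  h <- coarse_heart()
  act <- solve_coupled(h$mesh, h$tree, conduction_config(),
                       data.frame(kind = "tree", node = h$tree$root,
                                  onset = 0))
  reg <- h$regions
  bw <- bivat90(act, reg, weights = "volume", mesh = h$mesh)
  expect_gt(bw, 0)
  act2 <- act
  act2$node_time <- act2$node_time + 11
  expect_equal(bivat90(act2, reg, weights = "volume", mesh = h$mesh), bw,
               tolerance = 1e-9)
  act3 <- act
  act3$node_time <- act3$node_time * 3
  expect_equal(bivat90(act3, reg, weights = "volume", mesh = h$mesh),
               3 * bw, tolerance = 1e-9)
  # near the unweighted value on a quasi-uniform lattice
  expect_lt(abs(bw - bivat90(act, reg)) / bivat90(act, reg), 0.1)
})
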