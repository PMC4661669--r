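scenario_fixture <- list(BW = 60, EF = 350, ED = 30, IngR = 100, SA = 5000,
                         AF = 0.07, ABS = 0.03, InhR = 15, PEF = 1.36e9,
                         AT_ca = 365 * 70, AT_nc = 365 * 30, CF = 1e-6)

test_that("chronic daily intake matches the hand-evaluated ingestion formula", {
  # 100 * 100 * 350 * 30 * 1e-6 / (60 * 25550) = 105 / 1533000
  expect_equal(chronic_daily_intake(100, "ingestion", scenario_fixture, TRUE),
               105 / 1533000, tolerance = 1e-15)
  # dermal and inhalation, same literal arithmetic
  expect_equal(chronic_daily_intake(100, "dermal", scenario_fixture, TRUE),
               100 * 5000 * 0.07 * 0.03 * 350 * 30 * 1e-6 / (60 * 25550),
               tolerance = 1e-15)
  expect_equal(chronic_daily_intake(100, "inhalation", scenario_fixture, TRUE),
               100 * 15 * 350 * 30 / (1.36e9 * 60 * 25550), tolerance = 1e-15)
})

test_that("dose is linear in concentration and zero at zero", {
  for (pw in c("ingestion", "dermal", "inhalation")) {
    for (ca in c(TRUE, FALSE)) {
      expect_identical(chronic_daily_intake(0, pw, scenario_fixture, ca), 0)
      d1 <- chronic_daily_intake(13.7, pw, scenario_fixture, ca)
      d2 <- chronic_daily_intake(27.4, pw, scenario_fixture, ca)
      expect_equal(d2, 2 * d1, tolerance = 1e-12)
      expect_gt(d1, 0)
    }
  }
  expect_error(chronic_daily_intake(1, "groundwater", scenario_fixture),
               "unknown pathway")
  expect_error(chronic_daily_intake(-1, "ingestion", scenario_fixture),
               ">= 0")
})

test_that("carcinogenic risk and hazard quotient follow their definitions", {
  expect_identical(carcinogenic_risk(0, 1.5), 0)
  expect_equal(carcinogenic_risk(1e-4, 1.5), 1.5e-4)
  expect_identical(hazard_quotient(0, 0.3), 0)
  expect_equal(hazard_quotient(2e-3, 2e-3), 1)
  # CR additive over pathways when the slope factor is shared
  set.seed(41)
  for (i in 1:20) {
    doses <- runif(3, 0, 1e-3)
    sf <- runif(1, 0.01, 50)
    expect_equal(sum(carcinogenic_risk(doses, sf)),
                 carcinogenic_risk(sum(doses), sf), tolerance = 1e-12)
  }
  # HQ strictly increasing in dose at fixed rfd
  d <- sort(runif(10, 0, 1))
  expect_true(all(diff(hazard_quotient(d, 0.05)) > 0))
})

test_that("TCR classification respects the configured breaks and is monotone", {
  thr <- list(tcr_breaks = c(1e-6, 1e-5, 1e-4))
  expect_equal(as.character(classify_health_risk(5e-7, thr)), "low")
  expect_equal(as.character(classify_health_risk(5e-6, thr)), "moderate")
  expect_equal(as.character(classify_health_risk(2e-4, thr)), "extreme")
  # boundary straddles around each break, at machine-epsilon perturbations
  for (b in thr$tcr_breaks) {
    lo <- classify_health_risk(b, thr)
    hi <- classify_health_risk(b * (1 + 1e-12), thr)
    expect_equal(risk_rank(hi), risk_rank(lo) + 1)
  }
  x <- sort(c(10^runif(50, -8, -3), thr$tcr_breaks))
  expect_true(!is.unsorted(risk_rank(classify_health_risk(x, thr))))
  expect_error(classify_health_risk(-1e-7, thr), "negative TCR")
})

test_that("assess_sample agrees with an independent nested-loop oracle", {
  thr <- list(tcr_breaks = c(1e-6, 1e-5, 1e-4))
  set.seed(101)
  for (i in 1:25) {
    reg <- random_registry(3)
    s <- random_scenario()
    conc <- as.list(setNames(runif(3, 0, 500), names(reg)))
    got <- assess_sample(list(id = "t", conc = conc), reg, s, thr)
    want <- health_oracle(conc, reg, s)
    expect_equal(got$tcr, want$tcr, tolerance = 1e-12)
    expect_equal(got$thi, want$thi, tolerance = 1e-12)
    # internal consistency: TCR/THI are the sums of their components
    expect_equal(got$tcr, sum(got$cr), tolerance = 1e-12)
    expect_equal(got$thi, sum(got$hq), tolerance = 1e-12)
  }
})

test_that("assess_sample degenerate cases: zero field and single pathway", {
  thr <- list(tcr_breaks = c(1e-6, 1e-5, 1e-4))
  reg <- list(As = list(group = "heavy_metal",
                        sf = list(ingestion = 1.5),
                        rfd = list(ingestion = 3e-4), abs = 0.03))
  zero <- assess_sample(list(id = "z", conc = list(As = 0)), reg,
                        scenario_fixture, thr)
  expect_identical(zero$tcr, 0)
  expect_identical(zero$thi, 0)
  expect_equal(as.character(zero$level), "low")

  one <- assess_sample(list(id = "o", conc = list(As = 100)), reg,
                       scenario_fixture, thr)
  expect_equal(one$tcr,
               carcinogenic_risk(
                 chronic_daily_intake(100, "ingestion", scenario_fixture, TRUE),
                 1.5),
               tolerance = 1e-15)
  expect_error(
    assess_sample(list(id = "m", conc = list(Xx = 1)), reg, scenario_fixture, thr),
    "missing from registry")
})

test_that("TCR is homogeneous in concentration and additive over registry partitions", {
  thr <- list(tcr_breaks = c(1e-6, 1e-5, 1e-4))
  set.seed(202)
  for (i in 1:10) {
    reg <- random_registry(4)
    s <- random_scenario()
    conc <- as.list(setNames(runif(4, 0, 100), names(reg)))
    base <- assess_sample(list(id = "a", conc = conc), reg, s, thr)$tcr
    alpha <- runif(1, 0, 5)
    scaled <- assess_sample(list(id = "a", conc = lapply(conc, `*`, alpha)),
                            reg, s, thr)$tcr
    expect_equal(scaled, alpha * base, tolerance = 1e-12)
    # partition the registry into two disjoint halves
    ids <- names(reg)
    t1 <- assess_sample(list(id = "a", conc = conc[ids[1:2]]), reg[ids[1:2]],
                        s, thr)$tcr
    t2 <- assess_sample(list(id = "a", conc = conc[ids[3:4]]), reg[ids[3:4]],
                        s, thr)$tcr
    expect_equal(t1 + t2, base, tolerance = 1e-12)
  }
})

test_that("nondetects contribute zero by default and LOD/2 under lod2", {
  cfg <- default_cfg()
  samples <- data.frame(id = "s1", x = 100, y = 100, point_type = "census",
                        pH = 8, As = 50, Hg = NA_real_)
  h0 <- assess_samples(samples, cfg)
  cfg2 <- cfg
  cfg2$nondetect_policy <- "lod2"
  h2 <- assess_samples(samples, cfg2)
  # Hg carries only RfDs, so the policies differ in THI but not TCR
  expect_equal(h2$tcr, h0$tcr, tolerance = 1e-12)
  expect_gt(h2$thi, h0$thi)
  ref <- health_oracle(list(As = 50, Hg = cfg$lod$Hg / 2), cfg$pollutants,
                       cfg$scenarios$residential)
  expect_equal(h2$thi, ref$thi, tolerance = 1e-12)
})

test_that("vectorized table assessment matches the per-sample path and picks scenarios by land use", {
  cfg <- default_cfg()
  set.seed(7)
  ids <- names(cfg$pollutants)[1:5]
  samples <- data.frame(id = paste0("s", 1:6),
                        x = runif(6, 0, 40000), y = runif(6, 0, 30000),
                        point_type = "census", pH = 8)
  for (id in ids) samples[[id]] <- runif(6, 0, 50)
  lu <- generate_landuse(cfg)
  got <- assess_samples(samples, cfg, lu)
  for (i in 1:6) {
    conc <- as.list(setNames(as.numeric(samples[i, ids]), ids))
    ref <- assess_sample(list(id = samples$id[i], conc = conc),
                         cfg$pollutants, cfg$scenarios[[got$scenario[i]]],
                         cfg$thresholds)
    expect_equal(got$tcr[i], ref$tcr, tolerance = 1e-12)
    expect_equal(got$thi[i], ref$thi, tolerance = 1e-12)
  }
  # scenario column matches the land-use cell each point falls in
  codes <- extract_cells(lu, samples$x, samples$y)
  expect_identical(got$scenario[!is.na(codes)],
                   land_use_classes()[codes[!is.na(codes)]])
})
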