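test_that("indicator scoring covers all three rule kinds", {
  expect_equal(score_indicator(TRUE, list(kind = "boolean", score_true = 0,
                                          score_false = 3)), 0)
  expect_equal(score_indicator(FALSE, list(kind = "boolean", score_true = 0,
                                           score_false = 3)), 3)
  bins <- list(kind = "bins", breaks = c(10, 100), scores = c(0, 1.5, 3))
  expect_equal(score_indicator(50, bins), 1.5)
  expect_equal(score_indicator(10, bins), 0)    # at a break: lower interval
  expect_equal(score_indicator(100.001, bins), 3)
  cat_rule <- list(kind = "categorical", mapping = list(filed = 0, none = 3))
  expect_equal(score_indicator("none", cat_rule), 3)
  expect_error(score_indicator("unheard_of", cat_rule), "absent")
  expect_error(score_indicator("abc", bins), "non-numeric")
})

test_that("every default rule maps its domain onto [0, 3]", {
  cfg <- default_cfg()
  for (id in names(cfg$factory$indicators)) {
    rule <- cfg$factory$indicators[[id]]$rule
    raws <- switch(rule$kind,
      bins = {
        b <- rule$breaks
        c(b[1] - 1, b, b + 1e-9, b[length(b)] + 1)
      },
      categorical = names(rule$mapping),
      boolean = c(TRUE, FALSE))
    for (raw in raws) {
      s <- score_indicator(raw, rule)
      expect_gte(s, 0)
      expect_lte(s, 3)
    }
  }
})

test_that("criterion subscores are weight-normalized means", {
  cfg <- default_cfg()
  inds <- cfg$factory$indicators
  ids <- names(inds)
  all0 <- setNames(rep(0, length(ids)), ids)
  all3 <- setNames(rep(3, length(ids)), ids)
  all1 <- setNames(rep(1, length(ids)), ids)
  for (cr in c("sudden", "cumulative", "supervision")) {
    expect_equal(criterion_score(all0, inds, cr), 0)
    expect_equal(criterion_score(all3, inds, cr), 3)
  }
  # the cumulative criterion's printed weights sum to 0.65, yet a constant
  # field is a fixed point under normalization
  w_cum <- sum(vapply(inds, function(i)
    if (i$criterion == "cumulative") i$weight else 0, 0))
  expect_equal(w_cum, 0.65)
  expect_equal(criterion_score(all1, inds, "cumulative"), 1)

  two <- list(
    a = list(criterion = "sudden", weight = 0.35,
             rule = list(kind = "boolean", score_true = 0, score_false = 3)),
    b = list(criterion = "sudden", weight = 0.15,
             rule = list(kind = "boolean", score_true = 0, score_false = 3)))
  expect_equal(criterion_score(c(a = 3, b = 1), two, "sudden"),
               (0.35 * 3 + 0.15 * 1) / 0.5)  # = 2.4
  expect_error(criterion_score(c(a = 3), two, "sudden"), "missing indicator")
})

test_that("CRI combines subscores with the 0.30/0.30/0.40 criterion weights", {
  cfg <- default_cfg()
  fspec <- cfg$factory
  ids <- names(fspec$indicators)
  raw_for_score <- function(target) {
    sapply(ids, function(id) {
      rule <- fspec$indicators[[id]]$rule
      soilrisk:::invert_rule(rule, target)
    }, simplify = FALSE)
  }
  r0 <- comprehensive_risk_index(list(id = "f0", raw = raw_for_score(0)), fspec)
  expect_equal(r0$cri, 0)
  expect_equal(as.character(r0$level), "low")
  r3 <- comprehensive_risk_index(list(id = "f3", raw = raw_for_score(3)), fspec)
  expect_equal(r3$cri, 3)
  expect_equal(as.character(r3$level), "extreme")
  # subscores (1, 2, 3) -> 0.30*1 + 0.30*2 + 0.40*3 = 2.1, a high-risk CRI
  expect_equal(0.30 * 1 + 0.30 * 2 + 0.40 * 3, 2.1)
  expect_equal(as.character(classify_cri(2.1)), "high")
})

test_that("CRI classification reproduces the printed class boundaries", {
  expect_equal(as.character(classify_cri(1.0)), "low")
  expect_equal(as.character(classify_cri(1.000001)), "moderate")
  expect_equal(as.character(classify_cri(2.5)), "high")
  expect_equal(as.character(classify_cri(2.6)), "extreme")
  for (b in c(1, 2, 2.5)) {
    expect_equal(risk_rank(classify_cri(b + 1e-9)),
                 risk_rank(classify_cri(b)) + 1)
  }
  expect_error(classify_cri(3.2), "outside")
  expect_error(classify_cri(-0.1), "outside")
})

test_that("CRI is bounded, monotone per indicator, and weight-scale invariant", {
  set.seed(303)
  for (rep in 1:15) {
    fspec <- random_ruleset()
    ids <- names(fspec$indicators)
    scores <- setNames(runif(length(ids), 0, 3), ids)
    crits <- c("sudden", "cumulative", "supervision")
    sub <- vapply(crits, function(cr)
      criterion_score(scores, fspec$indicators, cr, fspec$weight_mode), 0)
    cri <- sum(unlist(fspec$criterion_weights[crits]) * sub)
    expect_gte(cri, 0)
    expect_lte(cri + 1e-12, 3)
    # raising one indicator's score never lowers its criterion subscore
    pick <- sample(ids, 1)
    bumped <- scores
    bumped[pick] <- min(3, bumped[pick] + runif(1, 0, 3 - bumped[pick]))
    cr_of <- fspec$indicators[[pick]]$criterion
    expect_gte(criterion_score(bumped, fspec$indicators, cr_of, fspec$weight_mode),
               criterion_score(scores, fspec$indicators, cr_of, fspec$weight_mode) - 1e-12)
    # scaling all of one criterion's weights leaves the normalized subscore unchanged
    scaled <- fspec$indicators
    lambda <- runif(1, 0.1, 10)
    for (id in ids) {
      if (scaled[[id]]$criterion == cr_of) {
        scaled[[id]]$weight <- scaled[[id]]$weight * lambda
      }
    }
    expect_equal(criterion_score(scores, scaled, cr_of, "normalized"),
                 criterion_score(scores, fspec$indicators, cr_of, "normalized"),
                 tolerance = 1e-12)
  }
})

test_that("missing-indicator policies behave as configured", {
  cfg <- default_cfg()
  fspec <- cfg$factory
  ids <- names(fspec$indicators)
  raw <- sapply(ids, function(id)
    soilrisk:::invert_rule(fspec$indicators[[id]]$rule, 1.5), simplify = FALSE)
  raw$hazardous_inventory <- NULL
  expect_error(comprehensive_risk_index(list(id = "fx", raw = raw), fspec),
               "missing indicator 'hazardous_inventory'")
  fspec$missing_policy <- "worst"
  worst <- comprehensive_risk_index(list(id = "fx", raw = raw), fspec)
  fspec$missing_policy <- "renormalize"
  renorm <- comprehensive_risk_index(list(id = "fx", raw = raw), fspec)
  expect_gt(worst$cri, renorm$cri)
  expect_lte(worst$cri, 3)
})

test_that("raw weight mode caps the cumulative contribution at its printed sum", {
  cfg <- default_cfg()
  fspec <- cfg$factory
  fspec$weight_mode <- "raw"
  ids <- names(fspec$indicators)
  raw <- sapply(ids, function(id)
    soilrisk:::invert_rule(fspec$indicators[[id]]$rule, 3), simplify = FALSE)
  scores <- setNames(rep(3, length(ids)), ids)
  expect_equal(criterion_score(scores, fspec$indicators, "cumulative", "raw"),
               3 * 0.65, tolerance = 1e-12)
  res <- comprehensive_risk_index(list(id = "fr", raw = raw), fspec)
  expect_equal(res$cri, 0.30 * 3 + 0.30 * 3 * 0.65 + 0.40 * 3, tolerance = 1e-9)
})
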