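# Shared fixtures and independent oracles. Oracles are deliberately written
# as literal direct computations (no calls into the package's own
# aggregation paths).

default_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- load_config()
    cfg
  }
})

# direct-summation IDW oracle: sort by distance, take k nearest (ties
# included), weight by d^-p
idw_oracle <- function(points, values, at, power = 2, k = "all",
                       snap_eps = 1e-9) {
  d <- sqrt((points[, 1] - at[1])^2 + (points[, 2] - at[2])^2)
  if (min(d) <= snap_eps) return(values[which.min(d)])
  if (!identical(k, "all") && k < length(d)) {
    dk <- sort(d)[k]
    keep <- d <= dk
    d <- d[keep]
    values <- values[keep]
  }
  num <- 0
  den <- 0
  for (i in seq_along(d)) {
    num <- num + values[i] / d[i]^power
    den <- den + 1 / d[i]^power
  }
  num / den
}

# nested-loop health-risk oracle over (pollutant, pathway): literal dose
# formulas, CR = dose * SF, HQ = dose / RfD
health_oracle <- function(conc, registry, s) {
  tcr <- 0
  thi <- 0
  for (id in names(conc)) {
    C <- conc[[id]]
    if (is.null(C) || is.na(C)) C <- 0
    p <- registry[[id]]
    abs_frac <- if (!is.null(p$abs)) p$abs else s$ABS
    doses <- function(AT) {
      c(ingestion = C * s$IngR * s$EF * s$ED * s$CF / (s$BW * AT),
        dermal = C * s$SA * s$AF * abs_frac * s$EF * s$ED * s$CF / (s$BW * AT),
        inhalation = C * s$InhR * s$EF * s$ED / (s$PEF * s$BW * AT))
    }
    d_ca <- doses(s$AT_ca)
    d_nc <- doses(s$AT_nc)
    for (pw in c("ingestion", "dermal", "inhalation")) {
      if (!is.null(p$sf[[pw]])) tcr <- tcr + d_ca[[pw]] * p$sf[[pw]]
      if (!is.null(p$rfd[[pw]])) thi <- thi + d_nc[[pw]] / p$rfd[[pw]]
    }
  }
  list(tcr = tcr, thi = thi)
}

random_scenario <- function() {
  list(BW = runif(1, 15, 80), EF = runif(1, 50, 365), ED = runif(1, 1, 70),
       IngR = runif(1, 20, 300), SA = runif(1, 1000, 6000),
       AF = runif(1, 0.01, 0.5), ABS = runif(1, 0.001, 1),
       InhR = runif(1, 5, 25), PEF = runif(1, 1e8, 2e9),
       AT_ca = 25550, AT_nc = runif(1, 365, 25550), CF = 1e-6)
}

random_registry <- function(n_pollutants = 3) {
  reg <- list()
  for (i in seq_len(n_pollutants)) {
    sf <- list()
    rfd <- list()
    for (pw in c("ingestion", "dermal", "inhalation")) {
      if (runif(1) < 0.7) sf[[pw]] <- runif(1, 0.01, 50)
      if (runif(1) < 0.7) rfd[[pw]] <- runif(1, 1e-4, 1)
    }
    if (!length(sf) && !length(rfd)) sf$ingestion <- runif(1, 0.01, 50)
    reg[[paste0("P", i)]] <- list(group = "heavy_metal", sf = sf, rfd = rfd,
                                  abs = runif(1, 0.001, 1))
  }
  reg
}

# random indicator ruleset on the [0, 3] scale for property tests
random_ruleset <- function(n_per_criterion = 3) {
  crits <- c("sudden", "cumulative", "supervision")
  inds <- list()
  for (cr in crits) {
    for (i in seq_len(n_per_criterion)) {
      kind <- sample(c("bins", "categorical", "boolean"), 1)
      rule <- switch(kind,
        bins = {
          nb <- sample(1:4, 1)
          list(kind = "bins", breaks = sort(runif(nb, 0, 100)),
               scores = sort(runif(nb + 1, 0, 3)))
        },
        categorical = {
          labs <- paste0("L", 1:3)
          list(kind = "categorical",
               mapping = as.list(setNames(runif(3, 0, 3), labs)))
        },
        boolean = list(kind = "boolean", score_true = runif(1, 0, 3),
                       score_false = runif(1, 0, 3)))
      inds[[paste0(cr, "_", i)]] <- list(criterion = cr,
                                         weight = runif(1, 0.01, 1),
                                         rule = rule)
    }
  }
  w <- runif(3)
  w <- w / sum(w)
  list(weight_mode = "normalized", missing_policy = "error",
       criterion_weights = as.list(setNames(w, crits)), indicators = inds)
}

# small scene for cheap generator tests: 12 x 9 km, same structure
small_scene_config <- function() {
  cfg <- default_cfg()
  cfg$scene$extent <- c(12000, 9000)
  cfg$scene$hotspots <- list(
    list(name = "zoneA", rect = c(7000, 5000, 10000, 8000)),
    list(name = "zoneB", rect = c(1000, 1000, 4000, 3000)))
  cfg$scene$reservoir <- c(4500, 3500, 6500, 5500)
  cfg$scene$landuse <- list(
    industrial = list(c(7000, 5000, 10000, 8000)),
    residential = list(c(8000, 1000, 11000, 4000)),
    conservation = list(c(4000, 3000, 7000, 6000)))
  cfg$scene$plumes <- list(
    list(pollutant = "As", center = c(8500, 6500), amplitude = 3,
         length_scale = 900))
  cfg$scene$factories$count <- 40
  validate_config(unclass(cfg))
}
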