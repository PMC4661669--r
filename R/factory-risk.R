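#' Score one raw indicator value
#'
#' Rules come in three kinds. `bins` maps a numeric raw value onto the score
#' of its enclosing interval, lower-open/upper-closed above the first
#' interval (a value exactly at a break takes the lower interval's score).
#' `categorical` is a total label-to-score lookup. `boolean` scores TRUE and
#' FALSE. All scores live on the shared [0, 3] severity scale.
#'
#' @param raw Raw indicator value (number, label, or flag).
#' @param rule A validated scoring rule (see config schema).
#' @return Score in [0, 3].
#' @export
score_indicator <- function(raw, rule) {
  switch(rule$kind,
    bins = {
      if (is.na(suppressWarnings(as.numeric(raw)))) {
        stop("non-numeric raw value for bins rule: '", raw, "'", call. = FALSE)
      }
      rule$scores[classify_interval(as.numeric(raw), rule$breaks) + 1L]
    },
    categorical = {
      raw <- as.character(raw)
      if (!(raw %in% names(rule$mapping))) {
        stop("label '", raw, "' absent from categorical rule mapping",
             call. = FALSE)
      }
      rule$mapping[[raw]]
    },
    boolean = {
      b <- if (is.logical(raw)) raw else as.logical(raw)
      if (is.na(b)) stop("raw value '", raw, "' is not a flag", call. = FALSE)
      if (b) rule$score_true else rule$score_false
    },
    stop("unknown rule kind: ", rule$kind, call. = FALSE)
  )
}

#' Aggregate indicator scores within one criterion
#'
#' With `weight_mode = "normalized"` (default) the subscore is the
#' weight-normalized mean `sum(w_i * s_i) / sum(w_i)` over the criterion's
#' indicators, which keeps every criterion on the same [0, 3] scale no
#' matter what the printed weights sum to. `"raw"` uses `sum(w_i * s_i)`
#' verbatim.
#'
#' @param scores Named numeric vector/list, indicator id -> score.
#' @param indicators Indicator spec table (named list with `criterion`,
#'   `weight`).
#' @param criterion One of `"sudden"`, `"cumulative"`, `"supervision"`.
#' @param weight_mode `"normalized"` or `"raw"`.
#' @return Criterion subscore (in [0, 3] under `"normalized"`).
#' @export
criterion_score <- function(scores, indicators, criterion,
                            weight_mode = "normalized") {
  ids <- names(indicators)[vapply(indicators, `[[`, "", "criterion") == criterion]
  if (!length(ids)) stop("criterion has no indicators: ", criterion, call. = FALSE)
  missing_ids <- setdiff(ids, names(scores))
  if (length(missing_ids)) {
    stop("missing indicator score: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  w <- vapply(indicators[ids], `[[`, 0, "weight")
  s <- vapply(ids, function(i) as.numeric(scores[[i]]), 0)
  if (identical(weight_mode, "raw")) {
    sum(w * s)
  } else {
    if (sum(w) <= 0) stop("criterion weights sum to zero: ", criterion,
                          call. = FALSE)
    sum(w * s) / sum(w)
  }
}

score_factory_indicators <- function(factory, fspec) {
  scores <- list()
  for (id in names(fspec$indicators)) {
    raw <- factory$raw[[id]]
    if (is.null(raw) || (length(raw) == 1L && is.na(raw))) {
      scores[[id]] <- switch(fspec$missing_policy,
        error = stop("factory '", factory$id, "': missing indicator '", id,
                     "' and missing_policy is 'error'", call. = FALSE),
        worst = 3,
        renormalize = NA_real_)
    } else {
      scores[[id]] <- tryCatch(
        score_indicator(raw, fspec$indicators[[id]]$rule),
        error = function(e) {
          stop("factory '", factory$id, "', indicator '", id, "': ",
               conditionMessage(e), call. = FALSE)
        })
    }
  }
  scores
}

#' Comprehensive risk index of one factory
#'
#' Scores each raw indicator, aggregates them into the three criterion
#' subscores (inherent sudden risk, cumulative risk, supervision level), and
#' combines those with the criterion weights (default 0.30 / 0.30 / 0.40)
#' into the comprehensive risk index CRI in [0, 3].
#'
#' @param factory A list with `id`, `x`, `y`, `industry`, and `raw` (named
#'   list indicator id -> raw value; NA/absent = missing).
#' @param fspec The factory section of a validated config (criterion
#'   weights, indicator specs, weight mode, missing policy).
#' @param cri_breaks CRI class breaks (default `c(1, 2, 2.5)`).
#' @return A list with `id`, per-criterion subscores, `cri`, and `level`.
#' @export
comprehensive_risk_index <- function(factory, fspec,
                                     cri_breaks = c(1, 2, 2.5)) {
  scores <- score_factory_indicators(factory, fspec)
  if (fspec$missing_policy == "renormalize") {
    scores <- scores[!vapply(scores, is.na, TRUE)]
    for (cr in names(fspec$criterion_weights)) {
      ids <- names(fspec$indicators)[
        vapply(fspec$indicators, `[[`, "", "criterion") == cr]
      if (!any(ids %in% names(scores))) {
        stop("factory '", factory$id, "': no scoreable indicator left in ",
             "criterion '", cr, "'", call. = FALSE)
      }
    }
    fspec$indicators <- fspec$indicators[names(fspec$indicators) %in% names(scores)]
  }
  crits <- c("sudden", "cumulative", "supervision")
  sub <- vapply(crits, function(cr) {
    criterion_score(scores, fspec$indicators, cr, fspec$weight_mode)
  }, 0)
  w <- vapply(crits, function(cr) fspec$criterion_weights[[cr]], 0)
  cri <- sum(w * sub)
  list(id = factory$id,
       sub_sudden = sub[["sudden"]],
       sub_cumulative = sub[["cumulative"]],
       sub_supervision = sub[["supervision"]],
       cri = cri,
       level = classify_cri(cri, cri_breaks))
}

#' Classify a comprehensive risk index value
#'
#' With the default breaks (1, 2, 2.5): low on [0, 1], moderate on (1, 2],
#' high on (2, 2.5], extreme on (2.5, 3].
#'
#' @param cri CRI value(s) in [0, 3].
#' @param thresholds Thresholds list holding `cri_breaks`, or a numeric
#'   break vector.
#' @return Ordered risk-level factor.
#' @export
classify_cri <- function(cri, thresholds = c(1, 2, 2.5)) {
  breaks <- if (is.list(thresholds)) thresholds$cri_breaks else thresholds
  if (any(cri < 0 | cri > 3, na.rm = TRUE)) {
    stop("CRI outside [0, 3]", call. = FALSE)
  }
  risk_level(classify_interval(cri, breaks))
}

#' Assess a table of factories
#'
#' @param factories Data frame with columns `id`, `x`, `y`, `industry`, then
#'   one raw column per indicator id.
#' @param config A `soilrisk_config`.
#' @return Data frame: `id`, `x`, `y`, `sub_sudden`, `sub_cumulative`,
#'   `sub_supervision`, `cri`, `level`.
#' @export
assess_factories <- function(factories, config) {
  ind_ids <- names(config$factory$indicators)
  out <- vector("list", nrow(factories))
  for (i in seq_len(nrow(factories))) {
    raw <- as.list(factories[i, intersect(ind_ids, names(factories)),
                             drop = FALSE])
    res <- comprehensive_risk_index(
      list(id = factories$id[i], raw = raw),
      config$factory, config$thresholds$cri_breaks)
    out[[i]] <- data.frame(
      id = factories$id[i], x = factories$x[i], y = factories$y[i],
      sub_sudden = res$sub_sudden, sub_cumulative = res$sub_cumulative,
      sub_supervision = res$sub_supervision, cri = res$cri,
      level = as.character(res$level), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
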