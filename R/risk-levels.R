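#' Ordered risk levels
#'
#' The four risk levels used throughout the pipeline, in increasing order of
#' severity. Ranks run 0 (low) to 3 (extreme) and are bijective with labels.
#'
#' @return Character vector `c("low", "moderate", "high", "extreme")`.
#' @export
risk_levels <- function() c("low", "moderate", "high", "extreme")

#' The four land-use classes
#'
#' Industrial, agriculture, residential and conservation land: the receptor
#' contexts that drive both the exposure scenario and the integrated-risk
#' matrix. The enumeration is closed; any other label is rejected at load
#' time.
#'
#' @return Character vector of the four class labels.
#' @export
land_use_classes <- function() c("industrial", "agriculture", "residential", "conservation")

#' Construct a risk level
#'
#' @param x Character vector of labels among `risk_levels()`, or integer
#'   ranks in 0..3.
#' @return An ordered factor with levels low < moderate < high < extreme.
#' @examples
#' risk_level("moderate") < risk_level("extreme")
#' @export
risk_level <- function(x) {
  lv <- risk_levels()
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 3 | x != floor(x)))) {
      stop("risk level rank must be an integer in 0..3", call. = FALSE)
    }
    x <- lv[x + 1L]
  } else {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      stop("unknown risk level label: ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Rank of a risk level
#'
#' @param x A risk level (label, rank, or ordered factor).
#' @return Integer rank(s) in 0..3.
#' @export
risk_rank <- function(x) {
  as.integer(risk_level(x)) - 1L
}

#' Compare two risk levels
#'
#' @param a,b Risk levels (labels or ordered factors).
#' @return -1 if `a < b`, 0 if equal, 1 if `a > b`.
#' @export
compare_levels <- function(a, b) {
  sign(risk_rank(a) - risk_rank(b))
}

#' Interval classification with the shared break convention
#'
#' Maps values to class ranks against an increasing break sequence. The
#' lowest class is closed on both sides (`x <= b1` gives rank 0); every
#' class above is lower-open/upper-closed (`b1 < x <= b2` gives rank 1, and
#' so on), matching the printed CRI class definitions. `NA` propagates.
#'
#' @param x Numeric vector.
#' @param breaks Strictly increasing numeric break sequence.
#' @return Integer ranks in `0..length(breaks)`.
#' @export
classify_interval <- function(x, breaks) {
  if (length(breaks) < 1L || any(!is.finite(breaks))) {
    stop("breaks must be finite and non-empty", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("non-increasing breaks", call. = FALSE)
  }
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.integer(rowSums(outer(x[ok], breaks, `>`)))
  }
  out
}
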