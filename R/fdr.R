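#' False discovery rate adjustment
#'
#' Adjusts a vector of p-values for multiple testing using either the
#' Benjamini-Hochberg (BH) step-up procedure or the Benjamini-Krieger-
#' Yekutieli (BKY) two-stage step-up procedure.
#'
#' The two-stage procedure runs at the reduced level q' = level / (1 + level).
#' Stage one is a BH pass at q' whose rejection count r1 yields the adaptive
#' null estimate m0 = m - r1; stage two is a step-up pass with thresholds
#' i * q' / m0. If stage one rejects everything, all hypotheses are rejected.
#' Adaptive q-values are the step-up-monotonised values p * m0 / i, so that
#' `rejected` is equivalent to `q <= level / (1 + level)` for the BKY method
#' and `q <= level` for BH.
#'
#' @param p Numeric vector of p-values in \[0, 1\]. NAs are not allowed.
#' @param method `"bh"` or `"two_stage_bky"`.
#' @param level Nominal FDR level (default 0.05).
#' @return A list with elements `q` (adjusted values, same order as `p`),
#'   `rejected` (logical), `method`, `level`, and for the two-stage method
#'   `m0` (estimated number of true nulls) and `stage1_rejections`.
#' @examples
#' fdr_adjust(c(0.001, 0.008, 0.039, 0.041, 0.6), method = "two_stage_bky")
#' @export
fdr_adjust <- function(p, method = c("bh", "two_stage_bky"), level = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0L) {
    return(list(q = numeric(0), rejected = logical(0), method = method,
                level = level))
  }
  if (anyNA(p) || !is.numeric(p)) {
    stop("p must be a numeric vector without missing values", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("p-values outside [0, 1]: ",
         paste(format(p[p < 0 | p > 1]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }

  m <- length(p)
  if (method == "bh") {
    q <- stepup_adjust(p, m)
    return(list(q = q, rejected = q <= level, method = method, level = level))
  }

  qprime <- level / (1 + level)
  r1 <- stepup_rejections(p, qprime, m)
  if (r1 == m) {
    return(list(q = rep(0, m), rejected = rep(TRUE, m), method = method,
                level = level, m0 = 0L, stage1_rejections = r1))
  }
  m0 <- m - r1
  q <- stepup_adjust(p, m0)
  list(q = q, rejected = q <= qprime, method = method, level = level,
       m0 = m0, stage1_rejections = r1)
}

# Step-up adjusted values with an effective hypothesis count m_eff:
# monotonised min_{j >= i} p_(j) * m_eff / j, capped at 1.
stepup_adjust <- function(p, m_eff) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m_eff / (m:1L) * p[o]))[ro]
}

# Number of step-up rejections of p at level alpha with denominator m_eff.
stepup_rejections <- function(p, alpha, m_eff) {
  ps <- sort(p)
  i <- seq_along(ps)
  ok <- which(ps <= i * alpha / m_eff)
  if (length(ok) == 0L) 0L else max(ok)
}
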