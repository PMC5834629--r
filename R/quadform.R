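## Upper-tail probability of a weighted sum of 1-df chi-squares,
## T = sum_k lambda_k * chisq_1, by Kuonen's saddlepoint approximation
## with a Satterthwaite moment-matching fallback.

.kuonen_K <- function(zeta, lam) -0.5 * sum(log1p(-2 * zeta * lam))
.kuonen_K1 <- function(zeta, lam) sum(lam / (1 - 2 * zeta * lam))
.kuonen_K2 <- function(zeta, lam) sum(2 * lam^2 / (1 - 2 * zeta * lam)^2)

.satterthwaite <- function(lam, t) {
  a <- sum(lam^2) / sum(lam)
  d <- sum(lam)^2 / sum(lam^2)
  pchisq(t / a, df = d, lower.tail = FALSE)
}

#' Tail probability of a weighted chi-square quadratic form
#'
#' Computes `P(sum_k lambda_k X_k > t)` for independent `X_k ~ chisq(1)`
#' by the Lugannani-Rice / Kuonen saddlepoint approximation. Weights
#' smaller than `1e-8 * max(weights)` are dropped. When the saddlepoint
#' equation cannot be solved (t at or extremely near the mean, or the
#' root-finder fails) the Satterthwaite scaled-chi-square approximation is
#' used instead; the approximation used is recorded in `attr(p, "method")`.
#'
#' @param weights nonnegative weights (eigenvalues), at least one positive.
#' @param t observed statistic, `t >= 0`.
#' @return p-value in (0, 1\], attribute `method` one of `"saddlepoint"`,
#'   `"satterthwaite"`, `"exact_chisq"`.
#' @export
quadform_pvalue <- function(weights, t) {
  lam <- weights[weights > 1e-8 * max(weights)]
  if (length(lam) == 0L || all(lam <= 0))
    stop("all weights are zero: degenerate quadratic form")
  if (t <= 0) {
    p <- 1
    attr(p, "method") <- "exact_chisq"
    return(p)
  }
  ## single (or equal) weights: exact chi-square
  if (diff(range(lam)) < 1e-12 * max(lam)) {
    p <- pchisq(t / lam[1], df = length(lam), lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)
    attr(p, "method") <- "exact_chisq"
    return(p)
  }

  mean_t <- sum(lam)
  if (abs(t - mean_t) < 1e-10 * mean_t) {
    p <- .satterthwaite(lam, t)
    attr(p, "method") <- "satterthwaite"
    return(p)
  }

  upper <- 1 / (2 * max(lam))
  root <- tryCatch({
    f <- function(z) .kuonen_K1(z, lam) - t
    if (t > mean_t) {
      lo <- 0
      hi <- upper * (1 - 1e-12)
    } else {
      hi <- 0
      lo <- -1
      while (f(lo) > 0 && lo > -1e8) lo <- lo * 2
    }
    uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)$root
  }, error = function(e) NULL)

  if (is.null(root) || abs(root) < 1e-12) {
    p <- .satterthwaite(lam, t)
    attr(p, "method") <- "satterthwaite"
    return(p)
  }

  K <- .kuonen_K(root, lam)
  w <- sign(root) * sqrt(2 * (root * t - K))
  v <- root * sqrt(.kuonen_K2(root, lam))
  if (!is.finite(w) || !is.finite(v) || w == 0) {
    p <- .satterthwaite(lam, t)
    attr(p, "method") <- "satterthwaite"
    return(p)
  }
  p <- pnorm(w + log(v / w) / w, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  attr(p, "method") <- "saddlepoint"
  p
}
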