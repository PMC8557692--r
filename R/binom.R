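#' Log-space binomial tail probability
#'
#' The scoring function of the whole method: the probability of observing at
#' least `k` occurrences of a residue in a window of `w` positions when each
#' position carries the residue independently with background probability
#' `p`, i.e. the upper tail of Binomial(w, p), returned as log10.
#'
#' Everything downstream carries P-values in log10 space: biased-region
#' P-values in proteome scans go far below the smallest double-precision
#' positive number, so linear-space probabilities would underflow. Each tail
#' is summed term by term from `i = w` down to `i = k` with pairwise
#' log-add-exp, i.e. from the smallest term upward, so the large terms are
#' added last and cancellation is bounded; binomial coefficients come from
#' log-gamma.
#'
#' @param k Number of successes (vectorised), `0 <= k <= w`.
#' @param w Window length (vectorised along with `k`).
#' @param p Background success probability, strictly inside (0, 1).
#' @return log10 of P(X >= k), X ~ Binomial(w, p); always `<= 0` and finite.
#' @examples
#' log_binom_tail(0, 10, 0.3)        # 0: the tail from zero is certain
#' log_binom_tail(5, 5, 0.05)        # 5 * log10(0.05)
#' 10^log_binom_tail(3, 10, 0.2)     # ~0.3222
#' @seealso [tail_table()] for a cached evaluator at fixed `p`.
#' @export
log_binom_tail <- function(k, w, p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("'p' must be a single probability strictly between 0 and 1 ",
         "(a degenerate null admits no bias test)")
  }
  k <- as.integer(k)
  w <- as.integer(w)
  if (length(k) != length(w)) {
    n <- max(length(k), length(w))
    k <- rep_len(k, n)
    w <- rep_len(w, n)
  }
  if (any(k < 0L) || any(w < 0L)) stop("'k' and 'w' must be non-negative")
  if (any(k > w)) stop("'k' cannot exceed the window length 'w'")
  vapply(seq_along(k), function(i) .log10_tail_scalar(k[i], w[i], p),
         numeric(1))
}

# ln-space pairwise log-add-exp
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

.log10_tail_scalar <- function(k, w, p) {
  if (k == 0L) return(0)
  i <- w:k  # smallest terms first for p below k/w, and bounded error anyway
  terms <- lchoose(w, i) + i * log(p) + (w - i) * log1p(-p)
  acc <- terms[1L]
  for (j in seq_along(terms)[-1L]) acc <- .logaddexp(acc, terms[j])
  min(acc / log(10), 0)
}

# All tails for one window length: lt[k + 1] = log10 P(X >= k), k = 0..w.
# Computed by the same smallest-term-first recurrence as the scalar path,
# so the cached values are bit-identical to direct calls.
.log10_tail_vector <- function(w, p) {
  if (w == 0L) return(0)
  i <- 0:w
  terms <- lchoose(w, i) + i * log(p) + (w - i) * log1p(-p)
  out <- numeric(w + 1L)
  log10e <- log(10)
  acc <- terms[w + 1L]
  out[w + 1L] <- min(acc / log10e, 0)
  if (w >= 2L) {
    # scalar log-add-exp kept inline: this loop dominates table building
    for (k in seq(w - 1L, 1L, by = -1L)) {
      t <- terms[k + 1L]
      acc <- if (t > acc) t + log1p(exp(acc - t))
             else acc + log1p(exp(t - acc))
      out[k + 1L] <- min(acc / log10e, 0)
    }
  }
  out[1L] <- 0
  out
}

#' Cached binomial-tail evaluator at fixed background probability
#'
#' Scanning recomputes the same tails many times (every window length in
#' `[m, M]` times every feasible count), so tails are computed once per
#' window length and memoised. The evaluator is bit-identical to
#' [log_binom_tail()] because both sum the same terms in the same order.
#'
#' @param w_max Largest window length that will be queried.
#' @param p Background probability, strictly inside (0, 1).
#' @return A function `f(k, w)` (vectorised) returning log10 P(X >= k).
#' @export
tail_table <- function(w_max, p) {
  stopifnot(length(w_max) == 1L, w_max >= 1)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("'p' must be a single probability strictly between 0 and 1")
  }
  w_max <- as.integer(w_max)
  cache <- vector("list", w_max)
  function(k, w) {
    k <- as.integer(k)
    w <- as.integer(w)
    if (length(k) != length(w)) {
      n <- max(length(k), length(w))
      k <- rep_len(k, n)
      w <- rep_len(w, n)
    }
    if (any(w > w_max)) stop("window length exceeds the table bound")
    if (any(k > w) || any(k < 0L)) stop("need 0 <= k <= w")
    out <- numeric(length(k))
    for (wu in unique(w)) {
      if (wu >= 1L && is.null(cache[[wu]])) {
        cache[[wu]] <<- .log10_tail_vector(wu, p)
      }
      sel <- which(w == wu)
      out[sel] <- if (wu == 0L) 0 else cache[[wu]][k[sel] + 1L]
    }
    out
  }
}

# Smallest count whose tail is strictly below log10(P0) at each window
# length 1..w_max, or NA when even an all-biased window fails. Used by the
# quick scan to turn the window test into an integer threshold.
.min_count_table <- function(w_max, p, log_p0) {
  vapply(seq_len(w_max), function(w) {
    lt <- .log10_tail_vector(w, p)
    hit <- which(lt < log_p0)
    if (length(hit)) hit[1L] - 1L else NA_integer_
  }, integer(1))
}
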