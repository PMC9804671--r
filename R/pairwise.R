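#' Pairwise quality comparison of two providers
#'
#' For two providers with quality profiles `a` and `b` on a common ordered
#' scale, and independent random draws of one patient from each, computes
#' the probability that the `b` patient's quality is strictly better, the
#' probability it is strictly worse, the probability of a tie, and the
#' signed pairwise quality difference
#' \deqn{\Delta = P(Q_b > Q_a) - P(Q_a > Q_b) \in [-1, 1],}
#' positive when the second profile is statistically preferred. The
#' computation uses exact cumulative sums; the equivalent shortcut
#' \eqn{\Delta = 1 - 2[P(Q_a > Q_b) + 0.5\,P(Q_a = Q_b)]} is used as an
#' internal cross-check.
#'
#' @param a,b Either numeric profile vectors on the same scale, or a
#'   [provider_set()] in `a` with two provider ids in `b`.
#' @return A list of class `pairwise_comparison` with `p_better`,
#'   `p_worse`, `p_tie` and `delta`.
#' @examples
#' # two practices on a poor < OK < good scale
#' b <- c(0.30, 0.30, 0.40)  # practice B
#' a <- c(0.40, 0.10, 0.50)  # practice A
#' pairwise_comparison(b, a)  # P(A better) = 0.33, P(B better) = 0.32
#' @export
pairwise_comparison <- function(a, b) {
  if (inherits(a, "provider_set")) {
    ids <- b
    if (length(ids) != 2) stop("give exactly two provider ids", call. = FALSE)
    m <- a$mass[ids, , drop = FALSE]
    a <- m[1, ]
    b <- m[2, ]
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("profiles must share one quality scale (lengths differ)", call. = FALSE)
  }
  Fa0 <- c(0, cumsum(a)[-length(a)])   # F_a(q - 1)
  Fb0 <- c(0, cumsum(b)[-length(b)])
  p_better <- sum(b * Fa0)             # P(Q_b > Q_a)
  p_worse <- sum(a * Fb0)              # P(Q_a > Q_b)
  p_tie <- sum(a * b)
  delta <- p_better - p_worse
  # shortcut identity on the same cumulative sums
  delta2 <- 1 - 2 * (p_worse + 0.5 * p_tie)
  stopifnot(abs(delta - delta2) < 1e-12)
  structure(
    list(p_better = p_better, p_worse = p_worse, p_tie = p_tie, delta = delta),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf(
    "<pairwise comparison> P(second better) = %.4f, P(first better) = %.4f, P(tie) = %.4f, delta = %+.4f\n",
    x$p_better, x$p_worse, x$p_tie, x$delta))
  invisible(x)
}

# rows of lagged cumulative masses: F_k(q - 1), with F_k(0) = 0
lagged_cdf <- function(M) {
  C <- t(apply(M, 1, cumsum))
  cbind(0, C[, -ncol(M), drop = FALSE])
}

# K x K matrix of P(Q_i > Q_j) for all provider pairs
exceedance_matrix <- function(M) {
  tcrossprod(M, lagged_cdf(M))
}

# K x K matrix of signed pairwise differences: D[i, j] = Delta_{ij}
# (positive when provider j is statistically preferred to provider i).
delta_matrix <- function(ps) {
  G <- exceedance_matrix(ps$mass)
  t(G) - G
}

#' Comparative quality indices for all providers
#'
#' The comparative quality index of provider \eqn{k} is the
#' registration-weighted average of its pairwise differences against every
#' provider, \eqn{\Delta_k = \sum_{k'} p_{k'} \Delta_{k'k}}: the difference
#' in chances that a randomly chosen patient of provider \eqn{k} reports
#' strictly better rather than strictly worse quality than a randomly
#' chosen patient from the whole population. By construction the indices
#' have population-weighted mean zero and \eqn{|\Delta_k| \le 1 - p_k}.
#'
#' Computed in O(KQ) by comparing each provider against the population
#' mixture profile rather than forming all pairs.
#'
#' @param ps A [provider_set()] with at least two providers.
#' @return A data frame with columns `provider_id`, `group_id`, `weight`
#'   and `delta`.
#' @examples
#' ps <- provider_set(
#'   mass = rbind(A = c(0.40, 0.10, 0.50), B = c(0.30, 0.30, 0.40)),
#'   weight = c(0.5, 0.5)
#' )
#' comparative_indices(ps)  # +0.005 for A, -0.005 for B
#' @export
comparative_indices <- function(ps) {
  if (n_providers(ps) < 2) {
    stop("comparative indices need at least two providers", call. = FALSE)
  }
  M <- ps$mass
  Q <- ncol(M)
  pop <- population_profile(ps)
  Fpop0 <- c(0, cumsum(pop)[-Q])
  # P(Q_k > Q_pop) - P(Q_pop > Q_k), mixing over providers
  p_k_better <- drop(M %*% Fpop0)
  p_pop_better <- drop(lagged_cdf(M) %*% pop)
  data.frame(
    provider_id = provider_ids(ps),
    group_id = unname(ps$group),
    weight = unname(ps$weight),
    delta = unname(p_k_better - p_pop_better),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Lottery index of quality variation
#'
#' The normalized, registration-weighted mean absolute pairwise quality
#' difference over all distinct pairs of providers,
#' \deqn{L = \frac{\sum_k \sum_{k'} p_k p_{k'} |\Delta_{kk'}|}{1 - \sum_k p_k^2} \in [0, 1].}
#' \eqn{L = 0} when all providers are statistically equivalent and
#' \eqn{L = 1} when every pair of quality profiles is completely separated
#' (non-overlapping supports). \eqn{L/2} is the mean gain in the chance of a
#' better outcome from choosing the better of a random pair of providers
#' instead of being assigned one at random.
#'
#' @param ps A [provider_set()] with at least two providers and weights not
#'   concentrated on a single provider.
#' @return A list of class `lottery_result` with `L`, `numerator`,
#'   `normalizer`, and `K`.
#' @examples
#' ps <- provider_set(
#'   mass = rbind(A = c(0.40, 0.10, 0.50), B = c(0.30, 0.30, 0.40)),
#'   weight = c(0.5, 0.5)
#' )
#' lottery_index(ps)  # L = 0.01
#' @export
lottery_index <- function(ps) {
  if (n_providers(ps) < 2) {
    stop("lottery index needs at least two providers", call. = FALSE)
  }
  p <- ps$weight
  normalizer <- 1 - sum(p^2)
  if (normalizer <= 1e-12) {
    stop("degenerate weights: one provider holds all registration weight",
         call. = FALSE)
  }
  G <- exceedance_matrix(ps$mass)
  D <- t(G) - G
  # choice-value identity |Delta| = 2 max(P(j>i), P(i>j)) - (P(j>i) + P(i>j));
  # cross-checked against the signed computation to guard the cumulative sums
  absD2 <- 2 * pmax(t(G), G) - (t(G) + G)
  stopifnot(max(abs(abs(D) - absD2)) < 1e-12)
  numerator <- drop(p %*% abs(D) %*% p)
  structure(
    list(L = numerator / normalizer, numerator = numerator,
         normalizer = normalizer, K = length(p), se = NULL),
    class = "lottery_result"
  )
}

#' @export
print.lottery_result <- function(x, ...) {
  cat(sprintf("<lottery index> L = %.4f (numerator %.6f / normalizer %.6f, K = %d)\n",
              x$L, x$numerator, x$normalizer, x$K))
  if (!is.null(x$se)) cat(sprintf("  bootstrap SE = %.4f\n", x$se))
  invisible(x)
}
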