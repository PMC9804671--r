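#' Within-group lottery indices
#'
#' Computes the lottery index separately inside each provider group, with
#' registration weights renormalized within the group, plus an overall
#' average of the group indices weighted by group registration shares.
#' Groups with a single provider (or with all weight on one provider) have
#' no within-group variation to measure; they are reported as `NA` and
#' excluded from the average with a warning, the averaging weights being
#' renormalized over the remaining groups.
#'
#' @param ps A [provider_set()] with a group mapping.
#' @return A list with `by_group` (data frame: `group_id`, `L`, `numerator`,
#'   `normalizer`, `K`, `weight`) and `average` (the group-share-weighted
#'   mean of the defined within-group indices).
#' @examples
#' ps <- provider_set(
#'   mass = rbind(A = c(.4, .1, .5), B = c(.3, .3, .4),
#'                C = c(.4, .1, .5), D = c(.3, .3, .4)),
#'   weight = rep(0.25, 4), group = c("g1", "g1", "g2", "g2")
#' )
#' within_group_lottery(ps)$average  # 0.01
#' @export
within_group_lottery <- function(ps) {
  gs <- unique(ps$group)
  rows <- lapply(gs, function(g) {
    idx <- which(ps$group == g)
    gw <- sum(ps$weight[idx])
    if (length(idx) < 2) {
      return(data.frame(group_id = g, L = NA_real_, numerator = NA_real_,
                        normalizer = NA_real_, K = length(idx), weight = gw,
                        stringsAsFactors = FALSE))
    }
    sub <- ps[idx]
    if (1 - sum(sub$weight^2) <= 1e-12) {
      return(data.frame(group_id = g, L = NA_real_, numerator = NA_real_,
                        normalizer = NA_real_, K = length(idx), weight = gw,
                        stringsAsFactors = FALSE))
    }
    res <- lottery_index(sub)
    data.frame(group_id = g, L = res$L, numerator = res$numerator,
               normalizer = res$normalizer, K = res$K, weight = gw,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$L)
  if (!any(ok)) {
    stop("no group has two or more providers with spread-out weight; within-group lottery undefined",
         call. = FALSE)
  }
  if (any(!ok)) {
    warning(sprintf("%d group(s) with undefined within-group index excluded from the average",
                    sum(!ok)), call. = FALSE)
  }
  w <- tab$weight[ok] / sum(tab$weight[ok])
  list(by_group = tab, average = sum(w * tab$L[ok]))
}

#' Between-group lottery index
#'
#' The lottery index computed on group-level quality profiles, i.e. after
#' [aggregate_to_groups()]: variation in quality a patient faces from being
#' served by one group of providers rather than another, ignoring variation
#' inside groups.
#'
#' @param ps A [provider_set()] with at least two groups.
#' @return A `lottery_result` (see [lottery_index()]).
#' @export
between_group_lottery <- function(ps) {
  if (length(unique(ps$group)) < 2) {
    stop("between-group lottery needs at least two groups", call. = FALSE)
  }
  lottery_index(aggregate_to_groups(ps))
}

#' Within/between-group variance decomposition of comparative quality
#'
#' Splits the registration-weighted variance of provider comparative
#' quality indices into a between-group part (variance of the weighted
#' group means) and a within-group remainder; the two shares sum to one.
#'
#' @param indices Data frame from [comparative_indices()] (columns
#'   `provider_id`, `group_id`, `weight`, `delta`).
#' @param ps Optional [provider_set()] used only to check alignment.
#' @return A list with `within_share`, `between_share`, `total_variance`,
#'   `between_variance`, `within_variance` and logical `defined` (FALSE when
#'   total variance is zero, in which case the shares are `NA`).
#' @export
variance_decomposition <- function(indices, ps = NULL) {
  if (!is.null(ps)) {
    if (!identical(indices$provider_id, provider_ids(ps))) {
      stop("indices are not aligned with the provider set", call. = FALSE)
    }
  }
  w <- indices$weight / sum(indices$weight)
  d <- indices$delta
  mu <- sum(w * d)
  total <- sum(w * (d - mu)^2)
  if (total <= 0) {
    return(list(within_share = NA_real_, between_share = NA_real_,
                total_variance = 0, between_variance = 0,
                within_variance = 0, defined = FALSE))
  }
  gw <- tapply(w, indices$group_id, sum)
  gmean <- tapply(w * d, indices$group_id, sum) / gw
  between <- sum(gw * (gmean - mu)^2)
  within <- total - between
  list(within_share = within / total, between_share = between / total,
       total_variance = total, between_variance = between,
       within_variance = within, defined = TRUE)
}

#' Kendall's tau-a rank agreement between two index vectors
#'
#' \eqn{\tau_a = (C - D) / \binom{n}{2}} where \eqn{C} and \eqn{D} count
#' concordant and discordant pairs; tied pairs count toward neither but
#' stay in the denominator. \eqn{\tau_a} is the difference in the chances
#' that the two measures agree rather than disagree over which of a random
#' pair of units has the strictly better value. A normal-approximation
#' confidence interval is attached using a leave-one-out jackknife standard
#' error.
#'
#' @param x,y Numeric vectors of index values aligned by unit.
#' @param conf_level Coverage of the normal-approximation interval.
#' @return A list with `tau_a`, `concordant`, `discordant`, `n_pairs`,
#'   `se`, `ci_lower`, `ci_upper`.
#' @examples
#' rank_agreement(1:5, c(2, 1, 3, 4, 5))$tau_a
#' @export
rank_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("need at least two units", call. = FALSE)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  prod <- sx * sy
  ut <- upper.tri(prod)
  concordant <- sum(prod[ut] > 0)
  discordant <- sum(prod[ut] < 0)
  n_pairs <- n * (n - 1) / 2
  tau <- (concordant - discordant) / n_pairs
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n >= 3) {
    # jackknife over units: tau recomputed without unit i
    contrib <- rowSums(prod) # 2 * sum of pair scores involving i
    tot <- sum(prod[ut])
    tau_i <- (tot - contrib) / ((n - 1) * (n - 2) / 2)
    se <- sqrt((n - 1) / n * sum((tau_i - mean(tau_i))^2))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(tau - z * se, tau + z * se)
  }
  list(tau_a = tau, concordant = concordant, discordant = discordant,
       n_pairs = n_pairs, se = se, ci_lower = ci[1], ci_upper = ci[2])
}
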