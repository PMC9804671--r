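#' Set of provider quality profiles on a common scale
#'
#' The central container of the package: one discrete quality distribution
#' ("profile") per provider over the ordered categories of a shared
#' [quality_scale()], a registration weight per provider, and a mapping of
#' providers to groups (e.g. general practices to their commissioning
#' groups). Every patient is assumed to belong to exactly one provider, so
#' provider patient lists are independent and weights form a distribution
#' over providers.
#'
#' Proportions whose row sum deviates from 1 by more than `tol` trigger a
#' warning before renormalization (published survey tables are rounded, so
#' small deviations are silently fixed). Weights are always renormalized to
#' sum to one; zero-weight providers are retained but contribute nothing to
#' any weighted index.
#'
#' @param mass Numeric matrix, one row per provider and one column per
#'   quality category (lowest first); rows are the category proportions.
#'   Row names are the provider ids.
#' @param weight Registration weights, one per provider (non-negative;
#'   renormalized to sum to 1).
#' @param group Group id per provider (character); defaults to a single
#'   group `"all"`.
#' @param scale A [quality_scale()]; defaults to an ordinal scale labelled
#'   `q1 < q2 < ...`.
#' @param n_responses Optional positive integer vector: survey sample size
#'   behind each provider's proportions (`NA` allowed).
#' @param tol Row sums further than this from 1 raise a renormalization
#'   warning.
#'
#' @return An object of class `provider_set` with elements `mass` (rows sum
#'   to 1), `weight` (sums to 1), `group`, `scale` and `n_responses`.
#' @seealso [aggregate_to_groups()], [collapse_categories()],
#'   [read_provider_set()]
#' @examples
#' ps <- provider_set(
#'   mass = rbind(A = c(0.40, 0.10, 0.50), B = c(0.30, 0.30, 0.40)),
#'   weight = c(0.5, 0.5),
#'   scale = quality_scale(c("poor", "OK", "good"))
#' )
#' ps
#' @export
provider_set <- function(mass, weight = NULL, group = NULL, scale = NULL,
                         n_responses = NULL, tol = 1e-6) {
  mass <- as.matrix(mass)
  storage.mode(mass) <- "double"
  K <- nrow(mass)
  if (K < 1) stop("provider_set needs at least one provider", call. = FALSE)
  if (is.null(rownames(mass))) rownames(mass) <- paste0("p", seq_len(K))
  ids <- rownames(mass)
  if (anyDuplicated(ids)) stop("duplicate provider ids", call. = FALSE)

  if (is.null(scale)) scale <- quality_scale(paste0("q", seq_len(ncol(mass))))
  if (!inherits(scale, "quality_scale")) stop("`scale` must be a quality_scale", call. = FALSE)
  if (ncol(mass) != scale$Q) {
    stop(sprintf("mass has %d categories but scale has Q = %d", ncol(mass), scale$Q),
         call. = FALSE)
  }
  colnames(mass) <- as.character(scale$levels)

  if (any(!is.finite(mass))) stop("profile proportions must be finite", call. = FALSE)
  if (any(mass < 0)) {
    bad <- which(mass < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative proportion for provider '%s', category '%s'",
                 ids[bad[1]], colnames(mass)[bad[2]]), call. = FALSE)
  }
  rs <- rowSums(mass)
  if (any(rs <= 0)) {
    stop(sprintf("provider '%s' has all-zero proportions", ids[which(rs <= 0)[1]]),
         call. = FALSE)
  }
  if (any(abs(rs - 1) > tol)) {
    off <- ids[abs(rs - 1) > tol]
    warning(sprintf("renormalizing proportions for %d provider(s) whose sums deviate from 1 by > %g (e.g. '%s')",
                    length(off), tol, off[1]), call. = FALSE)
  }
  mass <- mass / rs

  if (is.null(weight)) weight <- rep(1, K)
  weight <- as.numeric(weight)
  if (length(weight) != K) stop("`weight` must have one entry per provider", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight < 0)) {
    stop(sprintf("negative or non-finite weight for provider '%s'",
                 ids[which(!is.finite(weight) | weight < 0)[1]]), call. = FALSE)
  }
  if (sum(weight) <= 0) stop("weights must not all be zero", call. = FALSE)
  weight <- weight / sum(weight)
  names(weight) <- ids

  if (is.null(group)) group <- rep("all", K)
  group <- as.character(group)
  if (length(group) != K) stop("`group` must have one entry per provider", call. = FALSE)
  if (anyNA(group)) stop("group ids must not be missing", call. = FALSE)
  names(group) <- ids

  if (!is.null(n_responses)) {
    n_responses <- as.numeric(n_responses)
    if (length(n_responses) != K) {
      stop("`n_responses` must have one entry per provider", call. = FALSE)
    }
    ok <- is.na(n_responses) | (is.finite(n_responses) & n_responses > 0)
    if (!all(ok)) stop("n_responses must be positive where present", call. = FALSE)
    names(n_responses) <- ids
  }

  structure(
    list(mass = mass, weight = weight, group = group, scale = scale,
         n_responses = n_responses),
    class = "provider_set"
  )
}

#' @export
print.provider_set <- function(x, ...) {
  cat(sprintf("<provider_set: %d providers, %d group(s), %s>\n",
              nrow(x$mass), length(unique(x$group)), format(x$scale)))
  invisible(x)
}

#' Number of providers in a provider set
#' @param x A `provider_set`.
#' @return Integer count of providers.
#' @export
n_providers <- function(x) nrow(x$mass)

provider_ids <- function(x) rownames(x$mass)

#' Subset a provider set by provider ids or positions
#' @param x A `provider_set`.
#' @param i Provider ids or integer positions (with-replacement indexing is
#'   allowed; repeated providers get unique ids).
#' @param ... Ignored.
#' @return A `provider_set` restricted to the selected providers, with
#'   weights renormalized.
#' @export
`[.provider_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, provider_ids(x))
  if (anyNA(i)) stop("unknown provider id in subset", call. = FALSE)
  m <- x$mass[i, , drop = FALSE]
  ids <- rownames(x$mass)[i]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  rownames(m) <- ids
  provider_set(
    mass = m,
    weight = x$weight[i],
    group = x$group[i],
    scale = x$scale,
    n_responses = if (!is.null(x$n_responses)) x$n_responses[i]
  )
}

#' Population quality profile
#'
#' The registration-weighted mixture of all provider profiles: the
#' distribution of quality received by a patient drawn at random from the
#' whole population.
#'
#' @param ps A [provider_set()].
#' @return Numeric vector of category proportions (sums to 1).
#' @export
population_profile <- function(ps) {
  drop(crossprod(ps$mass, ps$weight))
}

#' Aggregate provider profiles to the group level
#'
#' Forms one profile per group as the registration-weighted average of its
#' member profiles, with weights renormalized within each group, and assigns
#' each group the sum of its members' weights. The returned set has one
#' provider per former group, each in its own singleton group, so that
#' group-level indices are computed with the same machinery as
#' provider-level ones.
#'
#' @param ps A [provider_set()].
#' @return A `provider_set` of group-level profiles.
#' @examples
#' ps <- provider_set(
#'   mass = rbind(a = c(1, 0, 0), b = c(0, 0, 1)),
#'   weight = c(0.25, 0.75), group = c("g", "g")
#' )
#' aggregate_to_groups(ps)$mass  # (0.25, 0, 0.75)
#' @export
aggregate_to_groups <- function(ps) {
  gs <- unique(ps$group)
  gm <- matrix(0, length(gs), ps$scale$Q, dimnames = list(gs, colnames(ps$mass)))
  gw <- numeric(length(gs))
  for (j in seq_along(gs)) {
    idx <- ps$group == gs[j]
    w <- ps$weight[idx]
    if (sum(w) <= 0) {
      # all-zero-weight group: plain average keeps the profile defined
      w <- rep(1, sum(idx))
    }
    gm[j, ] <- drop(crossprod(ps$mass[idx, , drop = FALSE], w / sum(w)))
    gw[j] <- sum(ps$weight[idx])
  }
  provider_set(mass = gm, weight = gw, group = gs, scale = ps$scale)
}

#' Collapse quality categories into coarser ordered blocks
#'
#' Merges contiguous runs of categories (e.g. dichotomizing a 5-category
#' patient-experience scale into "not good" vs "good"); each new category's
#' mass is the sum of its constituents', and order is preserved.
#'
#' @param ps A [provider_set()].
#' @param blocks Either a list of contiguous integer index vectors
#'   partitioning `1:Q` in order, or an integer vector of upper boundaries
#'   (the last index of every block except implicitly the final one, e.g.
#'   `3` splits a 5-level scale into `1:3` and `4:5`).
#' @param labels Optional labels for the new categories; defaults to joined
#'   original labels.
#' @return A `provider_set` on the coarsened scale (at least 2 blocks).
#' @examples
#' ps <- provider_set(mass = rbind(x = c(0.021, 0.044, 0.106, 0.378, 0.451)))
#' collapse_categories(ps, blocks = 3)$mass  # 0.171, 0.829
#' @export
collapse_categories <- function(ps, blocks, labels = NULL) {
  Q <- ps$scale$Q
  if (!is.list(blocks)) {
    cuts <- sort(unique(as.integer(blocks)))
    if (any(cuts < 1 | cuts >= Q)) {
      stop("boundary cuts must lie in 1..(Q-1)", call. = FALSE)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, Q)
    blocks <- Map(seq.int, starts, ends)
  }
  if (length(blocks) < 2) {
    stop("collapsed scale must keep at least 2 categories", call. = FALSE)
  }
  flat <- unlist(blocks)
  if (!identical(as.integer(flat), seq_len(Q))) {
    stop("blocks must partition the categories into contiguous ordered runs",
         call. = FALSE)
  }
  newm <- vapply(blocks, function(ix) rowSums(ps$mass[, ix, drop = FALSE]),
                 numeric(nrow(ps$mass)))
  if (nrow(ps$mass) == 1) newm <- matrix(newm, nrow = 1)
  rownames(newm) <- rownames(ps$mass)
  if (is.null(labels)) {
    labels <- vapply(blocks, function(ix) {
      paste(ps$scale$levels[ix], collapse = "|")
    }, character(1))
  }
  provider_set(
    mass = newm, weight = ps$weight, group = ps$group,
    scale = quality_scale(labels, kind = "ordinal"),
    n_responses = ps$n_responses
  )
}
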