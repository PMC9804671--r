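test_that("comparative indices reproduce the worked example and its algebra", {
  ci <- comparative_indices(two_practice_set())
  expect_equal(ci$delta[ci$provider_id == "A"], 0.005)
  expect_equal(ci$delta[ci$provider_id == "B"], -0.005)

  # identical profiles everywhere: all indices zero
  ps0 <- provider_set(rbind(a = c(.2, .8), b = c(.2, .8), c = c(.2, .8)))
  expect_equal(comparative_indices(ps0)$delta, rep(0, 3))

  expect_error(comparative_indices(provider_set(rbind(a = c(.5, .5)))),
               "at least two")
})

test_that("comparative indices match the brute-force pairwise average and its bounds", {
  set.seed(11)
  for (i in 1:10) {
    ps <- random_set(K = 5, Q = 4)
    ci <- comparative_indices(ps)
    # oracle: weighted average over explicit pairwise comparisons
    oracle <- vapply(seq_len(5), function(k) {
      sum(vapply(seq_len(5), function(j) {
        if (j == k) return(0)
        ps$weight[j] * brute_delta(ps$mass[j, ], ps$mass[k, ])
      }, numeric(1)))
    }, numeric(1))
    expect_equal(ci$delta, oracle, tolerance = 1e-12)
    expect_equal(sum(ps$weight * ci$delta), 0, tolerance = 1e-10)
    expect_true(all(abs(ci$delta) <= 1 - ps$weight + 1e-12))
  }
})

test_that("lottery index reproduces the worked example and its bounds", {
  res <- lottery_index(two_practice_set())
  expect_equal(res$L, 0.01)
  expect_equal(res$numerator, 0.005)
  expect_equal(res$normalizer, 0.5)

  # identical profiles: minimum value zero
  ps0 <- provider_set(rbind(a = c(.3, .7), b = c(.3, .7), c = c(.3, .7)))
  expect_equal(lottery_index(ps0)$L, 0)

  # pairwise disjoint supports with equal weights: maximum value one
  ps1 <- provider_set(diag(4), weight = rep(0.25, 4))
  expect_equal(lottery_index(ps1)$L, 1)

  # all weight on one provider: degenerate
  expect_error(
    lottery_index(provider_set(rbind(a = c(.5, .5), b = c(.4, .6)),
                               weight = c(1, 0))),
    "degenerate"
  )
})

test_that("binary-scale lottery equals the weighted mean absolute difference in good-care shares", {
  set.seed(13)
  for (i in 1:10) {
    K <- sample(3:8, 1)
    good <- runif(K)
    M <- cbind(1 - good, good)
    rownames(M) <- paste0("p", 1:K)
    w <- runif(K); w <- w / sum(w)
    ps <- provider_set(M, weight = w)
    oracle <- sum(outer(w, w) * abs(outer(good, good, "-"))) / (1 - sum(w^2))
    expect_equal(lottery_index(ps)$L, oracle, tolerance = 1e-12)
  }
})

test_that("indices are invariant to monotone relabeling of the categories", {
  set.seed(17)
  ps <- random_set(K = 6, Q = 5, n_groups = 2)
  relabeled <- provider_set(
    mass = ps$mass, weight = ps$weight, group = ps$group,
    scale = quality_scale(c("E", "D+", "C", "B-", "A*"))  # new labels, same order
  )
  expect_identical(comparative_indices(ps)$delta,
                   comparative_indices(relabeled)$delta)
  expect_identical(lottery_index(ps)$L, lottery_index(relabeled)$L)
  expect_identical(between_group_lottery(ps)$L,
                   between_group_lottery(relabeled)$L)
})

test_that("within-group lottery averages group indices by registration share", {
  # two identical copies of the worked-example pair
  ps <- provider_set(
    mass = rbind(A1 = practice_A, B1 = practice_B,
                 A2 = practice_A, B2 = practice_B),
    weight = rep(0.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  res <- within_group_lottery(ps)
  expect_equal(res$by_group$L, c(0.01, 0.01))
  expect_equal(res$average, 0.01)

  # group with one shared profile contributes zero
  ps2 <- provider_set(
    mass = rbind(A = practice_A, B = practice_B,
                 C = c(.2, .2, .6), D = c(.2, .2, .6)),
    weight = rep(0.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  expect_equal(within_group_lottery(ps2)$by_group$L[2], 0)

  # permutation invariance
  set.seed(19)
  ps3 <- random_set(K = 10, Q = 4, n_groups = 3)
  perm <- sample(10)
  res3a <- within_group_lottery(ps3)
  res3b <- within_group_lottery(ps3[perm])
  expect_equal(res3a$average, res3b$average, tolerance = 1e-14)
  ord <- match(res3a$by_group$group_id, res3b$by_group$group_id)
  expect_equal(res3a$by_group$L, res3b$by_group$L[ord], tolerance = 1e-14)
})

test_that("singleton groups are excluded from the within-group average with a warning", {
  ps <- provider_set(
    mass = rbind(A = practice_A, B = practice_B, C = c(.2, .2, .6)),
    weight = c(0.4, 0.4, 0.2), group = c("g1", "g1", "g2")
  )
  expect_warning(res <- within_group_lottery(ps), "excluded")
  expect_true(is.na(res$by_group$L[res$by_group$group_id == "g2"]))
  expect_equal(res$average, 0.01)

  ps_all_single <- provider_set(rbind(a = c(.5, .5), b = c(.4, .6)),
                                group = c("g1", "g2"))
  expect_error(within_group_lottery(ps_all_single), "within-group")
})

test_that("between-group lottery works on aggregated profiles", {
  # groups with identical aggregates but different internal spreads
  ps <- provider_set(
    mass = rbind(a = c(1, 0), b = c(0, 1), c = c(.5, .5), d = c(.5, .5)),
    weight = rep(.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  expect_equal(between_group_lottery(ps)$L, 0)

  # two equal-weight groups whose aggregates are the worked-example profiles
  ps2 <- provider_set(
    mass = rbind(a = practice_A, b = practice_A, c = practice_B, d = practice_B),
    weight = rep(.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  expect_equal(between_group_lottery(ps2)$L, 0.01)

  expect_error(between_group_lottery(two_practice_set()), "two groups")
})

test_that("between-group lottery is invariant to aggregate-preserving reshuffles", {
  set.seed(23)
  ps <- random_set(K = 8, Q = 4, n_groups = 2, weights = rep(1, 8))
  base <- between_group_lottery(ps)$L
  # swap quality mass between two equal-weight providers of the same group
  M <- ps$mass
  eps <- 0.05
  M[1, ] <- M[1, ] + c(eps, -eps, 0, 0)
  M[3, ] <- M[3, ] - c(eps, -eps, 0, 0)  # providers 1 and 3 share group g1
  stopifnot(all(M >= 0), ps$group[1] == ps$group[3])
  ps_shuffled <- provider_set(M, weight = ps$weight, group = ps$group)
  expect_equal(between_group_lottery(ps_shuffled)$L, base, tolerance = 1e-12)
  expect_true(between_group_lottery(ps)$L <= 1)
})

test_that("variance decomposition splits patient-weighted variance by group", {
  # no within spread: each group internally identical, group means differ
  ps_b <- provider_set(
    mass = rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1)),
    weight = rep(.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  vb <- variance_decomposition(comparative_indices(ps_b), ps_b)
  expect_equal(vb$between_share, 1)
  expect_equal(vb$within_share, 0)

  # group means all equal, spread inside groups
  ps_w <- provider_set(
    mass = rbind(a = c(1, 0), b = c(0, 1), c = c(0, 1), d = c(1, 0)),
    weight = rep(.25, 4), group = c("g1", "g1", "g2", "g2")
  )
  vw <- variance_decomposition(comparative_indices(ps_w), ps_w)
  expect_equal(vw$between_share, 0)
  expect_equal(vw$within_share, 1)

  # zero total variance: undefined with flag
  ps0 <- provider_set(rbind(a = c(.5, .5), b = c(.5, .5)))
  v0 <- variance_decomposition(comparative_indices(ps0), ps0)
  expect_false(v0$defined)
  expect_true(is.na(v0$within_share))

  # random case against a direct two-pass oracle
  set.seed(29)
  ps <- random_set(K = 12, Q = 5, n_groups = 3)
  ci <- comparative_indices(ps)
  v <- variance_decomposition(ci, ps)
  w <- ci$weight; d <- ci$delta; mu <- sum(w * d)
  total <- sum(w * (d - mu)^2)
  between <- 0
  for (g in unique(ci$group_id)) {
    idx <- ci$group_id == g
    gw <- sum(w[idx]); gm <- sum(w[idx] * d[idx]) / gw
    between <- between + gw * (gm - mu)^2
  }
  expect_equal(v$between_share, between / total, tolerance = 1e-12)
  expect_equal(v$within_share + v$between_share, 1, tolerance = 1e-12)
})

test_that("tau-a counts concordant minus discordant pairs over all pairs", {
  x <- 1:5
  expect_equal(rank_agreement(x, x)$tau_a, 1)
  expect_equal(rank_agreement(x, rev(x))$tau_a, -1)

  # n = 4 with one adjacent swap: one discordant pair out of six
  expect_equal(rank_agreement(1:4, c(2, 1, 3, 4))$tau_a, 4 / 6)

  # enumeration oracle on a random instance with ties
  set.seed(31)
  xs <- sample(1:4, 8, replace = TRUE)
  ys <- sample(1:4, 8, replace = TRUE)
  conc <- disc <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    s <- sign(xs[i] - xs[j]) * sign(ys[i] - ys[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  expect_equal(rank_agreement(xs, ys)$tau_a, (conc - disc) / choose(8, 2))

  # all-tied input: zero
  expect_equal(rank_agreement(rep(1, 5), 1:5)$tau_a, 0)
  expect_error(rank_agreement(1:3, 1:4), "equal length")
})

test_that("tau-a confidence interval brackets the point estimate symmetrically", {
  set.seed(33)
  r <- rank_agreement(rnorm(30), rnorm(30))
  expect_true(r$ci_lower < r$tau_a && r$tau_a < r$ci_upper)
  expect_equal(r$tau_a - r$ci_lower, r$ci_upper - r$tau_a, tolerance = 1e-12)
  expect_true(r$se > 0)
})
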