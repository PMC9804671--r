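# shared fixtures and independent oracles

# the two-practice example: A = 40/10/50, B = 30/30/40 over poor < OK < good
practice_A <- c(0.40, 0.10, 0.50)
practice_B <- c(0.30, 0.30, 0.40)

two_practice_set <- function(weight = c(0.5, 0.5), group = c("g1", "g1")) {
  provider_set(
    mass = rbind(A = practice_A, B = practice_B),
    weight = weight, group = group,
    scale = quality_scale(c("poor", "OK", "good"))
  )
}

random_profile <- function(Q) {
  m <- stats::runif(Q)
  m / sum(m)
}

random_set <- function(K, Q, n_groups = 1, weights = NULL) {
  M <- t(replicate(K, random_profile(Q)))
  rownames(M) <- paste0("p", seq_len(K))
  if (is.null(weights)) weights <- stats::runif(K, 0.5, 2)
  grp <- paste0("g", rep_len(seq_len(n_groups), K))
  provider_set(mass = M, weight = weights, group = grp)
}

# brute-force double-sum oracle over all Q x Q cells:
# P(second strictly better) - P(first strictly better)
brute_delta <- function(a, b) {
  S <- outer(seq_along(b), seq_along(a), function(i, j) sign(i - j))
  sum(outer(b, a) * S)
}

# brute-force cross-pair oracle for two cardinal samples with weights
brute_delta_scores <- function(sa, sb, wa = NULL, wb = NULL) {
  if (is.null(wa)) wa <- rep(1, length(sa))
  if (is.null(wb)) wb <- rep(1, length(sb))
  W <- outer(wb, wa)
  (sum(W * outer(sb, sa, ">")) - sum(W * outer(sb, sa, "<"))) / sum(W)
}
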