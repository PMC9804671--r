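#' Configuration for the synthetic multi-provider survey generator
#'
#' Describes a ground-truth data-generating process emulating national
#' GP-patient-survey-style data: providers nested in groups, each provider
#' with a socio-demographic composition, a latent quality location driven
#' by compositional main effects plus a group effect and idiosyncratic
#' provider noise, ordered-threshold category probabilities on a standard
#' normal latent scale, and multinomial survey noise on the observed
#' proportions.
#'
#' Defaults describe a compact study population: 5 groups of 40 providers
#' on a 5-category scale with 200 survey responses per provider, with
#' thresholds placed so the baseline national profile is 2.1/4.4/10.6/37.8/45.1
#' percent from worst to best category (the national distribution of
#' overall patient-experience responses that the generator emulates).
#'
#' @param n_groups Number of provider groups.
#' @param providers_per_group Providers in each group.
#' @param thresholds Strictly increasing ordered-probit thresholds
#'   (length Q-1) on the standard normal latent scale.
#' @param beta Named vector of compositional main effects on the latent
#'   quality scale (positive = better quality); names must be composition
#'   columns. Defaults give worse experience for working-age, Asian-ethnicity,
#'   long-term-condition and deprived patient lists.
#' @param group_sd SD of the group-level latent effect.
#' @param practice_sd SD of the idiosyncratic provider-level latent effect.
#' @param n_responses Survey responses per provider (scalar), or `NULL`
#'   for noise-free profiles equal to the true category probabilities.
#' @param concentration Dirichlet concentration for the share blocks
#'   (larger = more homogeneous compositions).
#' @param registration_meanlog,registration_sdlog Log-normal parameters of
#'   provider registration counts (weights are the normalized draws).
#' @param latent `"normal"` (ordered probit; default) or `"linear"`
#'   (cumulative proportions directly linear in the covariates, the
#'   regime in which the linear-probability model is exactly specified).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 5,
                       providers_per_group = 40,
                       thresholds = stats::qnorm(cumsum(c(0.021, 0.044, 0.106, 0.378))),
                       beta = c(age25_34 = -0.4, age35_44 = -0.4, age45_54 = -0.25,
                                eth_asian = -0.6, ltc = -0.4, imd = -0.012),
                       group_sd = 0.08,
                       practice_sd = 0.20,
                       n_responses = 200,
                       concentration = 50,
                       registration_meanlog = log(7000),
                       registration_sdlog = 0.45,
                       latent = c("normal", "linear"),
                       seed = 1) {
  latent <- match.arg(latent)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing with length Q - 1 >= 1",
         call. = FALSE)
  }
  if (group_sd < 0 || practice_sd < 0) stop("effect SDs must be >= 0", call. = FALSE)
  structure(
    list(n_groups = n_groups, providers_per_group = providers_per_group,
         thresholds = thresholds, beta = beta, group_sd = group_sd,
         practice_sd = practice_sd, n_responses = n_responses,
         concentration = concentration,
         registration_meanlog = registration_meanlog,
         registration_sdlog = registration_sdlog,
         latent = latent, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Dirichlet draws via independent gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

sim_blocks <- function() {
  list(
    sex = c("female", "male"),
    age = c("age16_24", "age25_34", "age35_44", "age45_54",
            "age55_64", "age65_74", "age75_84", "age85p"),
    ethnicity = c("eth_white", "eth_asian", "eth_black", "eth_mixed", "eth_other")
  )
}

sim_block_means <- function() {
  list(
    sex = c(0.51, 0.49),
    age = c(0.13, 0.17, 0.16, 0.17, 0.15, 0.12, 0.07, 0.03),
    ethnicity = c(0.85, 0.08, 0.03, 0.02, 0.02)
  )
}

#' Generate a synthetic provider population with known ground truth
#'
#' Draws compositions, latent quality locations, true category
#' probabilities and (optionally) multinomial survey noise according to a
#' [sim_config()]. Latent locations are centred so the
#' registration-weighted national profile sits at the configured
#' thresholds.
#'
#' @param cfg A [sim_config()].
#' @return A list with `ps` (the observed [provider_set()]), `X` (the
#'   [composition_matrix()]) and `truth` (ground-truth record: the true
#'   mass matrix, latent pieces, and the config), of class `sim_data`.
#' @export
generate_provider_data <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_groups * cfg$providers_per_group
  Q <- length(cfg$thresholds) + 1
  ids <- sprintf("prov%03d", seq_len(K))
  grp <- rep(sprintf("grp%02d", seq_len(cfg$n_groups)),
             each = cfg$providers_per_group)

  blocks <- sim_blocks()
  means <- sim_block_means()
  comp <- data.frame(provider_id = ids, group_id = grp,
                     stringsAsFactors = FALSE)
  for (bn in names(blocks)) {
    B <- rdirichlet(K, cfg$concentration * means[[bn]])
    colnames(B) <- blocks[[bn]]
    comp <- cbind(comp, as.data.frame(B))
  }
  comp$ltc <- stats::rbeta(K, 0.5 * 30, 0.5 * 30)
  comp$imd <- stats::rgamma(K, shape = 2.5, scale = 8.6)

  reg <- stats::rlnorm(K, cfg$registration_meanlog, cfg$registration_sdlog)
  w <- reg / sum(reg)

  covars <- setdiff(names(comp), c("provider_id", "group_id"))
  beta_full <- stats::setNames(numeric(length(covars)), covars)
  unknown <- setdiff(names(cfg$beta), covars)
  if (length(unknown)) {
    stop(sprintf("beta names not in composition: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  beta_full[names(cfg$beta)] <- cfg$beta

  Xc <- as.matrix(comp[, covars])
  eta_comp <- drop(Xc %*% beta_full)
  eta_comp <- eta_comp - sum(w * eta_comp)      # centre compositional part
  u_g <- stats::rnorm(cfg$n_groups, 0, cfg$group_sd)
  names(u_g) <- unique(grp)
  e_k <- stats::rnorm(K, 0, cfg$practice_sd)
  # centre each latent piece so the national profile stays at the thresholds
  eta <- eta_comp + (u_g[grp] - sum(w * u_g[grp])) + (e_k - sum(w * e_k))

  probs_from_eta <- function(e) {
    if (cfg$latent == "normal") {
      Fm <- stats::pnorm(outer(-e, cfg$thresholds, `+`))   # F(q) = pnorm(theta_q - eta)
    } else {
      baseF <- stats::pnorm(cfg$thresholds)
      Fm <- outer(rep(1, length(e)), baseF) - outer(e, rep(1, Q - 1))
      Fm <- pmin(pmax(Fm, 0), 1)
      if (Q > 2) Fm <- t(apply(Fm, 1, cummax))
    }
    M <- cbind(Fm, 1) - cbind(0, Fm)
    M
  }
  true_mass <- probs_from_eta(eta)
  rownames(true_mass) <- ids

  scale <- if (Q == 5) {
    quality_scale(c("very poor", "fairly poor", "neither", "fairly good", "very good"))
  } else {
    quality_scale(paste0("q", seq_len(Q)))
  }

  if (is.null(cfg$n_responses)) {
    obs <- true_mass
    nresp <- NULL
  } else {
    n <- rep(cfg$n_responses, K)
    obs <- t(vapply(seq_len(K), function(k) {
      as.numeric(stats::rmultinom(1, n[k], true_mass[k, ])) / n[k]
    }, numeric(Q)))
    rownames(obs) <- ids
    nresp <- n
  }

  ps <- provider_set(mass = obs, weight = w, group = grp, scale = scale,
                     n_responses = nresp)
  X <- composition_matrix(comp, blocks = blocks)
  truth <- list(cfg = cfg, true_mass = true_mass, eta = eta,
                eta_comp = eta_comp, group_effects = u_g,
                practice_noise = e_k, beta = beta_full, weight = w,
                group = grp, ids = ids, scale = scale,
                probs_from_eta = probs_from_eta)
  structure(list(ps = ps, X = X, truth = truth), class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data: %d providers in %d groups, Q = %d, seed %d>\n",
              n_providers(x$ps), length(unique(x$ps$group)),
              x$ps$scale$Q, x$truth$cfg$seed))
  invisible(x)
}

#' Oracle indices computed on the true category probabilities
#'
#' Computes raw, standardized and residual lottery indices from the
#' generator's ground truth, bypassing estimation: raw indices use the
#' true category probabilities; standardized truth zeroes the provider
#' noise and replaces each group effect by the registration-share-weighted
#' average of the group effects (the neutralization applied by
#' [predict_standardized()]); residual truth is their difference.
#'
#' @param truth The `truth` element of [generate_provider_data()].
#' @return A data frame with columns `statistic`, `raw`, `standardized`,
#'   `residual` for the average within-group and the between-group lottery
#'   index.
#' @export
true_indices <- function(truth) {
  mk <- function(M) {
    provider_set(mass = M, weight = truth$weight, group = truth$group,
                 scale = truth$scale)
  }
  ps_raw <- mk(truth$true_mass)
  w_avg_gshare <- tapply(truth$weight, truth$group, sum)
  eta_std <- truth$eta_comp + sum(w_avg_gshare * truth$group_effects[names(w_avg_gshare)])
  M_std <- truth$probs_from_eta(eta_std)
  rownames(M_std) <- truth$ids
  ps_std <- mk(M_std)

  some_multi <- any(table(truth$group) >= 2)
  multi_grp <- length(unique(truth$group)) >= 2
  raw_within <- if (some_multi) within_group_lottery(ps_raw)$average else NA_real_
  std_within <- if (some_multi) within_group_lottery(ps_std)$average else NA_real_
  raw_between <- if (multi_grp) between_group_lottery(ps_raw)$L else NA_real_
  std_between <- if (multi_grp) between_group_lottery(ps_std)$L else NA_real_
  out <- data.frame(
    statistic = c("within_group_average_L", "between_group_L"),
    raw = c(raw_within, raw_between),
    standardized = c(std_within, std_between),
    stringsAsFactors = FALSE
  )
  out$residual <- out$raw - out$standardized
  out
}
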