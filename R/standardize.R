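#' Socio-demographic composition of provider patient lists
#'
#' Per-provider covariates used as regressors in the indirect
#' standardization model: share blocks that each sum to one (e.g. sex,
#' age bands, ethnicity), free-standing shares (e.g. proportion with a
#' long-term condition) and continuous scores (e.g. an area deprivation
#' index). One reference column per block is dropped at model time.
#'
#' @param df Data frame with columns `provider_id`, `group_id` and numeric
#'   covariate columns.
#' @param blocks Named list of character vectors: the columns forming each
#'   simplex block (shares within a block must sum to 1 per provider,
#'   tolerance `1e-6`).
#' @param reference Named character vector or list: the column of each
#'   block to drop as the reference category. Defaults to each block's
#'   first column.
#' @return An object of class `composition_matrix`.
#' @export
composition_matrix <- function(df, blocks = list(), reference = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c("provider_id", "group_id")) {
    if (!col %in% names(df)) {
      stop(sprintf("composition table needs a '%s' column", col), call. = FALSE)
    }
  }
  if (anyDuplicated(df$provider_id)) {
    stop("duplicate provider rows in composition table", call. = FALSE)
  }
  covars <- setdiff(names(df), c("provider_id", "group_id"))
  for (v in covars) {
    if (!is.numeric(df[[v]])) stop(sprintf("covariate '%s' must be numeric", v), call. = FALSE)
    if (anyNA(df[[v]])) stop(sprintf("covariate '%s' has missing values", v), call. = FALSE)
  }
  for (bn in names(blocks)) {
    cols <- blocks[[bn]]
    miss <- setdiff(cols, covars)
    if (length(miss)) {
      stop(sprintf("block '%s' names absent column(s): %s", bn,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    B <- as.matrix(df[, cols, drop = FALSE])
    if (any(B < -1e-9) || any(B > 1 + 1e-9)) {
      stop(sprintf("block '%s' has shares outside [0, 1]", bn), call. = FALSE)
    }
    if (any(abs(rowSums(B) - 1) > 1e-6)) {
      stop(sprintf("block '%s' shares do not sum to 1 for provider '%s'",
                   bn, df$provider_id[which(abs(rowSums(B) - 1) > 1e-6)[1]]),
           call. = FALSE)
    }
  }
  ref <- lapply(blocks, `[[`, 1)
  if (!is.null(reference)) {
    for (bn in names(reference)) {
      if (!reference[[bn]] %in% blocks[[bn]]) {
        stop(sprintf("reference '%s' is not in block '%s'", reference[[bn]], bn),
             call. = FALSE)
      }
      ref[[bn]] <- reference[[bn]]
    }
  }
  structure(
    list(data = df, blocks = blocks, reference = ref,
         covariates = covars),
    class = "composition_matrix"
  )
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("<composition_matrix: %d providers, %d covariates, %d share block(s)>\n",
              nrow(x$data), length(x$covariates), length(x$blocks)))
  invisible(x)
}

# design matrix with one reference column dropped per share block and the
# first group dropped as reference; group dummy columns are flagged so
# prediction can swap them for population shares
build_design <- function(X, ids, group_levels = NULL) {
  df <- X$data[match(ids, X$data$provider_id), , drop = FALSE]
  if (anyNA(df$provider_id)) {
    stop("composition table does not cover every provider", call. = FALSE)
  }
  drop_cols <- unlist(X$reference, use.names = FALSE)
  keep <- setdiff(X$covariates, drop_cols)
  M <- as.matrix(df[, keep, drop = FALSE])
  if (is.null(group_levels)) group_levels <- unique(df$group_id)
  gidx <- match(df$group_id, group_levels)
  if (anyNA(gidx)) stop("provider group not among model group levels", call. = FALSE)
  n_dummies <- max(length(group_levels) - 1, 0)
  Gd <- matrix(0, nrow(df), n_dummies)
  if (n_dummies > 0) {
    colnames(Gd) <- paste0("group:", group_levels[-1])
    for (j in seq_len(n_dummies)) Gd[, j] <- as.numeric(gidx == j + 1)
  }
  list(design = cbind(`(Intercept)` = 1, M, Gd),
       covariate_cols = keep,
       group_cols = colnames(Gd),
       group_levels = group_levels)
}

#' Fit a distribution regression model for indirect standardization
#'
#' Characterizes the conditional distribution of provider quality by one
#' binary-outcome regression per cumulative cutoff \eqn{q = 1, \dots, Q-1}:
#' the dependent variable is each provider's observed cumulative proportion
#' \eqn{F_k(q)} of patients reporting quality no better than \eqn{q}, and
#' the regressors are the provider's socio-demographic composition (main
#' effects only) plus group intercept dummies.
#'
#' Two links are offered: `"lpdrm"`, a linear probability model fitted by
#' weighted least squares with registration weights; and `"gldrm"`, a
#' probit-link binomial quasi-likelihood in which the binomial denominator
#' is the provider's number of survey responses (1, with a warning, where
#' absent).
#'
#' @param ps A [provider_set()].
#' @param X A [composition_matrix()] covering every provider in `ps`.
#' @param link `"lpdrm"` or `"gldrm"`.
#' @return An object of class `distribution_regression` holding the
#'   \eqn{Q-1} coefficient vectors, the design metadata, the sample
#'   weighted mean of \eqn{F(q)} and of the category masses (rescale
#'   targets), and the fitting weights.
#' @export
fit_distribution_regression <- function(ps, X, link = c("lpdrm", "gldrm")) {
  link <- match.arg(link)
  ids <- provider_ids(ps)
  ds <- build_design(X, ids)
  # group mapping must agree between the two tables
  xg <- X$data$group_id[match(ids, X$data$provider_id)]
  if (!all(xg == unname(ps$group))) {
    stop("group ids differ between profiles and composition", call. = FALSE)
  }
  A <- ds$design
  # constant covariate columns carry no between-provider information and are
  # absorbed by the intercept; genuine collinearity among varying columns is
  # an error naming the offending columns
  const <- apply(A[, -1, drop = FALSE], 2, function(z) diff(range(z)) == 0)
  if (any(const)) A <- A[, c(TRUE, !const), drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    dropped <- colnames(A)[qrA$pivot[(qrA$rank + 1):ncol(A)]]
    stop(sprintf("collinear covariates: %s", paste(dropped, collapse = ", ")),
         call. = FALSE)
  }
  ds$kept_cols <- colnames(A)
  Q <- ps$scale$Q
  Fmat <- t(apply(ps$mass, 1, cumsum))      # K x Q, last column = 1
  if (link == "lpdrm") {
    wt <- ps$weight
  } else {
    n <- ps$n_responses
    if (is.null(n) || anyNA(n)) {
      warning("n_responses absent for some providers; using n = 1 for the binomial denominator",
              call. = FALSE)
      if (is.null(n)) n <- rep(1, length(ids))
      n[is.na(n)] <- 1
    }
    wt <- n
  }
  coefs <- matrix(NA_real_, Q - 1, ncol(A), dimnames = list(NULL, colnames(A)))
  for (q in seq_len(Q - 1)) {
    y <- pmin(pmax(Fmat[, q], 0), 1)
    if (link == "lpdrm") {
      fit <- stats::lm.wfit(A, y, w = wt)
      coefs[q, ] <- fit$coefficients
    } else {
      fit <- suppressWarnings(stats::glm.fit(
        A, y, weights = wt,
        family = stats::quasibinomial(link = "probit")
      ))
      coefs[q, ] <- fit$coefficients
    }
  }
  # registration-weighted sample means, the rescale targets
  target_F <- drop(ps$weight %*% Fmat)[seq_len(Q - 1)]
  target_mass <- drop(ps$weight %*% ps$mass)
  structure(
    list(link = link, coefficients = coefs, design_info = ds,
         provider_ids = ids, weight = ps$weight, scale = ps$scale,
         target_cumulative = target_F, target_mass = target_mass),
    class = "distribution_regression"
  )
}

#' @export
print.distribution_regression <- function(x, ...) {
  cat(sprintf("<distribution_regression: %s link, %d cutoff equations, %d columns>\n",
              x$link, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Counterfactual (indirectly standardized) quality profiles
#'
#' Predicts, for each provider, the quality profile expected if quality
#' conditional on socio-demographic composition were the same everywhere:
#' the provider's own composition enters the fitted cutoff equations, but
#' its group dummy is replaced by the population-share-weighted average of
#' the estimated group effects (on the link scale), so that group-specific
#' influences are neutralized. Predicted cumulative proportions are
#' censored to the unit interval, made non-decreasing across cutoffs by a
#' cumulative maximum, rescaled so their weighted mean matches the sample
#' weighted mean at each cutoff, and differenced into category masses.
#'
#' @param model A [fit_distribution_regression()] fit.
#' @param X A [composition_matrix()]; defaults to covering the fitted
#'   providers.
#' @param population_group_shares Named numeric vector of group weights
#'   summing to 1 used to average the group effects; defaults to the
#'   registration shares of the fitted set.
#' @param rescale `"multiplicative"` (default), `"additive"`, or `"none"`.
#' @param rescale_on Match the sample mean of the cumulative proportions
#'   (`"cumulative"`, default) or of the category masses (`"mass"`).
#' @return A list of class `standardized_profiles` with `profiles` (a
#'   [provider_set()] of counterfactual masses with the original weights
#'   and groups), `scaling` (per-cutoff factors applied), `censored`
#'   (count of predictions clamped per cutoff) and `second_pass` (count of
#'   residual monotonicity violations fixed after rescaling).
#' @export
predict_standardized <- function(model, X, population_group_shares = NULL,
                                 rescale = c("multiplicative", "additive", "none"),
                                 rescale_on = c("cumulative", "mass")) {
  rescale <- match.arg(rescale)
  rescale_on <- match.arg(rescale_on)
  ids <- model$provider_ids
  ds <- build_design(X, ids, group_levels = model$design_info$group_levels)
  A <- ds$design
  glv <- model$design_info$group_levels
  if (is.null(population_group_shares)) {
    population_group_shares <- tapply(model$weight,
                                      X$data$group_id[match(ids, X$data$provider_id)],
                                      sum)
  }
  shares <- population_group_shares[glv]
  if (anyNA(shares)) stop("population_group_shares must cover every group", call. = FALSE)
  shares <- shares / sum(shares)
  # swap each provider's group dummies for the population shares of the
  # non-reference groups: on the link scale this replaces the provider's
  # group effect with the share-weighted average effect (reference = 0)
  A[, ds$group_cols] <- matrix(shares[-1], nrow(A), length(glv) - 1, byrow = TRUE)
  kept <- model$design_info$kept_cols
  if (!is.null(kept)) A <- A[, kept, drop = FALSE]

  Q <- model$scale$Q
  eta <- A %*% t(model$coefficients)            # K x (Q-1)
  Fhat <- if (model$link == "gldrm") stats::pnorm(eta) else eta

  censored <- colSums(Fhat < 0 | Fhat > 1)
  Fhat <- pmin(pmax(Fhat, 0), 1)
  if (Q > 2) Fhat <- t(apply(Fhat, 1, cummax))

  w <- model$weight
  scaling <- rep(1, Q - 1)
  if (rescale != "none" && rescale_on == "cumulative") {
    for (q in seq_len(Q - 1)) {
      m <- sum(w * Fhat[, q])
      if (rescale == "multiplicative") {
        if (m > 0) {
          scaling[q] <- model$target_cumulative[q] / m
          Fhat[, q] <- Fhat[, q] * scaling[q]
        }
      } else {
        scaling[q] <- model$target_cumulative[q] - m
        Fhat[, q] <- Fhat[, q] + scaling[q]
      }
    }
    Fhat <- pmin(pmax(Fhat, 0), 1)
  }
  mono2 <- 0L
  if (Q > 2) {
    cm <- t(apply(Fhat, 1, cummax))
    mono2 <- sum(cm != Fhat)
    Fhat <- cm
  }

  Mhat <- cbind(Fhat, 1)
  Mhat <- Mhat - cbind(0, Fhat)
  colnames(Mhat) <- as.character(model$scale$levels)
  rownames(Mhat) <- ids

  if (rescale != "none" && rescale_on == "mass") {
    achieved <- drop(w %*% Mhat)
    fac <- ifelse(achieved > 0, model$target_mass / achieved, 1)
    Mhat <- sweep(Mhat, 2, fac, `*`)
    Mhat <- Mhat / rowSums(Mhat)
    scaling <- fac
  }

  grp <- X$data$group_id[match(ids, X$data$provider_id)]
  structure(
    list(
      profiles = provider_set(mass = Mhat, weight = w, group = grp,
                              scale = model$scale),
      scaling = scaling, censored = censored, second_pass = mono2
    ),
    class = "standardized_profiles"
  )
}

#' @export
print.standardized_profiles <- function(x, ...) {
  cat(sprintf("<standardized_profiles: %d providers; %d censored prediction(s); %d second-pass monotonicity fix(es)>\n",
              n_providers(x$profiles), sum(x$censored), x$second_pass))
  invisible(x)
}

#' Raw, standardized and residual quality-variation indices
#'
#' Runs the full indirect-standardization pipeline and reports, side by
#' side, the raw lottery indices (average within-group and between-group),
#' the same indices on the counterfactual standardized profiles, and the
#' residual defined as raw minus standardized — the part of the variation
#' not explained by socio-demographic composition. Comparative quality
#' indices at the requested level are reported the same way.
#'
#' @param ps A [provider_set()].
#' @param X A [composition_matrix()].
#' @param link `"lpdrm"` or `"gldrm"`.
#' @param level Level for the comparative indices: `"group"` (default) or
#'   `"provider"`.
#' @param ... Passed to [predict_standardized()] (`rescale`, `rescale_on`,
#'   `population_group_shares`).
#' @return A list with `lottery` (data frame: statistic, raw, standardized,
#'   residual), `comparative` (data frame keyed by id) and `fit` details
#'   (`model`, `standardized` profiles).
#' @export
standardized_and_residual_indices <- function(ps, X, link = c("lpdrm", "gldrm"),
                                              level = c("group", "provider"), ...) {
  link <- match.arg(link)
  level <- match.arg(level)
  model <- fit_distribution_regression(ps, X, link)
  std <- predict_standardized(model, X, ...)

  multi_group <- length(unique(ps$group)) >= 2
  some_group_multi <- any(table(ps$group) >= 2)

  raw_within <- if (some_group_multi) within_group_lottery(ps)$average else NA_real_
  std_within <- if (some_group_multi) within_group_lottery(std$profiles)$average else NA_real_
  raw_between <- if (multi_group) between_group_lottery(ps)$L else NA_real_
  std_between <- if (multi_group) between_group_lottery(std$profiles)$L else NA_real_

  lot <- data.frame(
    statistic = c("within_group_average_L", "between_group_L"),
    raw = c(raw_within, raw_between),
    standardized = c(std_within, std_between),
    stringsAsFactors = FALSE
  )
  lot$residual <- lot$raw - lot$standardized

  lvl_ps <- if (level == "group") aggregate_to_groups(ps) else ps
  lvl_std <- if (level == "group") aggregate_to_groups(std$profiles) else std$profiles
  ci_raw <- comparative_indices(lvl_ps)
  ci_std <- comparative_indices(lvl_std)
  comp <- data.frame(
    id = ci_raw$provider_id,
    raw = ci_raw$delta,
    standardized = ci_std$delta[match(ci_raw$provider_id, ci_std$provider_id)],
    stringsAsFactors = FALSE
  )
  comp$residual <- comp$raw - comp$standardized

  list(lottery = lot, comparative = comp, model = model, standardized = std)
}
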