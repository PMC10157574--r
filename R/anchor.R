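#' Fit the anchoring regression
#'
#' Ordinary least squares linking the two measurement arms over the anchor
#' states: the PHE-derived DW estimates (dependent variable, logit scale
#' by default so predictions stay inside (0, 1)) on the paired-comparison
#' predicted probabilities `pnorm(beta)` (default regressor; the raw
#' latent index is available as an alternative). Healthier states have
#' higher predicted probabilities and lower DWs, so a well-behaved fit has
#' a negative slope.
#'
#' @param phe_dws Tibble `state_id`, `dw_phe` from [phe_dw_estimates()].
#' @param probit_fit A `dw_probit_fit`.
#' @param anchor_states Optional subset of state IDs to anchor on
#'   (default: all states present in both inputs).
#' @param dependent_scale `"logit"` (default) or `"identity"`.
#' @param regressor `"probability"` (default, `pnorm(beta)`) or `"index"`
#'   (`beta`).
#' @return Object of class `dw_anchor`: `intercept`, `slope`,
#'   `r_squared`, scales, and the anchor table used.
#' @export
fit_anchor <- function(phe_dws, probit_fit, anchor_states = NULL,
                       dependent_scale = c("logit", "identity"),
                       regressor = c("probability", "index")) {
  dependent_scale <- match.arg(dependent_scale)
  regressor <- match.arg(regressor)
  ids <- intersect(phe_dws$state_id, probit_fit$states)
  if (!is.null(anchor_states)) ids <- intersect(ids, anchor_states)
  if (length(ids) < 2) abort("need >= 2 usable anchor states")

  pp <- predicted_probability(probit_fit, ids)
  x <- if (regressor == "probability") pp$prob else pp$beta
  dw <- phe_dws$dw_phe[match(ids, phe_dws$state_id)]
  y <- if (dependent_scale == "logit") logit(dw) else dw
  if (stats::var(x) == 0) abort("zero variance in the anchoring regressor")

  fit <- stats::lm.fit(cbind(1, x), y)
  coefs <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 dependent_scale = dependent_scale, regressor = regressor,
                 anchors = tibble(state_id = as.integer(ids), x = x,
                                  dw_phe = dw),
                 n_anchors = length(ids)),
            class = "dw_anchor")
}

anchor_regressor <- function(anchor, beta) {
  if (anchor$regressor == "probability") stats::pnorm(beta) else beta
}

#' Predict disability weights for all states from the anchored index
#'
#' Applies the anchoring map to every fitted state:
#' `DW = T^{-1}(a + b * x(state))` with `x` the chosen regressor. On the
#' logit dependent scale predictions lie in (0, 1) by construction; on the
#' identity scale they are clamped to \[0, 1\] with a warning.
#'
#' @param anchor A `dw_anchor`.
#' @param probit_fit A `dw_probit_fit`.
#' @param state_id Optional subset (default: all fitted states).
#' @return Tibble `state_id`, `dw`.
#' @export
predict_dws <- function(anchor, probit_fit, state_id = NULL) {
  pp <- predicted_probability(probit_fit, state_id)
  lin <- anchor$intercept + anchor$slope * anchor_regressor(anchor, pp$beta)
  dw <- if (anchor$dependent_scale == "logit") {
    expit(lin)
  } else {
    n_clamped <- sum(lin < 0 | lin > 1)
    if (n_clamped > 0) {
      warn(paste0(n_clamped, " prediction(s) clamped to [0, 1]"))
    }
    pmin(pmax(lin, 0), 1)
  }
  tibble(state_id = pp$state_id, dw = dw)
}

nearest_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-12)) return((V + t(V)) / 2)
  warn("covariance not positive semi-definite; projecting to nearest PSD")
  vals <- pmax(e$values, 0)
  e$vectors %*% (vals * t(e$vectors))
}

#' Monte Carlo mean of the anchored disability weights
#'
#' Propagates probit estimation uncertainty through the (nonlinear)
#' anchoring map: draws index vectors from the multivariate normal with
#' the probit point estimate and covariance (in the free parameterisation,
#' so the identifiability constraint is respected), pushes each draw
#' through [predict_dws()], and averages per state. The anchoring
#' coefficients are held at their point estimates; their sampling
#' variation enters the uncertainty intervals through the bootstrap
#' instead.
#'
#' @param anchor A `dw_anchor`.
#' @param probit_fit A `dw_probit_fit`.
#' @param n_draws Number of normal draws (default 1000).
#' @param seed Integer seed.
#' @return Tibble `state_id`, `dw_mean`.
#' @export
monte_carlo_mean <- function(anchor, probit_fit, n_draws = 1000L, seed = 1L) {
  p <- length(probit_fit$states)
  theta_hat <- if (probit_fit$constraint == "sum") {
    probit_fit$beta[-p] # free params
  } else {
    probit_fit$beta[-1L]
  }
  V <- probit_fit$vcov_free
  if (all(abs(V) < 1e-300)) {
    pt <- predict_dws(anchor, probit_fit)
    return(dplyr::rename(pt, dw_mean = "dw"))
  }
  V <- nearest_psd(V)
  draws <- with_seed(derive_seed(seed, "monte_carlo_mean"),
                     MASS::mvrnorm(n_draws, mu = theta_hat, Sigma = V,
                                   tol = 1e-6))
  B <- draws %*% t(probit_fit$basis)  # n_draws x p, constraint respected
  lin <- anchor$intercept + anchor$slope * anchor_regressor(anchor, B)
  dwm <- if (anchor$dependent_scale == "logit") {
    colMeans(expit(lin))
  } else {
    colMeans(pmin(pmax(lin, 0), 1))
  }
  tibble(state_id = probit_fit$states, dw_mean = unname(dwm))
}

#' @export
tidy.dw_anchor <- function(x, ...) {
  tibble(term = c("(Intercept)", x$regressor),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.dw_anchor <- function(x, ...) {
  tibble(r.squared = x$r_squared, n_anchors = x$n_anchors,
         dependent_scale = x$dependent_scale, regressor = x$regressor)
}

#' @export
print.dw_anchor <- function(x, ...) {
  cat("Anchoring regression: ", x$dependent_scale, "(DW_PHE) ~ ",
      x$regressor, "\n  intercept ", format(x$intercept, digits = 4),
      ", slope ", format(x$slope, digits = 4),
      ", R^2 ", format(x$r_squared, digits = 3),
      " on ", x$n_anchors, " anchors\n", sep = "")
  invisible(x)
}

#' Bootstrap 95% uncertainty intervals for the disability weights
#'
#' Resamples respondents with replacement (the exchangeable unit),
#' stratified by survey mode so household/web counts — and hence the
#' web-only PHE arm — are preserved; re-runs the whole estimation chain
#' (probit, interval regression, anchoring, prediction) per replicate; and
#' reports the 2.5th/97.5th percentiles of the replicate DWs per state.
#' Replicates in which a state drops out of the fit (or a replicate whose
#' estimation fails) are excluded for that state; states missing from more
#' than 10% of replicates are flagged unreliable.
#'
#' @param respondents,pc_responses,phe_responses QC-filtered survey tables.
#' @param catalog A `dw_catalog`.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param penalty,interval_scale,anchor_scale,regressor,anchor_states
#'   Estimation options, as in the point-estimate chain.
#' @param start Optional probit warm start (named beta).
#' @return Tibble `state_id`, `ui_low`, `ui_high`, `n_reps_used`,
#'   `unreliable`.
#' @export
bootstrap_ui <- function(respondents, pc_responses, phe_responses, catalog,
                         n_reps = 1000L, seed = 1L, penalty = 1e-6,
                         interval_scale = "logit", anchor_scale = "logit",
                         regressor = "probability", anchor_states = NULL,
                         start = NULL) {
  ids <- respondents$respondent_id
  modes <- split(seq_along(ids), respondents$mode)
  pc_responses <- dplyr::filter(pc_responses, .data$respondent_id %in% ids)
  phe_responses <- dplyr::filter(phe_responses, .data$respondent_id %in% ids)
  design <- suppressWarnings(build_pc_design(pc_responses, catalog))
  # map each retained design row to its respondent
  keep <- pc_responses$first_state %in% design$states &
    pc_responses$second_state %in% design$states
  pc_rid <- match(pc_responses$respondent_id[keep], ids)
  obs <- phe_to_interval(phe_responses, scale = interval_scale)
  phe_rid <- match(phe_responses$respondent_id, ids)

  all_states <- design$states
  reps <- with_seed(derive_seed(seed, "bootstrap_ui"), {
    lapply(seq_len(n_reps), function(r) {
      mult <- integer(length(ids))
      for (m in modes) {
        tab <- tabulate(sample(m, length(m), replace = TRUE),
                        nbins = length(ids))
        mult <- mult + tab
      }
      tryCatch({
        pfit <- suppressWarnings(
          fit_pc_probit(design, penalty = penalty, weights = mult[pc_rid],
                        start = start))
        w_obs <- obs
        w_obs$weight <- mult[phe_rid]
        ifit <- suppressWarnings(fit_interval_regression(w_obs,
                                                         interval_scale))
        anc <- fit_anchor(phe_dw_estimates(ifit, drop_boundary = TRUE), pfit,
                          anchor_states = anchor_states,
                          dependent_scale = anchor_scale,
                          regressor = regressor)
        pred <- predict_dws(anc, pfit)
        stats::setNames(pred$dw, pred$state_id)[as.character(all_states)]
      }, error = function(e) {
        stats::setNames(rep(NA_real_, length(all_states)), all_states)
      })
    })
  })
  M <- do.call(rbind, reps)
  # type 6 = (R+1)-based order statistics, the usual bootstrap percentile
  # convention (slightly wider tails at modest replicate counts)
  qs <- apply(M, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 6)
  used <- colSums(!is.na(M))
  tibble(state_id = as.integer(all_states),
         ui_low = unname(qs[1, ]), ui_high = unname(qs[2, ]),
         n_reps_used = unname(used),
         unreliable = unname(used < 0.9 * n_reps))
}

#' @export
autoplot.dw_anchor <- function(object, ...) {
  df <- object$anchors
  xs <- seq(min(df$x), max(df$x), length.out = 200)
  line <- tibble(x = xs, dw = if (object$dependent_scale == "logit") {
    expit(object$intercept + object$slope * xs)
  } else {
    pmin(pmax(object$intercept + object$slope * xs, 0), 1)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$dw_phe)) +
    ggplot2::geom_line(data = line, ggplot2::aes(y = .data$dw),
                       colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = if (object$regressor == "probability") {
        "Predicted probability of being judged healthier"
      } else "Latent healthiness index",
      y = "PHE disability weight") +
    ggplot2::theme_minimal()
}
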