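transform_dw <- function(x, scale) {
  switch(scale, logit = logit(x), log = log(x),
         abort(paste0("unknown scale: ", scale)))
}

inv_transform_dw <- function(x, scale) {
  switch(scale, logit = expit(x), log = exp(x))
}

#' Convert population-health-equivalence choices to censored observations
#'
#' A PHE question compares a program averting 1000 rapid deaths with one
#' averting M nonfatal lifelong cases of a state, so the indifference
#' threshold on the DW scale is `t = 1000/M`. Choosing the nonfatal
#' program reveals `DW > t` (a left-censored observation `(T(t), +Inf)` on
#' the transformed scale); choosing the fatal program reveals `DW < t`
#' (`(-Inf, T(t))`). The transform T is `logit` (default) or `log`.
#'
#' @param phe_responses Tibble `respondent_id`, `state`, `multiplier`,
#'   `choice` (`"fatal_program"`/`"nonfatal_program"`).
#' @param scale `"logit"` or `"log"`.
#' @param multipliers Valid multiplier set.
#' @return Tibble `state_id`, `lower`, `upper` (transformed-scale bounds,
#'   `-Inf`/`Inf` for the open side), with the scale kept as an attribute.
#' @export
phe_to_interval <- function(phe_responses, scale = c("logit", "log"),
                            multipliers = c(1500, 2000, 3000, 5000, 10000)) {
  scale <- match.arg(scale)
  bad <- setdiff(unique(phe_responses$multiplier), multipliers)
  if (length(bad) > 0) {
    abort(paste0("invalid multiplier(s): ", paste(bad, collapse = ", ")))
  }
  tt <- transform_dw(1000 / phe_responses$multiplier, scale)
  nonfatal <- phe_responses$choice == "nonfatal_program"
  out <- tibble(state_id = as.integer(phe_responses$state),
                lower = ifelse(nonfatal, tt, -Inf),
                upper = ifelse(nonfatal, Inf, tt))
  attr(out, "scale") <- scale
  out
}

#' Fit the interval regression of PHE-implied DW bounds
#'
#' Single-threshold censored-normal model: on the transformed scale the
#' latent DW of anchor state s is `Normal(gamma_s, sigma^2)` with a common
#' residual SD, and each PHE choice contributes
#' `log(Phi((upper - gamma_s)/sigma) - Phi((lower - gamma_s)/sigma))` to
#' the likelihood (infinite bounds handled as CDF limits). Maximised by
#' L-BFGS-B over `(gamma, log sigma)` with analytic gradients; `gamma` is
#' box-constrained to `T((1e-4, 1 - 1e-4))` so one-sided data cannot push
#' an estimate to infinity (boundary hits are flagged and warned).
#' Deterministic start: per-state means of finite bounds, `sigma = 1`.
#'
#' @param observations Output of [phe_to_interval()] (scale attribute
#'   honoured), optionally with a `weight` column.
#' @param scale Transform used; defaults to the observations' attribute.
#' @return Object of class `dw_interval_fit`: `gamma` (named per state),
#'   `sigma`, `loglik`, `scale`, `boundary_states`, `convergence`.
#' @export
fit_interval_regression <- function(observations,
                                    scale = attr(observations, "scale")) {
  scale <- scale %||% "logit"
  obs <- as_tibble(observations)
  if (nrow(obs) == 0) abort("no observations")
  if (!("weight" %in% names(obs))) obs$weight <- 1
  if (anyNA(obs$weight)) abort("missing observation weights")
  obs <- obs[obs$weight > 0, ]
  if (any(obs$lower >= obs$upper)) abort("need lower < upper for every row")

  # sigma is identified only if some state is observed in both directions
  dirs <- dplyr::summarise(obs,
                           has_lo = any(is.finite(.data$lower)),
                           has_hi = any(is.finite(.data$upper)),
                           .by = "state_id")
  if (!any(dirs$has_lo & dirs$has_hi)) {
    abort(paste0("residual SD not identifiable: no anchor state has ",
                 "observations in both directions"))
  }

  agg <- dplyr::summarise(obs, w = sum(.data$weight),
                          .by = c("state_id", "lower", "upper"))
  states <- sort(unique(agg$state_id))
  si <- match(agg$state_id, states)
  p <- length(states)
  glo <- transform_dw(1e-4, scale)
  ghi <- transform_dw(1 - 1e-4, scale)

  start_gamma <- vapply(states, function(s) {
    b <- agg[agg$state_id == s, ]
    fin <- c(b$lower[is.finite(b$lower)], b$upper[is.finite(b$upper)])
    mean(fin)
  }, numeric(1))
  start <- c(pmin(pmax(start_gamma, glo), ghi), 0)  # last: log sigma

  negll <- function(par) {
    gamma <- par[seq_len(p)]
    sigma <- exp(par[p + 1L])
    zu <- (agg$upper - gamma[si]) / sigma
    zl <- (agg$lower - gamma[si]) / sigma
    # one side is always infinite here, but handle the general case
    ll <- ifelse(is.infinite(agg$upper),
                 stats::pnorm(zl, log.p = TRUE, lower.tail = FALSE),
                 ifelse(is.infinite(agg$lower),
                        stats::pnorm(zu, log.p = TRUE),
                        log(pmax(stats::pnorm(zu) - stats::pnorm(zl),
                                 1e-300))))
    -sum(agg$w * ll)
  }

  neggrad <- function(par) {
    gamma <- par[seq_len(p)]
    sigma <- exp(par[p + 1L])
    zu <- (agg$upper - gamma[si]) / sigma
    zl <- (agg$lower - gamma[si]) / sigma
    # d loglik / d gamma and d/d log sigma, per aggregated row
    dg <- numeric(nrow(agg))
    ds <- numeric(nrow(agg))
    up <- is.infinite(agg$lower)   # right-censored: log Phi(zu)
    lo <- is.infinite(agg$upper)   # left-censored:  log Phi(-zl)
    dg[up] <- -mills(zu[up]) / sigma
    ds[up] <- -mills(zu[up]) * zu[up]
    dg[lo] <- mills(-zl[lo]) / sigma
    ds[lo] <- mills(-zl[lo]) * zl[lo]
    both <- !up & !lo
    if (any(both)) {
      den <- pmax(stats::pnorm(zu[both]) - stats::pnorm(zl[both]), 1e-300)
      du <- stats::dnorm(zu[both])
      dl <- stats::dnorm(zl[both])
      dg[both] <- -(du - dl) / (den * sigma)
      ds[both] <- -(du * zu[both] - dl * zl[both]) / den
    }
    gg <- tapply(agg$w * dg, si, sum)
    g <- numeric(p + 1L)
    g[as.integer(names(gg))] <- gg
    g[p + 1L] <- sum(agg$w * ds)
    -g
  }

  fit <- stats::optim(start, negll, neggrad, method = "L-BFGS-B",
                      lower = c(rep(glo, p), log(1e-3)),
                      upper = c(rep(ghi, p), log(1e3)),
                      control = list(maxit = 1000, factr = 1e2))
  if (!(fit$convergence %in% c(0L, 52L))) {
    abort(paste0("interval regression did not converge: code ",
                 fit$convergence, " (", fit$message, ")"))
  }
  gamma <- stats::setNames(fit$par[seq_len(p)], states)
  tol <- 1e-6 * (ghi - glo)
  at_bound <- states[gamma <= glo + tol | gamma >= ghi - tol]
  # states observed in one direction only reveal a bound, not a location:
  # their gamma is driven by the box constraint / residual SD, not by data
  one_sided <- dirs$state_id[!(dirs$has_lo & dirs$has_hi)]
  boundary <- sort(union(at_bound, one_sided))
  if (length(boundary) > 0) {
    warn(paste0("one-sided or bound-pinned interval data for state(s) ",
                paste(boundary, collapse = ", "),
                "; location not identified, interpret with care"))
  }
  structure(list(gamma = gamma, sigma = exp(fit$par[p + 1L]),
                 loglik = -fit$value, scale = scale,
                 n_observations = sum(agg$w),
                 boundary_states = as.integer(boundary),
                 convergence = fit$convergence),
            class = "dw_interval_fit")
}

#' DW estimates of the anchor states from an interval fit
#'
#' Inverse-transforms the fitted locations back to the 0-1 DW scale.
#'
#' @param fit A `dw_interval_fit`.
#' @param drop_boundary Drop states whose location was pinned at the box
#'   bound by entirely one-sided data (such estimates carry only a bound,
#'   not a location, and would distort the anchoring regression).
#' @return Tibble `state_id`, `dw_phe`, strictly inside (0, 1).
#' @export
phe_dw_estimates <- function(fit, drop_boundary = FALSE) {
  out <- tibble(state_id = as.integer(names(fit$gamma)),
                dw_phe = unname(inv_transform_dw(fit$gamma, fit$scale)))
  if (drop_boundary) {
    out <- out[!(out$state_id %in% fit$boundary_states), ]
  }
  out
}

#' @export
tidy.dw_interval_fit <- function(x, ...) {
  dplyr::mutate(phe_dw_estimates(x), gamma = unname(x$gamma),
                boundary = .data$state_id %in% x$boundary_states)
}

#' @export
glance.dw_interval_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sigma = x$sigma, scale = x$scale,
         n_observations = x$n_observations,
         n_states = length(x$gamma),
         n_boundary = length(x$boundary_states))
}

#' @export
print.dw_interval_fit <- function(x, ...) {
  cat("Interval regression (", x$scale, " scale): ", length(x$gamma),
      " anchor states, sigma = ", format(x$sigma, digits = 4), "\n",
      sep = "")
  invisible(x)
}
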