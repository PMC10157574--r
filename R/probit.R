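#' Build the paired-comparison probit design
#'
#' Encodes PC responses for the Thurstonian probit model: per response the
#' state shown first is coded +1, the state shown second -1, all other
#' states 0, and the outcome is 1 when the first state was chosen as the
#' healthier one. Responses referencing states without an estimable DW are
#' excluded with a warning.
#'
#' @param pc_responses Tibble `respondent_id`, `first_state`,
#'   `second_state`, `choice`.
#' @param catalog A `dw_catalog`; defines which states are estimable.
#' @return Object of class `dw_pc_design`: the response-level tibble
#'   (`first_state`, `second_state`, `y`) plus the included state set.
#' @export
build_pc_design <- function(pc_responses, catalog) {
  if (any(pc_responses$first_state == pc_responses$second_state)) {
    abort("a response pairs a state with itself")
  }
  states <- catalog$state_id[catalog$dw_available]
  ok <- pc_responses$first_state %in% states &
    pc_responses$second_state %in% states
  if (any(!ok)) {
    warn(paste0(sum(!ok), " response(s) reference states without an",
                " estimable DW and were excluded"))
  }
  d <- pc_responses[ok, ]
  structure(list(
    responses = tibble(first_state = as.integer(d$first_state),
                       second_state = as.integer(d$second_state),
                       y = as.integer(d$choice == "first")),
    states = states,
    n_responses = nrow(d),
    n_excluded = sum(!ok)
  ), class = "dw_pc_design")
}

#' Design matrix of a paired-comparison design
#'
#' Dense +1/-1/0 matrix representation (one row per response, one column
#' per state). Intended for small designs; the fitter works from the
#' aggregated form.
#'
#' @param design A `dw_pc_design`.
#' @return List with `X` (matrix) and `y` (0/1 outcome vector).
#' @export
pc_design_matrix <- function(design) {
  r <- design$responses
  X <- matrix(0, nrow(r), length(design$states),
              dimnames = list(NULL, design$states))
  X[cbind(seq_len(nrow(r)), match(r$first_state, design$states))] <- 1
  X[cbind(seq_len(nrow(r)), match(r$second_state, design$states))] <- -1
  list(X = X, y = r$y)
}

# Aggregate responses to unique (first, second) cells with trial and win
# counts; optional per-response weights (bootstrap multiplicities).
aggregate_design <- function(design, weights = NULL) {
  r <- design$responses
  w <- if (is.null(weights)) rep(1, nrow(r)) else weights
  agg <- dplyr::summarise(
    dplyr::mutate(r, .w = w),
    n = sum(.data$.w), wins = sum(.data$.w * .data$y),
    .by = c("first_state", "second_state"))
  agg[agg$n > 0, ]
}

# Stable phi(x)/Phi(x) ("inverse Mills ratio").
mills <- function(x) {
  exp(stats::dnorm(x, log = TRUE) - stats::pnorm(x, log.p = TRUE))
}

#' Penalised log-likelihood of the paired-comparison probit
#'
#' `sum(y * log(pnorm(eta)) + (1 - y) * log(pnorm(-eta))) -
#' penalty * sum(beta^2)` with `eta = beta[first] - beta[second]`, using
#' log-scale normal CDFs so extreme linear predictors stay finite.
#'
#' @param beta Named numeric vector of state indices (names = state IDs).
#' @param design A `dw_pc_design`.
#' @param penalty Ridge coefficient.
#' @return The penalised log-likelihood (scalar).
#' @export
probit_loglik <- function(beta, design, penalty = 0) {
  agg <- aggregate_design(design)
  eta <- beta[as.character(agg$first_state)] -
    beta[as.character(agg$second_state)]
  ll <- sum(agg$wins * stats::pnorm(eta, log.p = TRUE) +
              (agg$n - agg$wins) * stats::pnorm(-eta, log.p = TRUE))
  ll - penalty * sum(beta^2)
}

# Constraint basis C (p x (p-1)) mapping free parameters to beta = C theta.
# "sum": sum-to-zero; "reference": first state fixed at 0.
constraint_basis <- function(p, constraint) {
  if (constraint == "sum") {
    rbind(diag(p - 1L), rep(-1, p - 1L))
  } else {
    rbind(matrix(0, 1L, p - 1L), diag(p - 1L))
  }
}

#' Fit the Thurstonian paired-comparison probit by maximum likelihood
#'
#' Newton-Raphson maximisation of the ridge-penalised probit likelihood on
#' the aggregated choice counts, under an identifiability constraint (the
#' +1/-1 coding identifies only differences between states). The default
#' sum-to-zero constraint treats all states symmetrically; a
#' reference-state constraint (first state pinned at 0) is available to
#' verify that downstream anchored DWs do not depend on the choice. The
#' small default ridge keeps estimates finite under quasi-complete
#' separation (a state winning or losing all its comparisons), which is
#' detected and warned about.
#'
#' @param design A `dw_pc_design` from [build_pc_design()].
#' @param penalty Ridge coefficient (default 1e-6; negligible at survey
#'   scale).
#' @param constraint `"sum"` (default) or `"reference"`.
#' @param weights Optional per-response weights (bootstrap multiplicities).
#' @param start Optional named start vector (defaults to all zero).
#' @param tol Convergence: gradient max-norm below `tol`.
#' @param max_iter Newton iteration cap.
#' @return Object of class `dw_probit_fit`: `beta` (named, satisfying the
#'   constraint), `vcov` (on the beta scale), `vcov_free`, `basis`,
#'   `loglik`, `penalty`, `n_responses`, `dropped_states`,
#'   `separated_states`, `iterations`.
#' @export
fit_pc_probit <- function(design, penalty = 1e-6,
                          constraint = c("sum", "reference"),
                          weights = NULL, start = NULL,
                          tol = 1e-8, max_iter = 100L) {
  constraint <- match.arg(constraint)
  agg <- aggregate_design(design, weights)
  if (nrow(agg) == 0) abort("empty design: nothing to fit")

  seen <- sort(unique(c(agg$first_state, agg$second_state)))
  dropped <- setdiff(design$states, seen)
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " state(s) with no responses dropped: ",
                paste(utils::head(dropped, 5), collapse = ", ")))
  }
  p <- length(seen)
  if (p < 2) abort("need >= 2 states with responses")
  i1 <- match(agg$first_state, seen)
  i2 <- match(agg$second_state, seen)

  # separation diagnostics: states that win or lose every comparison
  tot_n <- tapply(c(agg$n, agg$n), c(i1, i2), sum)
  tot_w <- tapply(c(agg$wins, agg$n - agg$wins), c(i1, i2), sum)
  sep <- seen[which(tot_w == 0 | tot_w == tot_n)]
  if (length(sep) > 0) {
    warn(paste0("quasi-complete separation for state(s) ",
                paste(sep, collapse = ", "),
                "; estimates finite via ridge penalty"))
  }

  C <- constraint_basis(p, constraint)
  theta <- if (is.null(start)) {
    rep(0, p - 1L)
  } else {
    b0 <- start[as.character(seen)]
    b0[is.na(b0)] <- 0
    if (constraint == "sum") b0[-p] - mean(b0) else (b0 - b0[1L])[-1L]
  }

  pen_ll <- function(beta) {
    eta <- beta[i1] - beta[i2]
    sum(agg$wins * stats::pnorm(eta, log.p = TRUE) +
          (agg$n - agg$wins) * stats::pnorm(-eta, log.p = TRUE)) -
      penalty * sum(beta^2)
  }

  grad_hess <- function(beta) {
    eta <- beta[i1] - beta[i2]
    v <- mills(eta)     # d/deta log Phi(eta)
    u <- mills(-eta)    # -d/deta log Phi(-eta)
    g_eta <- agg$wins * v - (agg$n - agg$wins) * u
    w_eta <- agg$wins * v * (eta + v) + (agg$n - agg$wins) * u * (u - eta)
    g <- rep(0, p)
    g[seq_len(p)] <- tapply(c(g_eta, -g_eta), c(i1, i2), sum,
                            default = 0)[as.character(seq_len(p))]
    g[is.na(g)] <- 0
    g <- g - 2 * penalty * beta
    H <- matrix(0, p, p)
    for (k in seq_len(nrow(agg))) {
      wk <- w_eta[k]
      H[i1[k], i1[k]] <- H[i1[k], i1[k]] - wk
      H[i2[k], i2[k]] <- H[i2[k], i2[k]] - wk
      H[i1[k], i2[k]] <- H[i1[k], i2[k]] + wk
      H[i2[k], i1[k]] <- H[i2[k], i1[k]] + wk
    }
    diag(H) <- diag(H) - 2 * penalty
    list(g = g, H = H)
  }

  ll <- pen_ll(as.vector(C %*% theta))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    beta <- as.vector(C %*% theta)
    gh <- grad_hess(beta)
    g_free <- crossprod(C, gh$g)
    if (max(abs(g_free)) < tol) {
      converged <- TRUE
      break
    }
    H_free <- crossprod(C, gh$H %*% C)
    step <- tryCatch(solve(-H_free, g_free),
                     error = function(e) g_free / max(abs(diag(H_free)), 1))
    # step halving keeps Newton globally stable
    alpha <- 1
    repeat {
      theta_new <- theta + alpha * as.vector(step)
      ll_new <- pen_ll(as.vector(C %*% theta_new))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    if (abs(ll_new - ll) < 1e-13 && max(abs(g_free)) < 1e-6) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
    ll <- ll_new
  }
  if (!converged) {
    abort(paste0("probit fit did not converge after ", iter,
                 " iterations (gradient max-norm ",
                 format(max(abs(g_free))), ")"))
  }

  beta <- as.vector(C %*% theta)
  gh <- grad_hess(beta)
  H_free <- crossprod(C, gh$H %*% C)
  vcov_free <- tryCatch(solve(-H_free), error = function(e) {
    warn("observed information singular; using pseudo-inverse")
    MASS::ginv(-H_free)
  })
  vcov_beta <- C %*% vcov_free %*% t(C)
  names(beta) <- seen
  dimnames(vcov_beta) <- list(seen, seen)

  structure(list(beta = beta, vcov = vcov_beta, vcov_free = vcov_free,
                 basis = C, states = seen, constraint = constraint,
                 loglik = pen_ll(beta), penalty = penalty,
                 n_responses = if (is.null(weights)) design$n_responses
                               else sum(weights),
                 dropped_states = dropped, separated_states = sep,
                 iterations = iter),
            class = "dw_probit_fit")
}

#' Predicted probability of being judged healthier
#'
#' `pnorm(beta)` per state: the model probability that the state is judged
#' healthier than a hypothetical average state (index 0 under the
#' constraint). These predicted probabilities are the regressor of the
#' anchoring step.
#'
#' @param fit A `dw_probit_fit`.
#' @param state_id Optional subset of states (default: all fitted).
#' @return Tibble `state_id`, `beta`, `prob`.
#' @export
predicted_probability <- function(fit, state_id = NULL) {
  ids <- state_id %||% fit$states
  idx <- match(as.integer(ids), fit$states)
  if (anyNA(idx)) {
    abort(paste0("state(s) not in fit: ",
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  tibble(state_id = as.integer(ids), beta = unname(fit$beta[idx]),
         prob = stats::pnorm(unname(fit$beta[idx])))
}

#' @export
tidy.dw_probit_fit <- function(x, ...) {
  tibble(state_id = x$states,
         estimate = unname(x$beta),
         std.error = sqrt(pmax(diag(x$vcov), 0)))
}

#' @export
glance.dw_probit_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_responses = x$n_responses,
         n_states = length(x$states), penalty = x$penalty,
         iterations = x$iterations,
         n_separated = length(x$separated_states))
}

#' @export
print.dw_probit_fit <- function(x, ...) {
  cat("Paired-comparison probit fit:", length(x$states), "states,",
      x$n_responses, "responses\n")
  cat("  log-likelihood:", format(x$loglik), " constraint:", x$constraint,
      "\n")
  if (length(x$separated_states) > 0) {
    cat("  separated states:", paste(x$separated_states, collapse = ", "),
        "\n")
  }
  invisible(x)
}
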