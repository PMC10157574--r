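test_that("PHE choices map to the right censored intervals", {
  phe <- tibble::tibble(
    respondent_id = c("a", "b", "c"),
    state = c(1L, 1L, 2L),
    multiplier = c(2000, 10000, 1500),
    choice = c("nonfatal_program", "fatal_program", "nonfatal_program"))
  obs <- phe_to_interval(phe)  # logit scale
  expect_equal(obs$lower, c(qlogis(0.5), -Inf, qlogis(2 / 3)))
  expect_equal(obs$upper, c(Inf, qlogis(0.1), Inf))
  expect_equal(obs$lower[1], 0)
  expect_equal(obs$upper[2], qlogis(0.1), tolerance = 1e-12)

  logobs <- phe_to_interval(phe, scale = "log")
  expect_equal(logobs$upper[2], log(0.1))

  bad <- dplyr::mutate(phe, multiplier = c(2000, 2500, 1500))
  expect_error(phe_to_interval(bad), "invalid multiplier")
})

test_that("symmetric censoring at one threshold puts the location there", {
  phe <- phe_from_counts(1L, list(
    list(m = 2000, choice = "fatal_program", n = 50),
    list(m = 2000, choice = "nonfatal_program", n = 50)))
  fit <- fit_interval_regression(phe_to_interval(phe))
  expect_equal(unname(fit$gamma), 0, tolerance = 1e-5)
  expect_equal(phe_dw_estimates(fit)$dw_phe, 0.5, tolerance = 1e-5)
})

test_that("the interval MLE matches a two-dimensional grid oracle", {
  gamma_star <- qlogis(0.2)
  sigma_star <- 0.6
  mults <- c(1500, 2000, 3000, 5000, 10000)
  set.seed(77)
  m <- sample(mults, 500, replace = TRUE)
  t_logit <- qlogis(1000 / m)
  p_nonfatal <- pnorm((gamma_star - t_logit) / sigma_star)
  choice <- ifelse(runif(500) < p_nonfatal, "nonfatal_program",
                   "fatal_program")
  phe <- tibble::tibble(respondent_id = sprintf("r%03d", 1:500),
                        state = 1L, multiplier = m, choice = choice)
  obs <- phe_to_interval(phe)
  fit <- fit_interval_regression(obs)

  # independent oracle: two-stage grid over (gamma, sigma) of the same
  # censored-normal likelihood, final resolution 1e-3
  ll <- function(g, s) {
    z <- (t_logit - g) / s
    sum(ifelse(choice == "nonfatal_program",
               pnorm(z, log.p = TRUE, lower.tail = FALSE),
               pnorm(z, log.p = TRUE)))
  }
  centre <- c(qlogis(0.25), 1)
  for (step in c(0.02, 1e-3)) {
    gg <- seq(centre[1] - 30 * step, centre[1] + 30 * step, by = step)
    ss <- seq(max(centre[2] - 30 * step, 0.01), centre[2] + 30 * step,
              by = step)
    val <- outer(gg, ss, Vectorize(ll))
    ix <- arrayInd(which.max(val), dim(val))
    centre <- c(gg[ix[1]], ss[ix[2]])
  }
  expect_equal(unname(fit$gamma), centre[1], tolerance = 1.5e-3)
  expect_equal(fit$sigma, centre[2], tolerance = 1.5e-3)
  # and it recovered the truth to sampling accuracy
  expect_equal(unname(fit$gamma), gamma_star, tolerance = 0.15)
})

test_that("one-sided data are flagged; wholly one-sided designs error", {
  both <- dplyr::bind_rows(
    phe_from_counts(1L, list(
      list(m = 10000, choice = "fatal_program", n = 40))),
    phe_from_counts(2L, list(
      list(m = 2000, choice = "fatal_program", n = 20),
      list(m = 2000, choice = "nonfatal_program", n = 20))))
  expect_warning(fit <- fit_interval_regression(phe_to_interval(both)),
                 "one-sided")
  expect_true(1L %in% fit$boundary_states)
  expect_false(2L %in% fit$boundary_states)
  # the flagged state is excluded from anchoring targets on request
  expect_equal(phe_dw_estimates(fit, drop_boundary = TRUE)$state_id, 2L)

  onesided <- phe_from_counts(1L, list(
    list(m = 10000, choice = "fatal_program", n = 40)))
  expect_error(fit_interval_regression(phe_to_interval(onesided)),
               "not identifiable")
})

test_that("the likelihood is invariant to duplication up to a factor of two", {
  phe <- phe_from_counts(1L, list(
    list(m = 2000, choice = "fatal_program", n = 30),
    list(m = 2000, choice = "nonfatal_program", n = 10),
    list(m = 5000, choice = "fatal_program", n = 10),
    list(m = 5000, choice = "nonfatal_program", n = 25),
    list(m = 10000, choice = "nonfatal_program", n = 25)))
  obs <- phe_to_interval(phe)
  f1 <- fit_interval_regression(obs)
  doubled <- dplyr::bind_rows(obs, obs)
  attr(doubled, "scale") <- "logit"
  f2 <- fit_interval_regression(doubled)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("noise-free responses land every estimate in its threshold bracket", {
  thresholds <- c(0.1, 0.2, 1 / 3, 0.5, 2 / 3)
  dws <- c(0.15, 0.28, 0.42, 0.6)
  phe <- dplyr::bind_rows(lapply(seq_along(dws), function(k) {
    m <- rep(c(1500, 2000, 3000, 5000, 10000), each = 20)
    tibble::tibble(respondent_id = sprintf("s%d-%03d", k, seq_along(m)),
                   state = k, multiplier = m,
                   choice = simulate_phe_choice(dws[k], m, 0))
  }))
  fit <- fit_interval_regression(phe_to_interval(phe))
  est <- phe_dw_estimates(fit)
  for (k in seq_along(dws)) {
    lo <- max(thresholds[thresholds < dws[k]])
    hi <- min(thresholds[thresholds > dws[k]])
    expect_gt(est$dw_phe[est$state_id == k], lo)
    expect_lt(est$dw_phe[est$state_id == k], hi)
  }
})

test_that("anchor-state weights are recovered across simulation replicates", {
  # median |DW_hat - DW*| <= 0.03 at 500 responses per state
  dws <- c(0.15, 0.3, 0.55)
  errs <- vapply(1:50, function(rep) {
    set.seed(1000 + rep)
    phe <- dplyr::bind_rows(lapply(seq_along(dws), function(k) {
      m <- sample(c(1500, 2000, 3000, 5000, 10000), 500, replace = TRUE)
      tibble::tibble(respondent_id = sprintf("x%d-%03d", k, seq_along(m)),
                     state = k, multiplier = m,
                     choice = simulate_phe_choice(rep(dws[k], 500), m, 0.5))
    }))
    fit <- suppressWarnings(fit_interval_regression(phe_to_interval(phe)))
    est <- phe_dw_estimates(fit)
    max(abs(est$dw_phe[match(seq_along(dws), est$state_id)] - dws))
  }, numeric(1))
  expect_lte(median(errs), 0.03)
})
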