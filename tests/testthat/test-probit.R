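test_that("the design encodes +1/-1/0 with outcome 1 for a first-state win", {
  cat3 <- tiny_catalog(3)
  pc <- pc_from_counts(list(c(1, 3, 1, 0), c(1, 3, 0, 1)))
  design <- build_pc_design(pc, cat3)
  dm <- pc_design_matrix(design)
  expect_equal(unname(dm$X[1, ]), c(1, 0, -1))
  expect_equal(unname(dm$X[2, ]), c(1, 0, -1))
  expect_equal(dm$y, c(1, 0))
  expect_true(all(rowSums(dm$X) == 0))
  expect_true(all(rowSums(dm$X == 1) == 1 & rowSums(dm$X == -1) == 1))

  expect_error(
    build_pc_design(pc_from_counts(list(c(2, 2, 1, 0))), cat3),
    "with itself")

  # responses touching non-estimable states are dropped with a warning
  cat3b <- cat3
  cat3b$dw_available[3] <- FALSE
  expect_warning(d2 <- build_pc_design(pc, cat3b), "excluded")
  expect_equal(d2$n_responses, 0)
  expect_equal(d2$n_excluded, 2)
})

test_that("the likelihood matches closed forms and is order-invariant", {
  cat3 <- tiny_catalog(3)
  pc <- pc_from_counts(list(c(1, 2, 3, 2), c(2, 3, 1, 1), c(1, 3, 2, 1)))
  design <- build_pc_design(pc, cat3)
  beta0 <- c(`1` = 0, `2` = 0, `3` = 0)
  expect_equal(probit_loglik(beta0, design), 10 * log(0.5))

  one <- build_pc_design(pc_from_counts(list(c(1, 2, 1, 0))), cat3)
  b <- c(`1` = qnorm(0.95) / 2, `2` = -qnorm(0.95) / 2, `3` = 0)
  expect_equal(probit_loglik(b, one), log(0.95))

  shuf <- design
  perm <- sample(nrow(shuf$responses))
  shuf$responses <- shuf$responses[perm, ]
  bb <- c(`1` = 0.3, `2` = -0.1, `3` = -0.2)
  expect_equal(probit_loglik(bb, shuf), probit_loglik(bb, design))
})

test_that("symmetric data give zero indices and even win probabilities", {
  cat2 <- tiny_catalog(2)
  pc <- pc_from_counts(list(c(1, 2, 50, 50)))
  fit <- fit_pc_probit(build_pc_design(pc, cat2))
  expect_equal(unname(fit$beta), c(0, 0), tolerance = 1e-8)
  expect_equal(predicted_probability(fit, 1)$prob, 0.5, tolerance = 1e-8)
})

test_that("the MLE matches a brute-force grid over the free parameters", {
  cat3 <- tiny_catalog(3)
  pc <- pc_from_counts(list(c(1, 2, 90, 10), c(2, 3, 90, 10),
                            c(1, 3, 98, 2)))
  design <- build_pc_design(pc, cat3)
  fit <- fit_pc_probit(design, penalty = 1e-6)

  # independent oracle: two-stage grid maximisation of the same penalised
  # likelihood over (beta1, beta2), beta3 = -beta1 - beta2, final
  # resolution 1e-3
  grid_ll <- function(b1, b2) {
    e12 <- b1 - b2
    e23 <- 2 * b2 + b1
    e13 <- 2 * b1 + b2
    90 * pnorm(e12, log.p = TRUE) + 10 * pnorm(-e12, log.p = TRUE) +
      90 * pnorm(e23, log.p = TRUE) + 10 * pnorm(-e23, log.p = TRUE) +
      98 * pnorm(e13, log.p = TRUE) + 2 * pnorm(-e13, log.p = TRUE) -
      1e-6 * (b1^2 + b2^2 + (b1 + b2)^2)
  }
  centre <- c(0, 0)
  for (step in c(0.05, 0.005, 1e-3)) {
    g1 <- seq(centre[1] - 40 * step, centre[1] + 40 * step, by = step)
    g2 <- seq(centre[2] - 40 * step, centre[2] + 40 * step, by = step)
    ll <- outer(g1, g2, grid_ll)
    ix <- arrayInd(which.max(ll), dim(ll))
    centre <- c(g1[ix[1]], g2[ix[2]])
  }
  expect_equal(unname(fit$beta[1:2]), centre, tolerance = 1.5e-3)
  expect_equal(sum(fit$beta), 0, tolerance = 1e-10)
})

test_that("the fit agrees with a probit GLM under a reference constraint", {
  cat4 <- tiny_catalog(4)
  pc <- pc_from_counts(list(c(1, 2, 60, 40), c(2, 3, 70, 30),
                            c(3, 4, 55, 45), c(1, 4, 85, 15),
                            c(2, 4, 75, 25), c(1, 3, 80, 20)))
  design <- build_pc_design(pc, cat4)
  fit <- fit_pc_probit(design, penalty = 0, constraint = "reference")

  dm <- pc_design_matrix(design)
  glm_fit <- stats::glm(dm$y ~ dm$X[, -1] - 1,
                        family = binomial(link = "probit"))
  expect_equal(unname(fit$beta[-1]), unname(coef(glm_fit)),
               tolerance = 1e-5)
  # standard errors agree with the GLM information matrix (observed vs
  # expected information differ slightly at finite samples)
  se_glm <- sqrt(diag(vcov(glm_fit)))
  expect_equal(sqrt(diag(fit$vcov))[-1], se_glm, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("relabelling first/second with flipped outcomes leaves the fit unchanged", {
  cat3 <- tiny_catalog(3)
  pc <- pc_from_counts(list(c(1, 2, 70, 30), c(2, 3, 60, 40),
                            c(1, 3, 80, 20)))
  flipped <- dplyr::mutate(pc,
                           tmp = first_state,
                           first_state = second_state,
                           second_state = tmp,
                           choice = ifelse(choice == "first", "second",
                                           "first"))
  f1 <- fit_pc_probit(build_pc_design(pc, cat3))
  f2 <- fit_pc_probit(build_pc_design(flipped[names(pc)], cat3))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("separation is warned and penalised to a finite estimate", {
  cat3 <- tiny_catalog(3)
  pc <- pc_from_counts(list(c(1, 2, 20, 0), c(1, 3, 20, 0),
                            c(2, 3, 12, 8)))
  expect_warning(fit <- fit_pc_probit(build_pc_design(pc, cat3)),
                 "separation.*1")
  expect_true(all(is.finite(fit$beta)))
  expect_identical(fit$separated_states, 1L)
})

test_that("estimates sharpen as the response count grows tenfold", {
  cat5 <- tiny_catalog(5)
  beta_star <- c(0.8, 0.3, 0, -0.3, -0.8)
  sim <- function(n_per_pair, seed) {
    pairs <- utils::combn(5, 2)
    set.seed(seed)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      wins <- rbinom(1, n_per_pair, pnorm(beta_star[i] - beta_star[j]))
      c(i, j, wins, n_per_pair - wins)
    })
    fit <- fit_pc_probit(build_pc_design(pc_from_counts(rows), cat5))
    sqrt(mean((fit$beta - beta_star)^2))
  }
  rmse_small <- mean(vapply(1:3, function(s) sim(40, s), numeric(1)))
  rmse_large <- mean(vapply(1:3, function(s) sim(400, s + 10), numeric(1)))
  expect_lt(rmse_large, rmse_small)
})
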