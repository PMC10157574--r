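#' Sample a synthetic ground-truth set of disability weights
#'
#' Draws one true disability weight per `dw_available` state from a
#' right-skewed law on (0, 1) (default Beta(1.2, 6), calibrated so most
#' mass lies below DW 0.4, matching the skew observed in valuation
#' surveys), and fixes the generative constants that tie the DW scale to
#' the latent healthiness scale.
#'
#' The generative model is `logit(dw) = a + b * h` with healthiness index
#' `h`: healthier states (larger `h`) have smaller weights, so `b < 0`.
#'
#' @param catalog A `dw_catalog`.
#' @param shape1,shape2 Beta parameters of the truth distribution.
#' @param constant If non-`NULL`, every state gets this DW (degenerate
#'   point-mass spec, mainly for tests).
#' @param anchor_intercept,anchor_slope Constants `a`, `b` of the latent
#'   map; the defaults give a median paired-comparison choice accuracy of
#'   about 0.75 under the Beta(1.2, 6) truth.
#' @param phe_noise_sd Log-scale SD of the multiplicative perception noise
#'   in the PHE choice rule.
#' @param seed Integer seed.
#' @return List of class `dw_truth`: `true_dw` tibble (`state_id`,
#'   `true_dw`), the anchor constants, `phe_noise_sd`, `seed`.
#' @export
sample_true_dws <- function(catalog, shape1 = 1.2, shape2 = 6,
                            constant = NULL,
                            anchor_intercept = -2, anchor_slope = -1.6,
                            phe_noise_sd = 0.5, seed = 1L) {
  if (anchor_slope == 0) abort("anchor_slope must be non-zero")
  states <- catalog$state_id[catalog$dw_available]
  if (is.null(constant)) {
    if (shape1 <= 0 || shape2 <= 0) abort("Beta shapes must be positive")
    dw <- with_seed(derive_seed(seed, "sample_true_dws"),
                    stats::rbeta(length(states), shape1, shape2))
  } else {
    if (constant <= 0 || constant >= 1) abort("constant must lie in (0, 1)")
    dw <- rep(constant, length(states))
  }
  structure(list(true_dw = tibble(state_id = states, true_dw = dw),
                 anchor_intercept = anchor_intercept,
                 anchor_slope = anchor_slope,
                 phe_noise_sd = phe_noise_sd,
                 seed = as.integer(seed)),
            class = "dw_truth")
}

#' Latent healthiness index of a state under a truth set
#'
#' The exact generative inverse of the anchoring map:
#' `h = (logit(dw) - a) / b`. Strictly decreasing in the true DW.
#'
#' @param truth A `dw_truth`.
#' @param state_id State ID(s); default all states in the truth set.
#' @return Named numeric vector of healthiness indices.
#' @export
latent_health_index <- function(truth, state_id = NULL) {
  tab <- truth$true_dw
  if (!is.null(state_id)) {
    idx <- match(state_id, tab$state_id)
    if (anyNA(idx)) abort("state_id not in truth set")
    tab <- tab[idx, ]
  }
  h <- (logit(tab$true_dw) - truth$anchor_intercept) / truth$anchor_slope
  stats::setNames(h, tab$state_id)
}

#' Simulate one batch of paired-comparison choices
#'
#' Chooses `"first"` with probability `pnorm(h_first - h_second)` — the
#' same Thurstonian probit law the estimation model assumes. Uses the
#' current RNG stream; seed at the call site.
#'
#' @param h_first,h_second Latent healthiness indices (vectorised).
#' @return Character vector of `"first"`/`"second"`.
#' @export
simulate_pc_choice <- function(h_first, h_second) {
  p <- stats::pnorm(h_first - h_second)
  ifelse(stats::runif(length(p)) < p, "first", "second")
}

#' Simulate population-health-equivalence choices
#'
#' A respondent perceives the nonfatal program's benefit as
#' `M * dw * exp(e)` health-years with `e ~ Normal(0, phe_noise_sd^2)`
#' (multiplicative log-normal perception noise) and picks it over the
#' 1000-rapid-deaths program when the perceived benefit exceeds 1000, so
#' `P(nonfatal) = pnorm((log(dw) - log(1000/M)) / phe_noise_sd)`. With
#' `phe_noise_sd = 0` the rule is the deterministic threshold
#' `dw > 1000/M`; exact indifference resolves to `"fatal_program"`.
#'
#' @param true_dw True disability weight(s) in (0, 1).
#' @param multiplier PHE multiplier(s) M.
#' @param phe_noise_sd Log-scale perception noise SD (>= 0).
#' @return Character vector of `"fatal_program"`/`"nonfatal_program"`.
#' @export
simulate_phe_choice <- function(true_dw, multiplier, phe_noise_sd = 0.5) {
  threshold <- 1000 / multiplier
  if (phe_noise_sd == 0) {
    return(ifelse(true_dw > threshold, "nonfatal_program", "fatal_program"))
  }
  p_nonfatal <- stats::pnorm((log(true_dw) - log(threshold)) / phe_noise_sd)
  ifelse(stats::runif(length(p_nonfatal)) < p_nonfatal,
         "nonfatal_program", "fatal_program")
}

inject_pattern <- function(n, rule) {
  switch(rule,
    "all-A" = rep("first", n),
    "all-B" = rep("second", n),
    "alternation" = rep(c("first", "second"), length.out = n))
}

#' Generate a full synthetic survey cohort
#'
#' Simulates respondents (household + web), their paired-comparison
#' responses from the latent probit law, and web respondents' PHE
#' responses from the noisy threshold rule, using the survey engine's
#' assignment mechanics. Completion times are drawn above the QC
#' threshold; an optional fraction of respondents is made deliberately
#' invalid (short completion, straightlining or alternation) to exercise
#' the QC filter, and those injections are reported.
#'
#' @param catalog A `dw_catalog`.
#' @param truth A `dw_truth` from [sample_true_dws()].
#' @param n_household,n_web Cohort sizes (survey defaults 2610 and 3140).
#' @param config A [survey_config()]; its seed drives all draws.
#' @param invalid_fraction Fraction of respondents to corrupt (default 0).
#' @return List of class `dw_cohort`: `respondents`, `pc_responses`,
#'   `phe_responses`, `injected` (tibble `respondent_id`, `rule`), `truth`.
#' @export
generate_cohort <- function(catalog, truth, n_household = 2610L,
                            n_web = 3140L, config = survey_config(),
                            invalid_fraction = 0) {
  n <- n_household + n_web
  ids <- sprintf("R%06d", seq_len(n))
  mode <- c(rep("household", n_household), rep("web", n_web))

  respondents <- with_seed(derive_seed(config$seed, "respondents"), {
    secs <- pmax(round(stats::rlnorm(n, log(540), 0.4)),
                 config$min_completion_seconds + 1)
    tibble(
      respondent_id = ids, mode = mode, completion_seconds = secs,
      age = sample(18:70, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      education = sample(c("primary", "secondary", "tertiary"), n,
                         replace = TRUE, prob = c(0.2, 0.45, 0.35)),
      occupation = sample(c("employed", "student", "retired", "other"), n,
                          replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15)))
  })

  pc <- assign_pc_pairs(catalog, n, config, respondent_ids = ids)
  h <- latent_health_index(truth)
  pc$choice <- with_seed(derive_seed(config$seed, "pc_choices"), {
    simulate_pc_choice(h[as.character(pc$first_state)],
                       h[as.character(pc$second_state)])
  })
  # repeated positions are re-asked, not copied: redraw their choices
  rep_later <- pc$question_index %in%
    config$repeated_positions[-1L]
  pc$choice[rep_later] <- with_seed(derive_seed(config$seed, "pc_repeats"), {
    simulate_pc_choice(h[as.character(pc$first_state[rep_later])],
                       h[as.character(pc$second_state[rep_later])])
  })

  phe <- assign_phe_questions(catalog, respondents, config)
  dw_of <- stats::setNames(truth$true_dw$true_dw,
                           truth$true_dw$state_id)
  phe$choice <- with_seed(derive_seed(config$seed, "phe_choices"), {
    simulate_phe_choice(dw_of[as.character(phe$state)], phe$multiplier,
                        truth$phe_noise_sd)
  })

  injected <- tibble(respondent_id = character(), rule = character())
  if (invalid_fraction > 0) {
    injected <- with_seed(derive_seed(config$seed, "inject_invalid"), {
      bad_ids <- sample(ids, round(invalid_fraction * n))
      rules <- purrr::map_chr(bad_ids, function(id) {
        opts <- c("all-A", "all-B", "alternation",
                  if (mode[match(id, ids)] == "web") "min-time")
        sample(opts, 1L)
      })
      for (k in seq_along(bad_ids)) {
        if (rules[k] == "min-time") {
          respondents$completion_seconds[
            respondents$respondent_id == bad_ids[k]] <-
            sample(30:(config$min_completion_seconds - 1), 1L)
        } else {
          rows <- pc$respondent_id == bad_ids[k]
          pc$choice[rows][order(pc$question_index[rows])] <-
            inject_pattern(sum(rows), rules[k])
        }
      }
      tibble(respondent_id = bad_ids, rule = rules)
    })
  }

  structure(list(respondents = respondents, pc_responses = pc,
                 phe_responses = phe, injected = injected, truth = truth),
            class = "dw_cohort")
}

#' Construct a reduced synthetic study universe
#'
#' A small catalog-plus-truth pair for end-to-end simulation studies: the
#' first `n_states` health states of the packaged catalog, all estimable,
#' with `n_anchors` population-health-equivalence anchor states marked at
#' evenly spaced severity quantiles — emulating the purposive anchor
#' selection of the real design, where the anchor subset spans mild to
#' severe states. Anchors whose true weight falls outside the
#' instrument's measurable threshold band `[0.1, 2/3]` yield one-sided
#' equivalence data and exercise the boundary handling downstream.
#'
#' @param n_states Universe size (default 30).
#' @param n_anchors Number of PHE anchor states (default 10).
#' @param seed Integer seed (drives the truth draw).
#' @param ... Passed to [sample_true_dws()] (noise and scale constants).
#' @return List: `catalog` (a `dw_catalog`), `truth` (a `dw_truth`).
#' @export
example_universe <- function(n_states = 30L, n_anchors = 10L, seed = 1L,
                             ...) {
  catalog <- example_catalog()[seq_len(n_states), ]
  catalog$dw_available <- TRUE
  catalog$is_phe_anchor <- FALSE
  truth <- sample_true_dws(catalog, seed = seed, ...)
  ord <- order(truth$true_dw$true_dw)
  ranks <- unique(round(seq(1, n_states, length.out = n_anchors)))
  anchor_ids <- truth$true_dw$state_id[ord][ranks]
  catalog$is_phe_anchor <- catalog$state_id %in% anchor_ids
  list(catalog = catalog, truth = truth)
}
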