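test_that("pair assignment balances selections and repeats the retest pair", {
  cat10 <- tiny_catalog(10)
  cfg <- survey_config(seed = 3)
  asg <- assign_pc_pairs(cat10, 40, cfg)
  expect_equal(nrow(asg), 40 * 16)
  expect_true(all(asg$first_state != asg$second_state))

  # repeated positions carry the identical ordered pair per respondent
  reps <- dplyr::filter(asg, question_index %in% c(3, 10, 16))
  per <- dplyr::summarise(reps,
                          one = dplyr::n_distinct(paste(first_state,
                                                        second_state)),
                          .by = respondent_id)
  expect_true(all(per$one == 1))

  # fresh draws (position 3 counts once) have selection spread <= 1 and,
  # with 560 draws over 45 pairs, cover every unordered pair
  fresh <- dplyr::filter(asg, !(question_index %in% c(10, 16)))
  key <- paste(pmin(fresh$first_state, fresh$second_state),
               pmax(fresh$first_state, fresh$second_state))
  counts <- table(factor(key, levels = {
    p <- utils::combn(1:10, 2)
    paste(p[1, ], p[2, ])
  }))
  expect_equal(length(counts), 45)
  expect_true(min(counts) >= 1)
  expect_lte(max(counts) - min(counts), 1)

  # determinism
  expect_identical(asg, assign_pc_pairs(cat10, 40, cfg))
})

test_that("three states, one respondent, three questions use each pair once", {
  cat3 <- tiny_catalog(3)
  cfg <- survey_config(n_pc_questions = 3, repeated_positions = integer(0),
                       seed = 1)
  asg <- assign_pc_pairs(cat3, 1, cfg)
  key <- paste(pmin(asg$first_state, asg$second_state),
               pmax(asg$first_state, asg$second_state))
  expect_equal(sort(key), c("1 2", "1 3", "2 3"))
  expect_error(assign_pc_pairs(tiny_catalog(1), 1, cfg), ">= 2")
})

test_that("PHE assignment is web-only, state-balanced, multiplier-uniform", {
  cat28 <- tiny_catalog(30, anchors = 1:28)
  cfg <- survey_config(seed = 9)
  respondents <- tibble::tibble(
    respondent_id = sprintf("R%04d", 1:3200),
    mode = c(rep("household", 60), rep("web", 3140)))
  slots <- assign_phe_questions(cat28, respondents, cfg)
  expect_equal(nrow(slots), 3140 * 3)
  expect_false(any(slots$respondent_id %in% respondents$respondent_id[1:60]))

  per_state <- table(slots$state)
  expect_equal(length(per_state), 28)
  expect_true(all(per_state %in% c(336, 337)))  # 9420 / 28

  # multiplier frequencies within 3 binomial SE of 1/5
  p_hat <- as.vector(table(slots$multiplier)) / nrow(slots)
  se <- sqrt(0.2 * 0.8 / nrow(slots))
  expect_true(all(abs(p_hat - 0.2) < 3 * se))

  expect_error(assign_phe_questions(tiny_catalog(5), respondents, cfg),
               "no PHE anchor")
})

test_that("qc_filter applies every exclusion rule and is idempotent", {
  cfg <- survey_config()
  mixed <- c(rep(c("first", "second"), 7), "second", "first")  # one break
  pc <- dplyr::bind_rows(
    pc_block("ok-hh", mixed),
    pc_block("ok-web", mixed),
    pc_block("allA", rep("first", 16)),
    pc_block("allB", rep("second", 16)),
    pc_block("alt1", rep(c("first", "second"), 8)),
    pc_block("alt2", rep(c("second", "first"), 8)),
    pc_block("slow-web", mixed),
    pc_block("slow-hh", mixed),
    pc_block("short", mixed[1:10]),
    pc_block("dup", mixed))
  resp <- tibble::tibble(
    respondent_id = c("ok-hh", "ok-web", "allA", "allB", "alt1", "alt2",
                      "slow-web", "slow-hh", "short", "dup", "dup"),
    mode = c("household", "web", "web", "web", "web", "web", "web",
             "household", "web", "web", "web"),
    completion_seconds = c(400, 400, 400, 400, 400, 400, 150, 150, 400,
                           400, 400))

  qc <- qc_filter(resp, pc, cfg)
  rules <- tibble::deframe(qc$exclusions)
  expect_setequal(qc$respondents$respondent_id,
                  c("ok-hh", "ok-web", "slow-hh", "dup"))
  expect_equal(rules[["allA"]], "all-A")
  expect_equal(rules[["allB"]], "all-B")
  expect_equal(rules[["alt1"]], "alternation")
  expect_equal(rules[["alt2"]], "alternation")
  expect_equal(rules[["slow-web"]], "min-time")
  expect_equal(rules[["short"]], "incomplete")
  expect_equal(unname(rules[names(rules) == "dup"]), "duplicate")

  # a household respondent under the time floor is retained
  expect_true("slow-hh" %in% qc$respondents$respondent_id)

  # idempotence: filtering the retained set excludes nobody
  qc2 <- qc_filter(qc$respondents, qc$pc_responses, cfg)
  expect_equal(nrow(qc2$exclusions), 0)
  expect_equal(qc2$respondents, qc$respondents)
})

test_that("test-retest consistency follows its definition", {
  cfg <- survey_config()
  mk <- function(id, c3, c10, c16) {
    ch <- rep("first", 16)
    ch[c(3, 10, 16)] <- c(c3, c10, c16)
    pc_block(id, ch)
  }
  out <- test_retest_consistency(
    dplyr::bind_rows(mk("a", "first", "first", "first"),
                     mk("b", "first", "second", "first"),
                     mk("b2", "first", "second", "second")),
    cfg)
  per <- tibble::deframe(out$per_respondent)
  expect_equal(per[["a"]], 1.0)   # all three showings agree
  expect_equal(per[["b"]], 0.5)   # one of two later showings agrees
  expect_equal(per[["b2"]], 0.0)  # both later showings flipped
  expect_equal(out$aggregate, 0.5)

  # agreement is on the chosen state, not the button: flipped presentation
  flip <- pc_block("c", rep("first", 16))
  flip[flip$question_index == 10, c("first_state", "second_state")] <-
    list(2L, 1L)
  flip$choice[flip$question_index == 10] <- "second"  # same state chosen
  expect_equal(test_retest_consistency(flip, cfg)$aggregate, 1.0)

  # repeated positions holding different pairs is a data error
  broken <- pc_block("d", rep("first", 16))
  broken[broken$question_index == 16, c("first_state", "second_state")] <-
    list(3L, 4L)
  expect_error(test_retest_consistency(broken, cfg), "different pairs")
})

test_that("aggregate consistency matches the binomial prediction", {
  # choices at the repeated pair drawn iid with P(first) = 0.8:
  # P(agree with the first showing) = 0.8^2 + 0.2^2 = 0.68
  n <- 4000
  set.seed(421)
  draws <- matrix(sample(c("first", "second"), n * 3, replace = TRUE,
                         prob = c(0.8, 0.2)), ncol = 3)
  pc <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    ch <- rep("first", 16)
    ch[c(3, 10, 16)] <- draws[i, ]
    pc_block(sprintf("R%05d", i), ch)
  }))
  agg <- test_retest_consistency(pc, survey_config())$aggregate
  se <- sqrt(0.35^2 / n)  # conservative bound on SD of the mean
  expect_lt(abs(agg - 0.68), 3 * se + 0.01)
})
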