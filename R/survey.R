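#' Survey design configuration
#'
#' Bundles the design constants of the valuation survey: 16 paired-comparison
#' (PC) questions per respondent with one pair repeated at positions 3, 10
#' and 16 for test-retest assessment; 3 population-health-equivalence (PHE)
#' questions per web respondent with multipliers drawn from
#' \{1500, 2000, 3000, 5000, 10000\}; and a 3-minute minimum completion time
#' for web respondents.
#'
#' @param n_pc_questions Number of PC questions per respondent.
#' @param repeated_positions Question indices that all show the same pair
#'   (at least 2, within `1..n_pc_questions`).
#' @param n_phe_questions PHE questions per web respondent.
#' @param min_completion_seconds Web-mode quality-control threshold (s).
#' @param multipliers Candidate PHE multipliers M (the second program averts
#'   M nonfatal lifelong cases against 1000 rapid deaths).
#' @param seed Integer seed from which all randomised survey mechanics
#'   derive their streams.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(n_pc_questions = 16L,
                          repeated_positions = c(3L, 10L, 16L),
                          n_phe_questions = 3L,
                          min_completion_seconds = 180,
                          multipliers = c(1500, 2000, 3000, 5000, 10000),
                          seed = 1L) {
  repeated_positions <- sort(as.integer(repeated_positions))
  if (length(repeated_positions) == 1 ||
      any(repeated_positions < 1 | repeated_positions > n_pc_questions)) {
    abort(paste0("repeated_positions must be >= 2 indices within ",
                 "1..n_pc_questions (or empty for no repeated pair)"))
  }
  structure(list(n_pc_questions = as.integer(n_pc_questions),
                 repeated_positions = repeated_positions,
                 n_phe_questions = as.integer(n_phe_questions),
                 min_completion_seconds = min_completion_seconds,
                 multipliers = multipliers,
                 seed = as.integer(seed)),
            class = "survey_config")
}

# Minimum-selection balanced draws: drawing uniformly among the items with
# the current minimum selection count is equivalent to dealing from a
# shuffled deck and reshuffling on exhaustion, which guarantees a max-min
# count spread of at most 1 at any point.
balanced_draws <- function(n_items, n_draws) {
  rounds <- ceiling(n_draws / n_items)
  idx <- unlist(lapply(seq_len(rounds), function(i) sample.int(n_items)))
  idx[seq_len(n_draws)]
}

#' Assign paired-comparison questions
#'
#' Gives each respondent `n_pc_questions` ordered health-state pairs. Fresh
#' pairs are drawn uniformly from the unordered pairs with the current
#' minimum selection count (so the global spread of selection counts among
#' fresh draws never exceeds 1), and each is shown in a random presentation
#' order. The pair first drawn at the earliest repeated position is repeated
#' verbatim (same order) at the remaining repeated positions.
#'
#' @param catalog A `dw_catalog` with at least 2 `dw_available` states.
#' @param n_respondents Number of respondents to assign.
#' @param config A [survey_config()].
#' @param respondent_ids Optional character vector of IDs (defaults to
#'   `"R000001"...`).
#' @return Tibble `respondent_id`, `question_index`, `first_state`,
#'   `second_state`.
#' @export
assign_pc_pairs <- function(catalog, n_respondents, config = survey_config(),
                            respondent_ids = NULL) {
  states <- catalog$state_id[catalog$dw_available]
  if (length(states) < 2) abort("catalog must contain >= 2 dw_available states")
  if (n_respondents < 1) abort("n_respondents must be >= 1")
  if (is.null(respondent_ids)) {
    respondent_ids <- sprintf("R%06d", seq_len(n_respondents))
  }
  stopifnot(length(respondent_ids) == n_respondents)

  n_q <- config$n_pc_questions
  rep_pos <- config$repeated_positions
  n_fresh <- n_q - max(length(rep_pos) - 1L, 0L)  # fresh draws per respondent
  pairs <- utils::combn(states, 2L)        # unordered universe, 2 x P
  n_pairs <- ncol(pairs)

  with_seed(derive_seed(config$seed, "assign_pc_pairs"), {
    draw <- balanced_draws(n_pairs, n_respondents * n_fresh)
    flip <- stats::runif(length(draw)) < 0.5
    a <- ifelse(flip, pairs[2L, draw], pairs[1L, draw])
    b <- ifelse(flip, pairs[1L, draw], pairs[2L, draw])
  })

  # lay out fresh draws on the non-repeat positions (plus the first repeat
  # position), then copy that pair to the later repeat positions
  fresh_pos <- sort(unique(c(setdiff(seq_len(n_q), rep_pos), rep_pos[1L])))
  resp <- rep(respondent_ids, each = n_fresh)
  qidx <- rep(fresh_pos, times = n_respondents)
  out <- tibble(respondent_id = resp, question_index = qidx,
                first_state = as.integer(a), second_state = as.integer(b))
  if (length(rep_pos) > 0) {
    anchor_rows <- out[out$question_index == rep_pos[1L], ]
    copies <- lapply(rep_pos[-1L], function(p) {
      dplyr::mutate(anchor_rows, question_index = p)
    })
    out <- dplyr::bind_rows(out, copies)
  }
  dplyr::arrange(out, match(.data$respondent_id, respondent_ids),
                 .data$question_index)
}

#' Assign population-health-equivalence questions
#'
#' Gives each web-mode respondent `n_phe_questions` anchor-state slots,
#' balancing states over the anchor subset by the same minimum-selection
#' rule as [assign_pc_pairs()]; multipliers are drawn uniformly from the
#' configured set. Household respondents receive no PHE questions.
#'
#' @param catalog A `dw_catalog` with a non-empty anchor subset.
#' @param respondents Tibble with `respondent_id` and `mode`.
#' @param config A [survey_config()].
#' @return Tibble `respondent_id`, `state`, `multiplier`.
#' @export
assign_phe_questions <- function(catalog, respondents,
                                 config = survey_config()) {
  anchors <- catalog$state_id[catalog$is_phe_anchor & catalog$dw_available]
  if (length(anchors) == 0) abort("catalog has no PHE anchor states")
  web <- respondents$respondent_id[respondents$mode == "web"]
  n_slots <- length(web) * config$n_phe_questions
  if (n_slots == 0) {
    return(tibble(respondent_id = character(), state = integer(),
                  multiplier = numeric()))
  }
  with_seed(derive_seed(config$seed, "assign_phe_questions"), {
    st <- anchors[balanced_draws(length(anchors), n_slots)]
    mult <- sample(config$multipliers, n_slots, replace = TRUE)
  })
  tibble(respondent_id = rep(web, each = config$n_phe_questions),
         state = as.integer(st), multiplier = mult)
}

choice_pattern <- function(choices) {
  n <- length(choices)
  if (all(choices == "first")) return("all-A")
  if (all(choices == "second")) return("all-B")
  x <- choices == "first"
  if (all(x == rep(c(TRUE, FALSE), length.out = n)) ||
      all(x == rep(c(FALSE, TRUE), length.out = n))) {
    return("alternation")
  }
  NA_character_
}

#' Quality-control filter for survey respondents
#'
#' Applies the survey's data-quality rules before analysis: (1) a
#' respondent ID may appear once only (later duplicates dropped), (2) web
#' respondents must have spent at least `min_completion_seconds`
#' (household interviews are interviewer-administered and exempt), (3)
#' respondents whose PC choices are all first, all second, or a strict
#' alternation over the whole sequence are excluded, and respondents
#' without a complete set of PC answers are excluded as incomplete.
#'
#' @param respondents Tibble with `respondent_id`, `mode`,
#'   `completion_seconds`.
#' @param pc_responses Tibble with `respondent_id`, `question_index`,
#'   `first_state`, `second_state`, `choice` (`"first"`/`"second"`).
#' @param config A [survey_config()].
#' @return List of class `dw_qc`: `respondents` (retained), `pc_responses`
#'   (restricted to retained respondents), and `exclusions`
#'   (`respondent_id`, `rule` in `duplicate`, `incomplete`, `min-time`,
#'   `all-A`, `all-B`, `alternation`).
#' @export
qc_filter <- function(respondents, pc_responses, config = survey_config()) {
  excl <- list()
  resp <- as_tibble(respondents)

  dup <- resp$respondent_id[duplicated(resp$respondent_id)]
  if (length(dup) > 0) {
    excl$dup <- tibble(respondent_id = unique(dup), rule = "duplicate")
    resp <- resp[!duplicated(resp$respondent_id), ]
  }

  counts <- dplyr::count(pc_responses, .data$respondent_id)
  complete_ids <- counts$respondent_id[counts$n == config$n_pc_questions]
  inc <- setdiff(resp$respondent_id, complete_ids)
  if (length(inc) > 0) {
    excl$inc <- tibble(respondent_id = inc, rule = "incomplete")
    resp <- resp[resp$respondent_id %in% complete_ids, ]
  }

  slow <- resp$mode == "web" &
    resp$completion_seconds < config$min_completion_seconds
  if (any(slow)) {
    excl$time <- tibble(respondent_id = resp$respondent_id[slow],
                        rule = "min-time")
    resp <- resp[!slow, ]
  }

  pat <- pc_responses |>
    dplyr::filter(.data$respondent_id %in% resp$respondent_id) |>
    dplyr::arrange(.data$respondent_id, .data$question_index) |>
    dplyr::summarise(rule = choice_pattern(.data$choice),
                     .by = "respondent_id") |>
    dplyr::filter(!is.na(.data$rule))
  if (nrow(pat) > 0) {
    excl$pat <- pat
    resp <- resp[!(resp$respondent_id %in% pat$respondent_id), ]
  }

  exclusions <- dplyr::bind_rows(excl)
  if (nrow(exclusions) == 0) {
    exclusions <- tibble(respondent_id = character(), rule = character())
  }
  structure(list(
    respondents = resp,
    pc_responses = dplyr::filter(pc_responses,
                                 .data$respondent_id %in% resp$respondent_id),
    exclusions = exclusions
  ), class = "dw_qc")
}

#' Test-retest consistency of the repeated paired comparison
#'
#' The repeated positions of the PC sequence show the same pair; per
#' respondent this computes the fraction of later showings whose chosen
#' state agrees with the choice at the first repeated position (agreement
#' is on the state chosen, so presentation order does not matter).
#' Returned as a diagnostic; it is not a QC filter.
#'
#' @param pc_responses PC response tibble (see [qc_filter()]).
#' @param config A [survey_config()].
#' @return List of class `dw_retest`: `per_respondent` tibble
#'   (`respondent_id`, `consistency`) and `aggregate` (mean consistency).
#' @export
test_retest_consistency <- function(pc_responses, config = survey_config()) {
  rep_pos <- config$repeated_positions
  rep_rows <- pc_responses |>
    dplyr::filter(.data$question_index %in% rep_pos) |>
    dplyr::arrange(.data$respondent_id, .data$question_index)
  per <- rep_rows |>
    dplyr::summarise(consistency = {
      pair_key <- paste(pmin(.data$first_state, .data$second_state),
                        pmax(.data$first_state, .data$second_state))
      if (length(unique(pair_key)) != 1) {
        abort("repeated positions hold different pairs for a respondent")
      }
      chosen <- ifelse(.data$choice == "first",
                       .data$first_state, .data$second_state)
      mean(chosen[-1L] == chosen[1L])
    }, .by = "respondent_id")
  structure(list(per_respondent = per, aggregate = mean(per$consistency)),
            class = "dw_retest")
}
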