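# Small in-code fixtures shared across test files.

# minimal catalog of n states with deterministic flags; anchors optional
tiny_catalog <- function(n = 6, anchors = integer(0)) {
  flags <- withr::with_seed(1234 + n, {
    matrix(stats::runif(n * 11) < 0.35, n, 11,
           dimnames = list(NULL, paste0("flag_", symptom_categories())))
  })
  as_dw_catalog(tibble::tibble(
    state_id = seq_len(n),
    label = paste("state", seq_len(n)),
    lay_description = paste("description of state", seq_len(n)),
    tibble::as_tibble(flags),
    is_phe_anchor = seq_len(n) %in% anchors,
    dw_available = TRUE
  ))
}

# PC responses from explicit win counts: beats[[k]] = c(first, second,
# wins_first, losses_first)
pc_from_counts <- function(counts) {
  rows <- lapply(counts, function(ct) {
    tibble::tibble(
      first_state = ct[1], second_state = ct[2],
      choice = rep(c("first", "second"), times = ct[3:4])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$respondent_id <- sprintf("R%04d", seq_len(nrow(out)))
  out$question_index <- 1L
  out[, c("respondent_id", "question_index", "first_state", "second_state",
          "choice")]
}

# PHE responses for one state with given multiplier/choice counts
phe_from_counts <- function(state, spec) {
  rows <- lapply(spec, function(s) {
    tibble::tibble(state = state, multiplier = s$m,
                   choice = rep(s$choice, s$n))
  })
  out <- dplyr::bind_rows(rows)
  out$respondent_id <- sprintf("P%04d", seq_len(nrow(out)))
  out[, c("respondent_id", "state", "multiplier", "choice")]
}

# a complete 16-answer respondent block with a given choice vector
pc_block <- function(id, choices, first = 1L, second = 2L) {
  tibble::tibble(respondent_id = id, question_index = seq_along(choices),
                 first_state = first, second_state = second,
                 choice = choices)
}
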