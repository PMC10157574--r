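#' Estimation configuration for the full pipeline
#'
#' Collects every tunable of the estimation chain with defaults matching
#' the survey's stated design: 16 PC questions (repeat at 3/10/16), 3 PHE
#' questions per web respondent, a 180-second web completion floor, 1000
#' bootstrap replicates and 1000 Monte Carlo draws. Every stochastic stage
#' derives its stream from `seed` plus the stage name.
#'
#' @param seed Integer master seed.
#' @param penalty Probit ridge penalty.
#' @param interval_scale Transform for the interval regression (`"logit"`
#'   or `"log"`).
#' @param anchor_scale Dependent scale of the anchoring regression
#'   (`"logit"` or `"identity"`).
#' @param regressor Anchoring regressor (`"probability"` or `"index"`).
#' @param n_bootstrap Bootstrap replicates for the 95% UIs.
#' @param n_mc Monte Carlo draws for the DW means.
#' @param survey A [survey_config()].
#' @return A list of class `dw_config`.
#' @export
dw_config <- function(seed = 1L, penalty = 1e-6,
                      interval_scale = c("logit", "log"),
                      anchor_scale = c("logit", "identity"),
                      regressor = c("probability", "index"),
                      n_bootstrap = 1000L, n_mc = 1000L,
                      survey = NULL) {
  structure(list(seed = as.integer(seed), penalty = penalty,
                 interval_scale = match.arg(interval_scale),
                 anchor_scale = match.arg(anchor_scale),
                 regressor = match.arg(regressor),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_mc = as.integer(n_mc),
                 survey = survey %||% survey_config(seed = seed)),
            class = "dw_config")
}

#' Estimate disability weights from survey tables
#'
#' The full estimation chain: quality-control filtering, paired-comparison
#' probit scaling, PHE interval regression, anchoring, Monte Carlo means
#' and bootstrap 95% uncertainty intervals, assembled into one results
#' table. If a state's percentile interval fails to cover its mean (Monte
#' Carlo noise at small replicate counts), the interval is widened to
#' include it and the state flagged.
#'
#' @param respondents,pc_responses,phe_responses Raw survey tables (see
#'   [qc_filter()] for schemas).
#' @param catalog A `dw_catalog`.
#' @param config A [dw_config()].
#' @param anchor_states Optional explicit anchor subset (default: the
#'   catalog's `is_phe_anchor` states).
#' @return A tibble of class `dw_results`: `state_id`, `label`, `dw`
#'   (point estimate), `dw_mean`, `ui_low`, `ui_high`, `n_bootstrap`,
#'   `flags`; fitted components and the QC report in attributes
#'   (`probit_fit`, `interval_fit`, `anchor`, `qc`).
#' @export
estimate_dws <- function(respondents, pc_responses, phe_responses, catalog,
                         config = dw_config(), anchor_states = NULL) {
  if (nrow(catalog) == 0) abort("empty catalog: nothing to estimate")
  anchor_states <- anchor_states %||%
    catalog$state_id[catalog$is_phe_anchor]

  qc <- qc_filter(respondents, pc_responses, config$survey)
  phe <- dplyr::filter(phe_responses,
                       .data$respondent_id %in% qc$respondents$respondent_id)

  design <- build_pc_design(qc$pc_responses, catalog)
  pfit <- fit_pc_probit(design, penalty = config$penalty)
  obs <- phe_to_interval(phe, scale = config$interval_scale)
  ifit <- fit_interval_regression(obs, config$interval_scale)
  anc <- fit_anchor(phe_dw_estimates(ifit, drop_boundary = TRUE), pfit,
                    anchor_states = anchor_states,
                    dependent_scale = config$anchor_scale,
                    regressor = config$regressor)
  point <- predict_dws(anc, pfit)
  mc <- monte_carlo_mean(anc, pfit, n_draws = config$n_mc,
                         seed = config$seed)
  ui <- bootstrap_ui(qc$respondents, qc$pc_responses, phe, catalog,
                     n_reps = config$n_bootstrap, seed = config$seed,
                     penalty = config$penalty,
                     interval_scale = config$interval_scale,
                     anchor_scale = config$anchor_scale,
                     regressor = config$regressor,
                     anchor_states = anchor_states,
                     start = pfit$beta)

  out <- point |>
    dplyr::left_join(mc, by = "state_id") |>
    dplyr::left_join(ui, by = "state_id") |>
    dplyr::left_join(dplyr::select(as_tibble(catalog), "state_id", "label"),
                     by = "state_id") |>
    dplyr::relocate("label", .after = "state_id")

  widened <- !is.na(out$ui_low) &
    (out$ui_low > out$dw_mean | out$ui_high < out$dw_mean)
  if (any(widened)) {
    warn(paste0(sum(widened), " interval(s) widened to include the mean"))
    out$ui_low <- pmin(out$ui_low, out$dw_mean)
    out$ui_high <- pmax(out$ui_high, out$dw_mean)
  }
  out$flags <- dplyr::case_when(
    out$unreliable ~ "unreliable-ui",
    widened ~ "ui-widened",
    .default = ""
  )
  out <- dplyr::select(out, "state_id", "label", "dw", "dw_mean",
                       "ui_low", "ui_high",
                       n_bootstrap = "n_reps_used", "flags")
  structure(out, class = c("dw_results", class(out)),
            probit_fit = pfit, interval_fit = ifit, anchor = anc, qc = qc)
}

#' @export
glance.dw_results <- function(x, ...) {
  anc <- attr(x, "anchor")
  qc <- attr(x, "qc")
  tibble(n_states = nrow(x),
         n_respondents = nrow(qc$respondents),
         n_excluded = nrow(qc$exclusions),
         anchor_slope = anc$slope, anchor_r_squared = anc$r_squared,
         interval_sigma = attr(x, "interval_fit")$sigma)
}

#' @export
autoplot.dw_results <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$dw_mean)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$dw_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ui_low,
                                        ymax = .data$ui_high),
                           colour = "grey70", width = 0) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "Health state (ranked by severity)",
                  y = "Disability weight (mean and 95% UI)") +
    ggplot2::theme_minimal()
}

round3 <- function(x) round(x, 3)

#' Write a results table to disk
#'
#' Exports `results.csv` with DW columns rounded to 3 decimals (full
#' precision retained in the in-memory object).
#'
#' @param results A `dw_results`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dw_results <- function(results, path) {
  out <- as_tibble(results) |>
    dplyr::mutate(dplyr::across(c("dw", "dw_mean", "ui_low", "ui_high"),
                                round3))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline from files
#'
#' Reads the survey tables, runs [estimate_dws()], optionally the
#' cross-survey comparison, and writes `results.csv`, `bins.csv`,
#' `exclusions.csv` (QC report), comparison outputs when a reference is
#' given, and a machine-readable run manifest (input checksums, config,
#' package version). Identical inputs, config and seed produce
#' byte-identical outputs.
#'
#' @param catalog_file,respondents_file,pc_file,phe_file Input CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param config A [dw_config()].
#' @param reference_file Optional reference DW table for comparison.
#' @return The `dw_results` table, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_dw_pipeline <- function(catalog_file, respondents_file, pc_file,
                            phe_file, out_dir, config = dw_config(),
                            reference_file = NULL) {
  catalog <- load_catalog(catalog_file)
  respondents <- readr::read_csv(respondents_file, show_col_types = FALSE,
                                 progress = FALSE)
  pc <- readr::read_csv(pc_file, show_col_types = FALSE, progress = FALSE)
  phe <- readr::read_csv(phe_file, show_col_types = FALSE, progress = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- estimate_dws(respondents, pc, phe, catalog, config)
  write_dw_results(results, file.path(out_dir, "results.csv"))
  readr::write_csv(attr(results, "qc")$exclusions,
                   file.path(out_dir, "exclusions.csv"), progress = FALSE)
  bins <- bin_distribution(results$dw_mean, denominator = nrow(catalog))
  readr::write_csv(dplyr::mutate(bins, percent = round(.data$percent, 1)),
                   file.path(out_dir, "bins.csv"), progress = FALSE)

  notes <- character()
  if (!is.null(reference_file)) {
    reference <- load_reference_dws(reference_file, catalog)
    local_dws <- dplyr::select(as_tibble(results), "state_id",
                               dw = "dw_mean")
    comp <- compare_dws(local_dws, reference, catalog)
    readr::write_csv(comp, file.path(out_dir, "comparison.csv"),
                     progress = FALSE)
    # comparison analyses degrade to a recorded skip, not a failed run
    tryCatch(
      readr::write_csv(symptom_regression(comp),
                       file.path(out_dir, "symptom_regression.csv"),
                       progress = FALSE),
      error = function(e) {
        notes <<- c(notes, paste0("symptom_regression skipped: ",
                                  conditionMessage(e)))
      })
    tryCatch(
      readr::write_csv(dw_correlation(local_dws, reference),
                       file.path(out_dir, "correlation.csv"),
                       progress = FALSE),
      error = function(e) {
        notes <<- c(notes, paste0("correlation skipped: ",
                                  conditionMessage(e)))
      })
  } else {
    notes <- "comparison skipped: no reference table supplied"
  }

  inputs <- c(catalog_file, respondents_file, pc_file, phe_file,
              reference_file)
  manifest <- list(
    package = "dwkit",
    version = as.character(utils::packageVersion("dwkit")),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     basename(inputs))),
    config = list(seed = config$seed, penalty = config$penalty,
                  interval_scale = config$interval_scale,
                  anchor_scale = config$anchor_scale,
                  regressor = config$regressor,
                  n_bootstrap = config$n_bootstrap, n_mc = config$n_mc),
    counts = list(respondents_in = nrow(respondents),
                  respondents_retained =
                    nrow(attr(results, "qc")$respondents),
                  pc_responses = nrow(pc), phe_responses = nrow(phe)),
    notes = as.list(notes)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(results)
}
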