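# End-to-end orchestration of the item-bank development pipeline:
# screening -> GRM calibration (with the never-modal, S-X2 and DIF screens
# and Cronbach's alpha) -> recalibration on the final item set -> CAT
# simulation -> validity statistics, with per-stage item accounting.

#' Run the full CAT-development pipeline
#'
#' Executes, in order: the pre-calibration screening battery
#' ([screen_items()]), GRM calibration ([fit_grm()]), the never-modal
#' category and S-X2 item-fit screens, the DIF screen (when a two-level
#' group with enough respondents is available), recalibration of the final
#' item set (whose MAP scores become `theta_true`), the CAT simulation
#' ([simulate_cat()]) and, when metadata are available, the concurrent and
#' discriminant validity statistics. Item counts entering and leaving each
#' stage are recorded.
#'
#' @param data A [response_matrix()], or a path to a response CSV.
#' @param config A [run_config()].
#' @param meta_path Optional metadata CSV (only used when `data` is a
#'   path).
#' @param out_dir Optional directory; when given, the item bank, the stage
#'   report and the per-respondent simulation results are written there as
#'   JSON/CSV.
#' @param seed Integer seed for the CAT simulation (default from config).
#' @return An object of class `pipeline_result`: `screening`, `calibration`
#'   (initial fit), `item_fit`, `dif`, `final` (recalibration on the final
#'   set), `simulation`, `validity`, `funnel` (stage-by-stage item counts),
#'   `bank` (the final bank).
#' @export
run_pipeline <- function(data, config = run_config(), meta_path = NULL,
                         out_dir = NULL, seed = NULL) {
  if (is.character(data)) {
    data <- read_response_csv(data, meta_path = meta_path)
  }
  stopifnot(inherits(data, "response_matrix"))
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed

  funnel <- list()
  note <- function(stage, n_in, n_out) {
    funnel[[length(funnel) + 1L]] <<-
      data.frame(stage = stage, items_in = n_in, items_out = n_out)
  }

  screening <- screen_items(data, config)
  funnel <- lapply(seq_len(nrow(screening$stages)), function(i) {
    screening$stages[i, ]
  })
  cur <- screening$data

  calibration <- fit_grm(cur)

  nm <- never_modal_category_screen(calibration$bank)
  keep_ids <- setdiff(cur$item_ids, nm$excluded)
  note("never_modal_category", length(cur$item_ids), length(keep_ids))

  item_fit <- s_x2_item_fit(calibration$bank, cur,
                            alpha = config$item_fit_alpha)
  fit_excl <- item_fit$item_id[item_fit$excluded]
  n_in <- length(keep_ids)
  keep_ids <- setdiff(keep_ids, fit_excl)
  note("item_fit", n_in, length(keep_ids))
  if (length(keep_ids) < 3L) {
    stop("fewer than 3 items survive the GRM-based screens", call. = FALSE)
  }
  cur <- subset_response_matrix(cur, items = keep_ids)

  dif <- NULL
  if (!is.null(cur$group) && nlevels(cur$group) == 2L &&
      all(table(cur$group) >= 50L)) {
    dif <- dif_screen(cur, alpha = config$dif_alpha)
    dif_excl <- dif$item_id[dif$excluded]
    n_in <- length(cur$item_ids)
    cur <- subset_response_matrix(cur, items = setdiff(cur$item_ids, dif_excl))
    note("dif", n_in, length(cur$item_ids))
  }
  if (length(cur$item_ids) < 3L) {
    stop("fewer than 3 items survive the DIF screen", call. = FALSE)
  }

  # recalibrate the final item set; its MAP scores are theta_true.
  # The simulation replays the observed responses (real-data simulation):
  # the adaptive test administers a subset of the answers each respondent
  # actually gave, and its score is compared with the full-bank score.
  final <- fit_grm(cur)
  simulation <- simulate_cat(final$bank, final$theta$value, config,
                             seed = seed, replay = cur$values)

  validity <- list(concurrent = NULL, discriminant = NULL)
  if (!is.null(cur$external_scores)) {
    validity$concurrent <- concurrent_validity(
      simulation$respondents$theta_est, cur$external_scores)
  }
  if (!is.null(cur$group) && nlevels(cur$group) >= 2L) {
    validity$discriminant <- discriminant_validity(
      simulation$respondents$theta_est, cur$group)
  }

  result <- structure(
    list(screening = screening, calibration = calibration,
         item_fit = item_fit, dif = dif, final = final,
         simulation = simulation, validity = validity,
         funnel = do.call(rbind, funnel), bank = final$bank),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("CAT-development pipeline\n")
  print(x$funnel, row.names = FALSE)
  cat(sprintf("final bank: %d items, Cronbach's alpha %.3f\n",
              length(x$bank$item_ids), x$final$alpha))
  cat(sprintf("CAT simulation: PCC %.3f (95%% CI %.3f-%.3f), mean items %.3f\n",
              x$simulation$pcc, x$simulation$pcc_ci_low,
              x$simulation$pcc_ci_high, x$simulation$mean_items))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Writes `bank.json` (final calibrated bank), `report.json` (stage funnel,
#' screening table, item fit, DIF, alpha, simulation summary, validity)
#' and `simulation.csv` (per-respondent rows).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bank_json(result$bank, file.path(out_dir, "bank.json"))
  utils::write.csv(result$simulation$respondents,
                   file.path(out_dir, "simulation.csv"), row.names = FALSE)
  report <- list(
    funnel = result$funnel,
    screening = result$screening$item_table,
    item_fit = result$item_fit,
    dif = result$dif,
    alpha = result$final$alpha,
    simulation = list(pcc = result$simulation$pcc,
                      pcc_ci = c(result$simulation$pcc_ci_low,
                                 result$simulation$pcc_ci_high),
                      mean_items = result$simulation$mean_items),
    validity = result$validity
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(out_dir)
}
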