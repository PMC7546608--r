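#' Run the full RSA pipeline on a dataset
#'
#' Convenience wrapper chaining the whole analysis for a multi-participant
#' dataset (real or simulated): per participant, estimate the neural RDM
#' timecourse ([rdm_timecourse], with a per-participant seed derived from
#' `config$seed`), build the predictor suite from the face metadata and the
#' participant's aggregated responses ([build_predictor_suite]), fit the
#' requested analyses ([fit_timecourse]), then combine across participants
#' with [group_summary].
#'
#' @param dataset An `rsa_simulation` (see [generate_dataset]) or any list
#'   with the same shape (`faces` + `participants`, each holding `behavior`
#'   and `epochs`).
#' @param config An [rdm_config] for the neural RDM estimator.
#' @param analyses Analysis list as for [fit_timecourse]. Defaults to plain
#'   fits of the three attractiveness predictors.
#' @param alpha,fdr_scope Passed to [group_summary].
#' @param activations Optional named list of activation matrices shared by
#'   all participants.
#' @return List with `group` (an `rsa_group`) and `fits` (per-participant
#'   `rsa_fit` objects).
#' @export
run_rsa_pipeline <- function(dataset, config = rdm_config(),
                             analyses = list(list(predictor = "db_rating"),
                                             list(predictor = "yesno"),
                                             list(predictor = "rating")),
                             alpha = 0.05, fdr_scope = "all",
                             activations = NULL) {
  faces <- dataset$faces
  fits <- vector("list", length(dataset$participants))
  for (p in seq_along(dataset$participants)) {
    part <- dataset$participants[[p]]
    cfg_p <- config
    cfg_p$seed <- derive_seed(config$seed, "participant", p)
    tc <- rdm_timecourse(part$epochs, cfg_p)
    predictors <- build_predictor_suite(
      faces, aggregate_responses(part$behavior, faces),
      activations = activations)
    fits[[p]] <- fit_timecourse(tc, predictors, analyses,
                                participant_id = part$epochs$participant_id)
  }
  list(group = group_summary(fits, alpha = alpha, fdr_scope = fdr_scope),
       fits = fits)
}
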