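#' Parameter-recovery experiment for one maternal factor
#'
#' Runs the full two-stage pipeline on a synthetic herd in which the
#' published effect sizes of one maternal circumstance are planted as ground
#' truth ([reference_effects()]), and returns the pipeline's estimates of
#' those effects. Three experiment kinds:
#'
#' * `"lact"`: lactation-concurrence effects planted on all three traits;
#'   stage-2 contrasts of groups 1-3 against the heifer-dam group 0.
#' * `"mastitis"`: the mastitis-exposure effect planted (lifespan by
#'   default); dam episodes drawn at the configured 13% incidence; stage-2
#'   binary contrast.
#' * `"merit"`: the genetic-merit by concurrence interaction planted for
#'   concurrent cows in the top true-merit decile, with heritability 0.3;
#'   estimated by the merit-stratified linear model within the tails of the
#'   posterior-mean breeding-value distribution.
#'
#' @param factor experiment kind.
#' @param seed RNG seed driving simulation and both Gibbs stages.
#' @param config optional [sim_config()] override; defaults to the
#'   `recovery` preset with the relevant effects planted.
#' @param traits traits to run (defaults depend on `factor`).
#' @param stage1,stage2 [gibbs_config()]s for the two stages (seeds are
#'   derived from `seed` when unset).
#' @return list with `contrasts` (data.frame of stage-2 contrast summaries,
#'   one block per trait), `strat` (merit-stratified estimates, `"merit"`
#'   only), `planted` (the planted values), `n_cows`, and `fits` (stage-1
#'   fits, named by trait).
#' @export
recovery_experiment <- function(factor = c("lact", "mastitis", "merit"),
                                seed = 1,
                                config = NULL,
                                traits = NULL,
                                stage1 = gibbs_config(5000, 500),
                                stage2 = gibbs_config(5000, 500)) {
  factor <- match.arg(factor)
  if (is.null(config)) {
    config <- sim_config("recovery")
    if (factor == "merit") {
      # heritability 0.3 for the merit experiment: selection on estimated
      # breeding values needs genetic signal
      config$traits$my$sigma_u <- config$traits$my$sigma_e * sqrt(0.3 / 0.7)
    }
    config <- plant_effects(config, factors = factor)
  }
  if (is.null(traits))
    traits <- switch(factor, lact = c("my", "fp", "dim_life"),
                     mastitis = "dim_life", merit = "my")
  herd <- simulate_herd(config, seed = seed)
  flt <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
  pheno <- derive_traits(flt$cows, max_length = config$max_std_length)
  circ <- assign_circumstance(flt$cows, herd$lactations, herd$scc,
                              herd$pedigree,
                              threshold = config$scc_threshold,
                              wood = config$wood)
  ainv <- make_Ainv(herd$pedigree)
  fits <- list()
  contrasts <- NULL
  strat <- NULL
  for (k in seq_along(traits)) {
    tr <- traits[k]
    s1 <- stage1; s1$seed <- if (is.null(stage1$seed)) seed + 100 + k else
      stage1$seed
    fit <- fit_animal_model(stage1_model(pheno, herd$pedigree, tr,
                                         ainv = ainv), s1)
    fits[[tr]] <- fit
    fct <- switch(factor,
                  lact = circ$lact_group,
                  mastitis = circ$mastitis,
                  merit = NULL)
    if (factor %in% c("lact", "mastitis")) {
      s2 <- stage2; s2$seed <- if (is.null(stage2$seed)) seed + 200 + k else
        stage2$seed
      mfit <- fit_maternal_model(unname(fit$residuals), fct, s2)
      cs <- all_contrasts(mfit, reference = "0")
      cs$trait <- tr
      contrasts <- rbind(contrasts, cs)
    } else {
      ebv_rec <- fit$ebv[pheno$cow_id]
      sets <- genetic_merit_percentiles(ebv_rec)
      strat <- merit_stratified_fit(fit$residuals, circ, sets)
    }
  }
  key <- setNames(c("my", "fp", "dim"), c("my", "fp", "dim_life"))
  planted <- lapply(setNames(traits, traits), function(tr)
    config$maternal[[key[[tr]]]])
  list(contrasts = contrasts, strat = strat, planted = planted,
       n_cows = nrow(pheno), fits = fits, circumstance = circ,
       truth = herd$truth)
}
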