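# tiny polynomial hash of a deparsed object, for metadata sidecars
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_with_meta <- function(df, path, meta) {
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every setting of the simulate - preprocess - stage 1 - stage 2 -
#' report pipeline. All seeds are recorded in each output's metadata
#' sidecar; stages communicate through files only.
#'
#' @param out_dir output directory.
#' @param preset generator preset (ignored when `input_dir` is given).
#' @param seed global seed; stage seeds derive from it.
#' @param input_dir directory with existing `pedigree.csv`, `cows.csv`,
#'   `lactations.csv`, `scc.csv` (non-simulation mode); `NULL` simulates.
#' @param factors maternal factors for stage 2.
#' @param traits traits to analyse.
#' @param sim a [sim_config()] (simulation mode).
#' @param stage1,stage2 [gibbs_config()]s.
#' @param merit lower/upper tail fractions of the merit stratification.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            preset = "recovery",
                            seed = 1,
                            input_dir = NULL,
                            factors = c("lact", "yield", "mastitis"),
                            traits = c("my", "fp", "dim_life"),
                            sim = sim_config(preset),
                            stage1 = gibbs_config(5000, 500),
                            stage2 = gibbs_config(10000, 1000),
                            merit = c(lower = 0.1, upper = 0.9)) {
  if (missing(out_dir)) stop("out_dir is required")
  factors <- match.arg(factors, several.ok = TRUE)
  traits <- match.arg(traits, several.ok = TRUE)
  if (!is.null(input_dir)) {
    need <- file.path(input_dir,
                      c("pedigree.csv", "cows.csv", "lactations.csv",
                        "scc.csv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("input_dir is missing required files: ",
           paste(basename(miss), collapse = ", "))
  }
  structure(list(out_dir = out_dir, preset = preset, seed = seed,
                 input_dir = input_dir, factors = factors, traits = traits,
                 sim = sim, stage1 = stage1, stage2 = stage2, merit = merit),
            class = c("pipeline_config", "list"))
}

#' Read a herd previously written by [write_herd()]
#'
#' @param dir directory with the herd CSV files.
#' @return list with `cows`, `lactations`, `scc`, `pedigree` (and `truth_u`
#'   when a ground-truth file is present).
#' @export
read_herd <- function(dir) {
  out <- list(
    cows = read.csv(file.path(dir, "cows.csv"), stringsAsFactors = FALSE,
                    colClasses = c(cow_id = "character",
                                   sire_id = "character",
                                   dam_id = "character")),
    lactations = read.csv(file.path(dir, "lactations.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(cow_id = "character")),
    scc = read.csv(file.path(dir, "scc.csv"), stringsAsFactors = FALSE,
                   colClasses = c(cow_id = "character")),
    pedigree = read_pedigree(file.path(dir, "pedigree.csv")))
  tu <- file.path(dir, "ground_truth_u.csv")
  if (file.exists(tu))
    out$truth_u <- read.csv(tu, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
  out
}

#' Run the full pipeline
#'
#' Simulates (or loads) a herd, applies the record filters, derives the
#' traits and maternal circumstances, fits the stage-1 animal model per
#' trait, the stage-2 maternal model per factor and trait, the
#' merit-stratified concurrence model for milk yield, and writes every
#' intermediate artifact plus a Markdown report. When ground truth is
#' available the report includes a planted-vs-estimated table.
#'
#' @param config a [pipeline_config()].
#' @return list with the contrast table, merit-stratified estimates, the
#'   exclusion log and the output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hashed <- config[setdiff(names(config), c("out_dir", "input_dir"))]
  meta0 <- list(seed = config$seed, config_hash = .config_hash(hashed),
                package_version = as.character(utils::packageVersion("matlact")))

  truth <- NULL
  if (is.null(config$input_dir)) {
    herd <- simulate_herd(config$sim, seed = config$seed)
    write_herd(herd, file.path(config$out_dir, "sim"))
    truth <- herd$truth
  } else {
    herd <- read_herd(config$input_dir)
  }

  flt <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
  pheno <- derive_traits(flt$cows, max_length = config$sim$max_std_length)
  circ <- assign_circumstance(flt$cows, herd$lactations, herd$scc,
                              herd$pedigree,
                              threshold = config$sim$scc_threshold,
                              wood = config$sim$wood)
  .write_with_meta(flt$log, file.path(config$out_dir, "exclusions.csv"),
                   c(meta0, stage = "preprocess",
                     n_in = nrow(herd$cows), n_kept = nrow(pheno)))
  .write_with_meta(cbind(pheno[c("cow_id", "my", "fp", "dim_life")],
                         circ[c("lact_group", "yield_group", "mastitis")]),
                   file.path(config$out_dir, "analysis_table.csv"),
                   c(meta0, stage = "preprocess"))

  ainv <- make_Ainv(herd$pedigree)
  contrasts <- NULL
  resids <- list()
  fits <- list()
  for (k in seq_along(config$traits)) {
    tr <- config$traits[k]
    s1 <- config$stage1
    if (is.null(s1$seed)) s1$seed <- config$seed + 100 + k
    fit <- fit_animal_model(stage1_model(pheno, herd$pedigree, tr,
                                         ainv = ainv), s1)
    fits[[tr]] <- fit
    resids[[tr]] <- fit$residuals
    .write_with_meta(extract_residuals(fit),
                     file.path(config$out_dir,
                               paste0("residuals_", tr, ".csv")),
                     c(meta0, stage = "stage1", trait = tr,
                       seed_stage = s1$seed))
    .write_with_meta(as.data.frame(fit$chain$samples),
                     file.path(config$out_dir, paste0("chain_", tr, ".csv")),
                     c(meta0, stage = "stage1", trait = tr,
                       n_iter = s1$n_iter, burn_in = s1$burn_in,
                       seed_stage = s1$seed))
    for (fc in config$factors) {
      fct <- switch(fc, lact = circ$lact_group, yield = circ$yield_group,
                    mastitis = circ$mastitis)
      s2 <- config$stage2
      if (is.null(s2$seed)) s2$seed <- config$seed + 1000 + 10 * k +
          match(fc, config$factors)
      mfit <- fit_maternal_model(unname(fit$residuals), fct, s2)
      cs <- all_contrasts(mfit, reference = "0")
      cs <- cbind(trait = tr, factor = fc, cs)
      contrasts <- rbind(contrasts, cs)
    }
  }
  .write_with_meta(contrasts, file.path(config$out_dir, "contrasts.csv"),
                   c(meta0, stage = "stage2"))

  strat <- NULL
  if ("my" %in% config$traits) {
    ebv_rec <- fits[["my"]]$ebv[pheno$cow_id]
    sets <- genetic_merit_percentiles(ebv_rec, config$merit["lower"],
                                      config$merit["upper"])
    strat <- merit_stratified_fit(fits[["my"]]$residuals, circ, sets)
    .write_with_meta(strat, file.path(config$out_dir, "merit_strata.csv"),
                     c(meta0, stage = "stage2"))
  }

  report <- c(
    "# Maternal-circumstance analysis report", "",
    sprintf("Cows analysed: %d (of %d records; %d excluded).",
            nrow(pheno), nrow(herd$cows), nrow(flt$log)),
    sprintf("Seed: %d. Config hash: %s.", config$seed, meta0$config_hash),
    "", "## Stage-2 contrasts vs reference level 0", "",
    knit_table(contrasts[c("trait", "factor", "level", "mean", "mcse",
                           "hpd_low", "hpd_high", "prob_neg")]))
  if (!is.null(strat))
    report <- c(report, "", "## Merit-stratified concurrence effect", "",
                knit_table(strat))
  if (!is.null(truth)) {
    key <- c(my = "my", fp = "fp", dim_life = "dim")
    pl <- contrasts[contrasts$factor == "lact", ]
    pl$planted <- mapply(function(tr, lv)
      truth$maternal[[key[[tr]]]]$lact[as.integer(lv)],
      pl$trait, pl$level)
    report <- c(report, "", "## Planted vs estimated (lactation groups)", "",
                knit_table(pl[c("trait", "level", "planted", "mean",
                                "mcse")]))
  }
  writeLines(report, file.path(config$out_dir, "report.md"))

  invisible(list(contrasts = contrasts, strat = strat, exclusions = flt$log,
                 out_dir = config$out_dir))
}

# minimal fixed-format Markdown table
knit_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "g", digits = 6)
    else as.character(x)
  body <- do.call(cbind, lapply(df, fmt))
  body <- rbind(colnames(df), rep("---", ncol(df)), body)
  apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
}
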