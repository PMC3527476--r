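#' Monte-Carlo standard error by non-overlapping batch means
#'
#' MCSE of the mean of a (possibly autocorrelated) chain: the chain is cut
#' into `n_batches` equal batches and the standard error of the batch means
#' is reported, which honours the chain's autocorrelation when batches are
#' long relative to the mixing time.
#'
#' @param x numeric chain (>= 100 samples).
#' @param n_batches number of non-overlapping batches (>= 10).
#' @return scalar MCSE of `mean(x)`.
#' @export
mcse_batch <- function(x, n_batches = 30) {
  n <- length(x)
  if (n < 100) stop("need at least 100 samples for a batch-means MCSE")
  if (n_batches < 10 || floor(n / n_batches) < 1)
    stop("too few samples for at least 10 batches")
  m <- floor(n / n_batches)
  bm <- colMeans(matrix(x[seq_len(m * n_batches)], nrow = m))
  sqrt(var(bm) / n_batches)
}

#' Fit the stage-2 maternal-circumstance model
#'
#' Hierarchical Bayesian model on stage-1 residuals for a single maternal
#' factor: `e_hat = mu + m_level + error`. Every level effect (including the
#' reference) and the overall mean draw from their normal full conditionals
#' with an effectively flat prior (`N(0, prior_var)` with `prior_var` large),
#' and the residual variance from its scaled-inverse-chi-square conditional.
#' Only contrasts between levels are identified — exactly what is reported.
#'
#' @param resid numeric vector of stage-1 posterior-mean residuals.
#' @param fct factor (or coercible) giving each cow's level of one maternal
#'   circumstance; every level must have at least one observation.
#' @param config a [gibbs_config()] (`keep`, `prior_h2` unused here).
#' @param prior_var flat-by-large-variance prior on `mu` and the level
#'   effects.
#' @param prior_S2 prior scale of the residual variance (default: moment
#'   estimate `var(resid)`).
#' @return object of class `stage2_fit` with the post-burn-in sample matrix
#'   (columns `mu`, `m_<level>`..., `sigma2`).
#' @export
fit_maternal_model <- function(resid, fct,
                               config = gibbs_config(),
                               prior_var = 1e10,
                               prior_S2 = var(resid)) {
  stopifnot(length(resid) == length(fct), !anyNA(resid))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.factor(fct)) fct <- factor(fct)
  cnt <- table(fct)
  if (any(cnt == 0))
    stop("maternal factor level with zero observations: ",
         names(cnt)[cnt == 0][1])
  lev <- levels(fct)
  k <- length(lev)
  n <- length(resid)
  gi <- as.integer(fct)
  n_l <- as.numeric(tabulate(gi, k))
  S_l <- as.numeric(rowsum(resid, gi))      # group sums, level order
  Sy <- sum(resid)
  Syy <- sum(resid^2)
  nu <- config$prior_nu
  S2 <- prior_S2

  n_keep <- config$n_iter - config$burn_in
  out <- matrix(NA_real_, n_keep, k + 2,
                dimnames = list(NULL, c("mu", paste0("m_", lev), "sigma2")))
  fix_s2 <- config$fixed_sigma_e
  mu <- mean(resid)
  m <- numeric(k)
  s2 <- if (!is.na(fix_s2)) fix_s2 else max(S2, 1e-12)
  for (it in seq_len(config$n_iter)) {
    prec_mu <- n / s2 + 1 / prior_var
    mu <- rnorm(1, (Sy - sum(n_l * m)) / s2 / prec_mu, sqrt(1 / prec_mu))
    prec_m <- n_l / s2 + 1 / prior_var
    m <- rnorm(k, (S_l - n_l * mu) / s2 / prec_m, sqrt(1 / prec_m))
    sse <- Syy - 2 * mu * Sy - 2 * sum(m * S_l) + 2 * mu * sum(n_l * m) +
      n * mu^2 + sum(n_l * m^2)
    sse <- max(sse, 0)
    if (is.na(fix_s2))
      s2 <- (nu * S2 + sse) / stats::rchisq(1, nu + n)
    if (it > config$burn_in)
      out[it - config$burn_in, ] <- c(mu, m, s2)
  }
  structure(list(samples = out, levels = lev,
                 n_iter = config$n_iter, burn_in = config$burn_in,
                 seed = config$seed, n_obs = n_l),
            class = c("stage2_fit", "posterior_chain", "list"))
}

#' Posterior summary of a maternal contrast
#'
#' Per-iteration contrast `m_level - m_reference`, summarised by its
#' posterior mean, batch-means MCSE, the equal-tail 95% interval
#' (2.5th-97.5th sample quantiles) and the posterior sign probabilities.
#'
#' @param fit a `stage2_fit`.
#' @param level factor level to contrast.
#' @param reference reference level (default `"0"`, the heifer-dam group).
#' @return one-row data.frame: `level`, `reference`, `mean`, `mcse`,
#'   `hpd_low`, `hpd_high`, `prob_neg`, `prob_pos`.
#' @export
contrast_summary <- function(fit, level, reference = "0") {
  stopifnot(inherits(fit, "stage2_fit"))
  level <- as.character(level); reference <- as.character(reference)
  if (level == reference) stop("contrast of a level against itself")
  for (l in c(level, reference))
    if (!l %in% fit$levels) stop("level not in the fitted factor: ", l)
  d <- fit$samples[, paste0("m_", level)] -
    fit$samples[, paste0("m_", reference)]
  qs <- unname(quantile(d, c(0.025, 0.975), type = 7))
  data.frame(level = level, reference = reference,
             mean = mean(d), mcse = mcse_batch(d),
             hpd_low = qs[1], hpd_high = qs[2],
             prob_neg = mean(d < 0), prob_pos = mean(d > 0),
             stringsAsFactors = FALSE)
}

#' All contrasts of a stage-2 fit against the reference level
#'
#' @param fit a `stage2_fit`.
#' @param reference reference level.
#' @return data.frame with one [contrast_summary()] row per non-reference
#'   level.
#' @export
all_contrasts <- function(fit, reference = "0") {
  lev <- setdiff(fit$levels, reference)
  do.call(rbind, lapply(lev, contrast_summary, fit = fit,
                        reference = reference))
}

#' Concurrence effect within genetic-merit strata
#'
#' Refits the concurrence question inside the top and bottom tails of the
#' estimated genetic-merit distribution: within each stratum, the linear
#' model `residual ~ concurrence` (concurrence = any open maternal lactation
#' at conception) is fitted and the coefficient and its standard error
#' reported.
#'
#' @param resid named vector of stage-1 residuals (names = cow ids).
#' @param circumstance data.frame from [assign_circumstance()].
#' @param merit_sets list with character vectors `bottom` and `top` from
#'   [genetic_merit_percentiles()].
#' @return data.frame `(stratum, estimate, se, p_value, n0, n1)`.
#' @export
merit_stratified_fit <- function(resid, circumstance, merit_sets) {
  stopifnot(all(c("bottom", "top") %in% names(merit_sets)))
  conc <- setNames(as.integer(circumstance$lact_group > 0),
                   circumstance$cow_id)
  one <- function(ids, label) {
    ids <- intersect(ids, intersect(names(resid), names(conc)))
    if (!length(ids)) stop("empty merit stratum: ", label)
    x <- conc[ids]
    if (length(unique(x)) < 2)
      stop("stratum ", label, " has a single concurrence level")
    fit <- lm(resid[ids] ~ x)
    sm <- summary(fit)$coefficients
    data.frame(stratum = label, estimate = sm["x", "Estimate"],
               se = sm["x", "Std. Error"], p_value = sm["x", "Pr(>|t|)"],
               n0 = sum(x == 0), n1 = sum(x == 1),
               stringsAsFactors = FALSE)
  }
  rbind(one(merit_sets$top, "top"), one(merit_sets$bottom, "bottom"))
}
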