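#' Gibbs sampler configuration
#'
#' Chain settings shared by the stage-1 animal model and the stage-2
#' maternal model. The defaults mirror routine genetic-evaluation practice:
#' a single chain of 10,000 iterations with the first 1,000 discarded.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded from the front of the chain.
#' @param seed optional RNG seed recorded with the chain.
#' @param keep labels of location parameters whose full chains are stored
#'   (stage 1 only); posterior means of all parameters are always stored.
#' @param prior_nu degrees of freedom of the scaled-inverse-chi-square
#'   variance priors.
#' @param prior_h2 heritability used to split an overall moment estimate of
#'   the phenotypic variance into the prior scales S2_u and S2_e. The
#'   default `NA` derives the scales from a paternal half-sib ANOVA moment
#'   estimate instead (`S2_u = 4 * sire variance component`), which centres
#'   the weakly informative prior on a data-driven value.
#' @param fixed_sigma_u,fixed_sigma_e freeze a variance component at this
#'   value instead of sampling it (`NA` = sample).
#' @param refresh iterations between exact recomputations of the cached
#'   sampler products (numerical hygiene).
#' @return list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 10000, burn_in = 1000, seed = NULL,
                         keep = character(), prior_nu = 4, prior_h2 = NA,
                         fixed_sigma_u = NA, fixed_sigma_e = NA,
                         refresh = 200) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  structure(list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                 keep = keep, prior_nu = prior_nu, prior_h2 = prior_h2,
                 fixed_sigma_u = fixed_sigma_u, fixed_sigma_e = fixed_sigma_e,
                 refresh = refresh),
            class = c("gibbs_config", "list"))
}

# paternal half-sib one-way ANOVA moment estimates of the variance-prior
# scales: S2_u = 4 * between-sire component, S2_e = within-sire MS less the
# within-family genetic share; both clipped to stay proper
.sire_anova_scales <- function(y, sire, vy) {
  ok <- !is.na(sire) & sire != "0"
  if (sum(ok) < 30 || length(unique(sire[ok])) < 3)
    return(c(0.25 * vy, 0.75 * vy))
  y <- y[ok]; g <- factor(sire[ok])
  n <- length(y); k <- nlevels(g)
  ng <- tabulate(g)
  gbar <- tapply(y, g, mean)
  ssb <- sum(ng * (gbar - mean(y))^2)
  ssw <- sum((y - gbar[g])^2)
  msb <- ssb / (k - 1); msw <- ssw / (n - k)
  n0 <- (n - sum(ng^2) / n) / (k - 1)
  s2s <- max((msb - msw) / n0, 0)
  S2u <- min(max(4 * s2s, 0.005 * vy), 0.9 * vy)
  S2e <- min(max(msw - 0.75 * S2u, 0.1 * vy), 1.5 * vy)
  c(S2u, S2e)
}

#' Build a stage-1 animal model
#'
#' Assembles the response and design of the Bayesian animal model
#' `y = X b + Z u + e` with `u ~ N(0, A sigma2_u)`: fixed environmental
#' effects (age at first parity in 1-month bins, year-region of birth,
#' herd-year of first calving; flat priors through a full-rank
#' treatment-contrast design), and one additive genetic effect per pedigree
#' individual. For the lifespan trait the first-lactation milk yield enters
#' as a centered covariate (functional-longevity adjustment).
#'
#' @param pheno output of [derive_traits()].
#' @param ped ordered pedigree containing every cow and its ancestors.
#' @param trait one of `"my"`, `"fp"`, `"dim_life"`.
#' @param ainv optional precomputed [make_Ainv()] for `ped`.
#' @param milk_covariate logical; default adds the milk covariate exactly
#'   for the lifespan trait.
#' @return list of class `stage1_model`.
#' @export
stage1_model <- function(pheno, ped, trait = c("my", "fp", "dim_life"),
                         ainv = NULL,
                         milk_covariate = identical(trait, "dim_life")) {
  trait <- match.arg(trait)
  y <- pheno[[trait]]
  stopifnot(is.numeric(y), !anyNA(y))
  zi <- match(pheno$cow_id, ped$id)
  if (anyNA(zi)) stop("cows missing from the pedigree: ",
                      pheno$cow_id[which(is.na(zi))[1]])
  df <- data.frame(age = factor(pheno$age_bin),
                   yr = factor(pheno$year_region),
                   hy = factor(pheno$herd_year))
  terms <- names(df)[vapply(df, nlevels, 0L) > 1]  # constant factors drop out
  if (isTRUE(milk_covariate)) {
    df$milk_c <- pheno$my - mean(pheno$my)
    terms <- c(terms, "milk_c")
  }
  form <- stats::reformulate(if (length(terms)) terms else "1")
  X <- Matrix::sparse.model.matrix(form, df)
  if (is.null(ainv)) ainv <- make_Ainv(ped)
  structure(list(trait = trait, y = y, X = X, zi = zi,
                 cow_id = pheno$cow_id, ped_id = ped$id,
                 sire = ped$sire[zi], ainv = ainv),
            class = c("stage1_model", "list"))
}

#' Fit the animal model by single-site Gibbs sampling
#'
#' Samples fixed effects and breeding values from their normal full
#' conditionals and the two variance components from their
#' scaled-inverse-chi-square conditionals. Prior scales default to a moment
#' split of `var(y)` by `prior_h2` with `prior_nu` degrees of freedom
#' (weakly informative); fixed effects are flat.
#'
#' @param model a [stage1_model()].
#' @param config a [gibbs_config()].
#' @return object of class `stage1_fit`: posterior means/sds of all location
#'   parameters, named breeding-value means (`ebv`), posterior-mean
#'   residuals, and a `posterior_chain` with the variance samples (plus any
#'   `keep` parameters).
#' @export
fit_animal_model <- function(model, config = gibbs_config()) {
  stopifnot(inherits(model, "stage1_model"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(model$y)
  q <- length(model$ped_id)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = model$zi, x = 1,
                            dims = c(n, q))
  W <- cbind(model$X, Z)
  labels <- c(colnames(model$X), model$ped_id)
  WtW <- methods::as(methods::as(Matrix::crossprod(W), "generalMatrix"),
                     "CsparseMatrix")
  Wty <- as.numeric(Matrix::crossprod(W, model$y))
  A <- methods::as(methods::as(model$ainv, "generalMatrix"),
                   "CsparseMatrix")
  vy <- var(model$y)
  if (is.na(config$prior_h2)) {
    sc <- .sire_anova_scales(model$y, model$sire, vy)
    S2u <- sc[1]; S2e <- sc[2]
  } else {
    S2u <- config$prior_h2 * vy
    S2e <- (1 - config$prior_h2) * vy
  }
  keep_idx <- match(config$keep, labels)
  if (anyNA(keep_idx)) stop("unknown parameter in keep: ",
                            config$keep[which(is.na(keep_idx))[1]])
  res <- animal_gibbs_cpp(WtW@p, WtW@i, WtW@x, Wty, sum(model$y^2), n,
                          A@p, A@i, A@x, ncol(model$X),
                          config$prior_nu, S2u, config$prior_nu, S2e,
                          config$n_iter, config$burn_in,
                          as.integer(keep_idx - 1L),
                          ifelse(is.na(config$fixed_sigma_u), -1,
                                 config$fixed_sigma_u),
                          ifelse(is.na(config$fixed_sigma_e), -1,
                                 config$fixed_sigma_e),
                          config$refresh)
  theta <- setNames(res$theta_mean, labels)
  samples <- cbind(sigma2_u = res$sigma2_u, sigma2_e = res$sigma2_e)
  if (length(keep_idx)) {
    colnames(res$kept) <- config$keep
    samples <- cbind(samples, res$kept)
  }
  chain <- structure(list(samples = samples,
                          n_iter = config$n_iter, burn_in = config$burn_in,
                          seed = config$seed),
                     class = c("posterior_chain", "list"))
  e_hat <- model$y - as.numeric(W %*% theta)
  structure(list(trait = model$trait,
                 theta_mean = theta,
                 theta_sd = setNames(res$theta_sd, labels),
                 ebv = setNames(theta[-seq_len(ncol(model$X))],
                                model$ped_id),
                 residuals = setNames(e_hat, model$cow_id),
                 cow_id = model$cow_id,
                 chain = chain),
            class = c("stage1_fit", "list"))
}

#' Posterior-mean residuals of a stage-1 fit
#'
#' `e_i = y_i - x_i' E(b) - z_i' E(u)` at the posterior means: the adjusted
#' performance of each cow, free of the modelled environmental and genetic
#' effects, which stage 2 regresses on the maternal circumstance.
#'
#' @param fit a `stage1_fit`.
#' @return data.frame `(cow_id, trait, e_hat)`.
#' @export
extract_residuals <- function(fit) {
  stopifnot(inherits(fit, "stage1_fit"))
  data.frame(cow_id = fit$cow_id, trait = fit$trait,
             e_hat = unname(fit$residuals), stringsAsFactors = FALSE)
}

#' Cows in the tails of the estimated genetic-merit distribution
#'
#' Splits the cows with records by the quantiles of their posterior-mean
#' breeding values; ties are broken by stable cow-id order so the set sizes
#' are exact.
#'
#' @param ebv named vector of posterior-mean breeding values of cows with
#'   records (subset the `ebv` element of a `stage1_fit`).
#' @param lower,upper tail fractions (defaults: bottom and top decile).
#' @return list with character vectors `bottom` and `top`.
#' @export
genetic_merit_percentiles <- function(ebv, lower = 0.1, upper = 0.9) {
  n <- length(ebv)
  k_lo <- round(n * lower)
  k_hi <- round(n * (1 - upper))
  if (k_lo < 1 || k_hi < 1)
    stop("degenerate quantiles: empty merit set")
  ord <- order(ebv, names(ebv))
  list(bottom = names(ebv)[ord[seq_len(k_lo)]],
       top = names(ebv)[ord[seq(n - k_hi + 1, n)]])
}
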