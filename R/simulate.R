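#' Calibrate the conception days-in-milk distribution
#'
#' Conception timing in lactating dams is modelled as a log-normal number of
#' days in milk (DIM). The two parameters are solved numerically from the two
#' summaries available for the breed: the distribution mode and the central
#' probability mass inside a DIM window (defaults: mode 73 d and 80% of
#' conceptions within 54-160 DIM).
#'
#' @param mode target mode of the distribution, days.
#' @param window two-sided DIM window, days.
#' @param mass probability mass required inside `window`.
#' @return list with `meanlog`, `sdlog` and the calibration inputs.
#' @export
conception_dim_params <- function(mode = 73, window = c(54, 160),
                                  mass = 0.80) {
  stopifnot(mode > 0, length(window) == 2, window[1] < window[2],
            mass > 0, mass < 1)
  f <- function(s) {
    m <- log(mode) + s^2
    plnorm(window[2], m, s) - plnorm(window[1], m, s) - mass
  }
  lo <- 0.02; hi <- 3
  if (f(lo) < 0 || f(hi) > 0)
    stop("infeasible conception-DIM calibration: mode/window/mass ",
         "cannot be met by a log-normal")
  s <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  list(meanlog = log(mode) + s^2, sdlog = s, mode = mode,
       window = window, mass = mass)
}

#' Draw conception DIM values
#'
#' @param n number of draws.
#' @param params calibration from [conception_dim_params()].
#' @return numeric vector of days in milk at conception.
#' @export
rconception_dim <- function(n, params = conception_dim_params()) {
  rlnorm(n, params$meanlog, params$sdlog)
}

#' Daily milk yield from a Wood-type lactation curve
#'
#' Scales the incomplete-gamma Wood curve `t^b * exp(-c t)` so that it
#' integrates to the 305-d standardized yield; used to interpolate the dam's
#' daily milk on the conception day from her lactation total.
#'
#' @param dim day in milk at which daily yield is evaluated.
#' @param my305 305-d standardized yield, kg.
#' @param b,c Wood shape parameters (defaults give a peak near 50 DIM).
#' @return daily yield, kg/d.
#' @export
wood_daily <- function(dim, my305, b = 0.2, c = 0.004) {
  total <- gamma(b + 1) / c^(b + 1) * pgamma(305, shape = b + 1, rate = c)
  my305 * dim^b * exp(-c * dim) / total
}

#' Published maternal-effect sizes used as planted ground truth
#'
#' Benchmark effect sizes for the three maternal circumstances, taken from
#' published estimates in Spanish Holstein data: lactation-concurrence effects
#' on milk yield, lifespan and fat/protein ratio, the mastitis-exposure
#' effects, and the genetic-merit by concurrence interaction for top-merit
#' cows. The recovery experiments plant these values in synthetic herds and
#' require the pipeline to estimate them back.
#'
#' @return data.frame with columns `trait`, `factor`, `level`, `value`.
#' @export
reference_effects <- function() {
  path <- system.file("extdata", "reference_effects.csv", package = "matlact")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

trait_names <- c("my", "fp", "dim")

#' Simulation configuration
#'
#' Builds the full configuration of the synthetic herd generator. The
#' `recovery` preset is the verification condition used throughout the test
#' suite: ~10,000 recorded cows over 4 discrete generations, residual
#' standard deviations shrunk to 100 kg (milk), 0.15 percentage points
#' (fat/protein) and 30 d (lifetime DIM) so that planted contrasts of tens of
#' units are estimable, and heritability 0.05 so that the animal model
#' absorbs almost none of the unmodelled maternal signal (see the methods
#' vignette for the attenuation algebra). The `paper_scale` preset mimics the
#' published phenotypic magnitudes (mean milk 8,500 kg, sd ~1,550 kg,
#' heritability 0.3). The `smoke` preset is a miniature herd for fast checks.
#'
#' @param preset one of `"recovery"`, `"paper_scale"`, `"smoke"`.
#' @param ... top-level fields to override (supply complete sub-lists).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(preset = c("recovery", "paper_scale", "smoke"), ...) {
  preset <- match.arg(preset)
  h2 <- 0.01
  sig_u <- function(sig_e, h2) sig_e * sqrt(h2 / (1 - h2))
  cfg <- list(
    preset = preset,
    n_founder_females = 1300, n_founder_males = 60,
    n_generations = 4, cows_per_gen = 3000, n_sires = 50,
    birth_order_frac = c(0.361, 0.310, 0.204, 0.125),
    herds = 25, regions = 3, p_dam_herd = 0.8,
    herd_allocation = "rotation",
    founder_birth_spread_d = 7300,
    analysis_window_q = c(0.1, 0.9),
    conception = conception_dim_params(),
    age_first_conception_mo = c(mean = 17.2, sd = 1.2),
    gestation_d = 282,
    dry_offset_d = 222,
    last_lactation_length = c(mean = 320, sd = 25, min = 250, max = 450),
    max_std_length = 450,
    wood = c(b = 0.2, c = 0.004),
    parity_factor = c(1, 1.12, 1.18, 1.20),
    parity_sd = 100,
    protein_frac = 0.032,
    mastitis_incidence = 0.13,
    scc_threshold = 4e5,
    scc_baseline = c(meanlog = log(8e4), sdlog = 0.5),
    scc_episode = c(meanlog = log(9e5), sdlog = 0.4),
    scc_interval_d = 30,
    abortion_rate = 0.004,
    cull_slope = 0.05,
    merit_frac = 0.10,
    traits = list(
      my  = list(mu = 8500, sigma_e = 100, sigma_u = sig_u(100, h2),
                 sd_herd_year = 30, sd_year_region = 15, beta_age = 5),
      fp  = list(mu = 118, sigma_e = 0.15, sigma_u = sig_u(0.15, h2),
                 sd_herd_year = 0.05, sd_year_region = 0.02,
                 beta_age = 0.01),
      dim = list(mu = 1000, sigma_e = 30, sigma_u = sig_u(30, h2),
                 sd_herd_year = 10, sd_year_region = 5, beta_age = 1)
    ),
    maternal = list(
      my  = list(lact = c(0, 0, 0), decile = rep(0, 10), mastitis = 0,
                 merit_interaction = 0),
      fp  = list(lact = c(0, 0, 0), decile = rep(0, 10), mastitis = 0,
                 merit_interaction = 0),
      dim = list(lact = c(0, 0, 0), decile = rep(0, 10), mastitis = 0,
                 merit_interaction = 0)
    )
  )
  if (preset == "paper_scale") {
    cfg$traits$my[c("sigma_e", "sigma_u", "sd_herd_year", "sd_year_region",
                    "beta_age")] <- list(1300, sig_u(1300, 0.3), 300, 150, 30)
    cfg$traits$fp[c("sigma_e", "sigma_u", "sd_herd_year", "sd_year_region",
                    "beta_age")] <- list(10, sig_u(10, 0.3), 2, 1, 0.1)
    cfg$traits$dim[c("sigma_e", "sigma_u", "sd_herd_year", "sd_year_region",
                     "beta_age")] <- list(350, sig_u(350, 0.3), 80, 40, 5)
    cfg$parity_sd <- 800
    cfg$cull_slope <- 0.02
    cfg$herd_allocation <- "inherit"
  }
  if (preset == "smoke") {
    cfg$n_founder_females <- 220; cfg$n_founder_males <- 15
    cfg$n_generations <- 2; cfg$cows_per_gen <- 300; cfg$n_sires <- 10
    cfg$herds <- 8
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim_config fields: ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(all(vapply(cfg$traits, function(t) t$sigma_e > 0, TRUE)),
            cfg$mastitis_incidence >= 0, cfg$mastitis_incidence <= 1,
            cfg$abortion_rate >= 0, cfg$abortion_rate <= 1)
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Plant reference maternal effects into a configuration
#'
#' Copies the effect sizes of [reference_effects()] (or a compatible table)
#' into the generator configuration, for the requested factors only; all
#' other maternal effects stay at zero (the reference level, concurrence
#' group 0, is always zero).
#'
#' @param config a [sim_config()].
#' @param factors subset of `c("lact", "mastitis", "merit")` to plant.
#' @param effects effect table with columns trait, factor, level, value.
#' @return the modified configuration.
#' @export
plant_effects <- function(config, factors = c("lact", "mastitis", "merit"),
                          effects = reference_effects()) {
  factors <- match.arg(factors, c("lact", "mastitis", "merit"),
                       several.ok = TRUE)
  for (k in seq_len(nrow(effects))) {
    tr <- effects$trait[k]; fa <- effects$factor[k]
    if (!fa %in% factors || !tr %in% trait_names) next
    if (fa == "lact") {
      config$maternal[[tr]]$lact[as.integer(effects$level[k])] <-
        effects$value[k]
    } else if (fa == "mastitis") {
      config$maternal[[tr]]$mastitis <- effects$value[k]
    } else if (fa == "merit") {
      config$maternal[[tr]]$merit_interaction <- effects$value[k]
    }
  }
  config
}

#' Simulate a discrete-generation dairy pedigree
#'
#' Founders are unrelated; each later generation is produced by mating a
#' small pool of sires (large half-sib families, as in dairy AI breeding) to
#' dams of the previous generation. Every dam has up to four parities; the
#' recorded daughters of a dam are a random subset of those parities (only
#' part of a cow's calves are female and enter the recording scheme), drawn
#' so that the population-level birth-order composition matches
#' `birth_order_frac`. The birth order determines the dam's parity at the
#' daughter's conception and hence the maternal lactation-concurrence group
#' (first calf: the dam was a non-lactating heifer).
#'
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return an ordered `ped_df` with extra columns `sex`, `generation`,
#'   `birth_order`.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- config$birth_order_frac / sum(config$birth_order_frac)
  n_ord <- length(q)
  rows <- list(
    data.frame(id = sprintf("F%05d", seq_len(config$n_founder_females)),
               sire = "0", dam = "0", sex = "F", generation = 0L,
               birth_order = NA_integer_),
    data.frame(id = sprintf("M%05d", seq_len(config$n_founder_males)),
               sire = "0", dam = "0", sex = "M", generation = 0L,
               birth_order = NA_integer_)
  )
  prev_f <- rows[[1]]$id
  prev_m <- rows[[2]]$id
  for (g in seq_len(config$n_generations)) {
    N <- config$cows_per_gen
    counts <- as.integer(round(N * q))
    counts[1] <- counts[1] + (N - sum(counts))
    if (max(counts) > length(prev_f))
      stop("not enough females in generation ", g - 1, " to serve as dams")
    # one (dam, parity) slot per recorded daughter; a dam holds at most one
    # recorded daughter per parity, and parities are sampled independently,
    # so birth order is not confounded with family size
    dam_vec <- unlist(lapply(counts, function(nj) sample(prev_f, nj)))
    order_vec <- rep.int(seq_len(n_ord), counts)
    sire_pool <- if (length(prev_m) > config$n_sires)
      sample(prev_m, config$n_sires) else prev_m
    cows <- data.frame(
      id = sprintf("C%d_%05d", g, seq_len(N)),
      sire = sample(sire_pool, N, replace = TRUE),
      dam = dam_vec, sex = "F", generation = g,
      birth_order = order_vec)
    males <- data.frame(
      id = sprintf("S%d_%03d", g, seq_len(config$n_sires)),
      sire = sample(sire_pool, config$n_sires, replace = TRUE),
      dam = sample(prev_f, config$n_sires,
                   replace = length(prev_f) < config$n_sires),
      sex = "M", generation = g, birth_order = NA_integer_)
    rows <- c(rows, list(cows, males))
    prev_f <- cows$id
    prev_m <- males$id
  }
  order_pedigree(do.call(rbind, rows))
}

#' Simulate additive genetic merit along a pedigree
#'
#' Founders draw `N(0, sigma_u^2)`; non-founders receive the parent average
#' plus a Mendelian-sampling deviate with variance
#' `sigma_u^2 * (0.5 - 0.25 (F_sire + F_dam))` (0.75/1 with one/two unknown
#' parents).
#'
#' @param ped ordered pedigree.
#' @param sigma_u named vector of genetic standard deviations (one column of
#'   breeding values is simulated per entry).
#' @param seed optional RNG seed.
#' @return matrix of breeding values, rows named by individual.
#' @export
simulate_breeding_values <- function(ped, sigma_u, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ix <- ped_indices(ped)
  f <- inbreeding_ml(ix$sire, ix$dam)
  n <- nrow(ped)
  s <- ix$sire + 1L; d <- ix$dam + 1L
  msd <- sqrt(ifelse(s == 0 & d == 0, 1,
               ifelse(s == 0, 0.75 - 0.25 * f[pmax(d, 1)],
               ifelse(d == 0, 0.75 - 0.25 * f[pmax(s, 1)],
                      0.5 - 0.25 * (f[pmax(s, 1)] + f[pmax(d, 1)])))))
  out <- matrix(0, n, length(sigma_u),
                dimnames = list(ped$id, names(sigma_u)))
  for (k in seq_along(sigma_u)) {
    if (sigma_u[k] == 0) next
    z <- rnorm(n)
    u <- numeric(n)
    for (i in seq_len(n)) {
      pa <- 0
      if (s[i] > 0) pa <- pa + 0.5 * u[s[i]]
      if (d[i] > 0) pa <- pa + 0.5 * u[d[i]]
      u[i] <- pa + z[i] * sigma_u[k] * msd[i]
    }
    out[, k] <- u
  }
  out
}

# months -> days
.mo_d <- 30.44

#' Simulate a complete recorded herd with planted maternal effects
#'
#' Generates the pedigree, breeding values, conception and calving timeline,
#' dam lactation histories with somatic-cell tests, and first-lactation
#' phenotype records for every analysis cow, composing each trait as fixed
#' environmental effects + additive genetic merit + planted maternal effects
#' + residual noise. Lifetime days in milk additionally depends on
#' first-lactation milk through a linear culling term, which the stage-1
#' milk-yield covariate must absorb. Ground truth sufficient to score every
#' downstream estimate is returned alongside the records.
#'
#' @param config a [sim_config()].
#' @param seed optional RNG seed; identical config + seed give identical
#'   tables.
#' @return list of class `sim_herd` with elements `cows`, `lactations`,
#'   `scc`, `pedigree`, `truth`, `config`. Dates are numeric days from an
#'   arbitrary origin.
#' @export
simulate_herd <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- simulate_pedigree(config)
  sig_u <- vapply(config$traits, function(t) t$sigma_u, 0)
  u <- simulate_breeding_values(ped, sig_u)

  fem <- as.data.frame(ped)[ped$sex == "F", ]
  nf <- nrow(fem)
  fem$pos <- seq_len(nf)
  rownames(fem) <- fem$id
  dam_pos <- match(fem$dam, fem$id)          # NA for founders
  is_cow <- fem$generation > 0
  ord <- fem$birth_order
  gest <- config$gestation_d
  n_par <- 4L

  # every female's own reproductive timeline: age at first conception, then
  # chained conceptions (DIM draws) and calvings for four parities
  a0 <- round(.mo_d * pmin(24, pmax(13,
          rnorm(nf, config$age_first_conception_mo["mean"],
                config$age_first_conception_mo["sd"]))))
  dimp <- matrix(round(rconception_dim(nf * (n_par - 1), config$conception)),
                 nf, n_par - 1)
  cofs <- matrix(0, nf, n_par)               # calving offsets from own birth
  cofs[, 1] <- a0 + gest
  for (p in 2:n_par) cofs[, p] <- cofs[, p - 1] + dimp[, p - 1] + gest

  # births follow the dam's calving of the recorded parity slot
  birth <- numeric(nf)
  # founders stagger over many birth years: cohorts overlap in calendar
  # time, as in national recording data, so that the maternal-circumstance
  # composition is stationary across herd-years
  birth[!is_cow] <- floor(runif(sum(!is_cow),
                                0, config$founder_birth_spread_d))
  for (g in seq_len(config$n_generations)) {
    r <- which(fem$generation == g)
    birth[r] <- birth[dam_pos[r]] + cofs[cbind(dam_pos[r], ord[r])]
  }
  conc <- ifelse(is_cow, birth - gest, NA_real_)
  dimc <- rep(NA_real_, nf)                  # dam DIM at this conception
  o2 <- which(is_cow & ord >= 2)
  dimc[o2] <- dimp[cbind(dam_pos[o2], ord[o2] - 1L)]
  calving1 <- birth + cofs[, 1]
  age_mo <- round(cofs[, 1] / .mo_d)

  lact_group <- ifelse(is_cow, pmin(ord - 1L, 3L), NA_integer_)

  # analysis window: only cows whose first calving falls in the central
  # recording years are analysed (edge years have unbalanced group
  # composition by construction); the others remain as dams and ancestors
  cy <- floor(calving1 / 365.25)
  qw <- quantile(cy[is_cow], config$analysis_window_q, type = 1,
                 names = FALSE)
  analysis <- is_cow & cy >= qw[1] & cy <= qw[2]

  # herds and regions. Two allocation schemes:
  # "inherit": cows mostly stay in their dam's herd (realistic herd
  #   lineages);
  # "rotation": within each first-calving year, analysis cows are dealt to
  #   herds in rotation ordered by maternal group, so every herd-year cell
  #   holds a near-proportional mix of exposure groups. The verification
  #   presets use rotation: with several hundred flat-prior herd-year
  #   levels, random allocation lets the cell estimates absorb an
  #   O(levels/n) share of any unmodelled group signal, which a recovery
  #   harness must avoid.
  herd <- sample.int(config$herds, nf, replace = TRUE)
  if (identical(config$herd_allocation, "inherit")) {
    for (g in seq_len(config$n_generations)) {
      r <- which(fem$generation == g)
      keep <- runif(length(r)) < config$p_dam_herd
      herd[r] <- ifelse(keep, herd[dam_pos[r]],
                        sample.int(config$herds, length(r), replace = TRUE))
    }
  } else {
    ai <- which(analysis)
    o <- ai[order(cy[ai], lact_group[ai], ai)]
    start <- sample.int(config$herds, 1)
    herd[o] <- (start + seq_along(o) - 1L) %% config$herds + 1L
  }
  region <- (herd - 1L) %% config$regions + 1L

  # lactation skeleton: four parities per female
  lact_female <- rep(seq_len(nf), each = n_par)
  lact_parity <- rep.int(seq_len(n_par), nf)
  lact_calving <- birth[lact_female] +
    cofs[cbind(lact_female, lact_parity)]
  ll <- config$last_lactation_length
  lact_length <- ifelse(
    lact_parity < n_par,
    dimp[cbind(lact_female, pmin(lact_parity, n_par - 1L))] +
      config$dry_offset_d,
    round(pmin(ll["max"], pmax(ll["min"],
               rnorm(nf * n_par, ll["mean"], ll["sd"]))))[
      seq_len(nf * n_par)])

  # planted-circumstance ingredients available before phenotypes
  conc_frac <- mean(lact_group[analysis] > 0)
  p_epi <- min(1, config$mastitis_incidence / max(conc_frac, 1e-12))
  mastitis <- integer(nf)
  mastitis[is_cow & lact_group > 0] <-
    rbinom(sum(is_cow & lact_group > 0), 1, p_epi)
  u_my_cows <- u[match(fem$id, rownames(u)), "my"]
  top_thr <- quantile(u_my_cows[analysis], 1 - config$merit_frac,
                      names = FALSE)
  true_top <- is_cow & u_my_cows >= top_thr
  abortion <- integer(nf)
  abortion[is_cow] <- rbinom(sum(is_cow), 1, config$abortion_rate)

  # fixed-effect level values (same label convention as derive_traits)
  herd_year <- .hy_label(herd, calving1)
  year_region <- .yr_label(region, birth)
  hy_lev <- sort(unique(herd_year[is_cow]))
  yr_lev <- sort(unique(year_region[is_cow]))
  fx <- list()
  for (tr in trait_names) {
    fx[[tr]] <- list(
      herd_year = setNames(rnorm(length(hy_lev), 0,
                                 config$traits[[tr]]$sd_herd_year), hy_lev),
      year_region = setNames(rnorm(length(yr_lev), 0,
                                   config$traits[[tr]]$sd_year_region),
                             yr_lev),
      beta_age = config$traits[[tr]]$beta_age)
  }

  # residual draws, fixed once, reused by both phenotype passes
  eps <- sapply(trait_names, function(tr)
    rnorm(nf, 0, config$traits[[tr]]$sigma_e))
  parity_eps <- rnorm(nf * n_par, 0, config$parity_sd)

  u_all <- u[match(fem$id, rownames(u)), , drop = FALSE]

  # one phenotype pass; dec_eff is the per-cow planted decile effect per
  # trait. Trait records are composed for every female with a record (the
  # maternal effects of non-analysed cows still shape their own yields and
  # hence their daughters' dam-yield circumstance).
  run_pass <- function(dec_eff) {
    my <- fp <- di <- numeric(nf)
    my305 <- rep(NA_real_, nf * n_par)
    daily <- rep(NA_real_, nf)
    for (g in 0:config$n_generations) {
      r <- which(fem$generation == g)
      if (g == 0) {
        my[r] <- config$traits$my$mu + u_all[r, "my"] + eps[r, "my"]
        fp[r] <- config$traits$fp$mu + u_all[r, "fp"] + eps[r, "fp"]
        di[r] <- config$traits$dim$mu + u_all[r, "dim"] + eps[r, "dim"]
      } else {
        lg <- lact_group[r]
        conc_open <- lg > 0
        # dam daily milk at conception from her open lactation's 305-d total
        dm <- rep(NA_real_, length(r))
        if (any(conc_open)) {
          ro <- r[conc_open]
          lrow <- (dam_pos[ro] - 1L) * n_par + (ord[ro] - 1L)
          dm <- replace(dm, conc_open,
                        wood_daily(dimc[ro], my305[lrow],
                                   config$wood["b"], config$wood["c"]))
        }
        daily[r] <- dm
        mk_tr <- function(tr, vec_u) {
          m <- config$maternal[[tr]]
          config$traits[[tr]]$mu +
            fx[[tr]]$herd_year[herd_year[r]] +
            fx[[tr]]$year_region[year_region[r]] +
            fx[[tr]]$beta_age * (age_mo[r] - 26) +
            vec_u +
            c(0, m$lact)[lg + 1L] +
            m$mastitis * mastitis[r] +
            m$merit_interaction * (lg > 0) * true_top[r] +
            dec_eff[[tr]][r] +
            eps[r, tr]
        }
        my[r] <- mk_tr("my", u_all[r, "my"])
        fp[r] <- mk_tr("fp", u_all[r, "fp"])
        di[r] <- mk_tr("dim", u_all[r, "dim"]) +
          config$cull_slope * (my[r] - config$traits$my$mu)
      }
      # 305-d totals for this generation's lactations
      lr <- as.vector(outer(seq_len(n_par), (r - 1L) * n_par, "+"))
      p1 <- my[lact_female[lr]]
      pf <- config$parity_factor[pmin(lact_parity[lr],
                                      length(config$parity_factor))]
      my305[lr] <- ifelse(lact_parity[lr] == 1, p1,
                          p1 * pf + parity_eps[lr])
    }
    list(my = my, fp = fp, dim = di, my305 = my305, daily = daily)
  }

  zero_dec <- lapply(setNames(trait_names, trait_names),
                     function(tr) numeric(nf))
  pass <- run_pass(zero_dec)
  any_decile <- any(vapply(config$maternal,
                           function(m) any(m$decile != 0), TRUE))
  lactating <- is_cow & lact_group > 0
  # decile boundaries on the population the analysis will retain, so the
  # preprocessing step re-derives identical groups
  L1 <- numeric(nf)
  L1[lact_female[lact_parity == 1]] <- lact_length[lact_parity == 1]
  cum_milk <- pass$my * pmin(L1, config$max_std_length) / 305
  retained <- analysis & abortion == 0 & cum_milk >= 1000
  bounds <- decile_bounds(pass$daily[lactating & retained])
  yield_group <- integer(nf)
  yield_group[lactating] <- assign_decile(pass$daily[lactating], bounds)
  if (any_decile) {
    dec_eff <- lapply(setNames(trait_names, trait_names), function(tr)
      ifelse(lactating, config$maternal[[tr]]$decile[pmax(yield_group, 1)],
             0))
    pass <- run_pass(dec_eff)
    # groups used for planting are the ground truth; realized daily milk
    # shifts the empirical bounds slightly (documented in the vignette)
  }

  # guard the trait invariant: lifetime DIM covers the first lactation
  dim_life <- pmax(pass$dim, L1 + 1)

  # cow (analysis) table with raw cumulative first-lactation yields
  ci <- which(analysis)
  len1 <- L1[ci]
  scale1 <- pmin(len1, config$max_std_length) / 305
  prot305 <- pass$my[ci] * config$protein_frac
  fat305 <- prot305 * pass$fp[ci] / 100
  cows <- data.frame(
    cow_id = fem$id[ci],
    sire_id = fem$sire[ci],
    dam_id = fem$dam[ci],
    birth_date = birth[ci],
    conception_date = conc[ci],
    herd = herd[ci], region = region[ci],
    calving1_date = calving1[ci],
    age_first_parity_mo = age_mo[ci],
    length1_d = len1,
    milk_kg = pass$my[ci] * scale1,
    fat_kg = fat305 * scale1,
    prot_kg = prot305 * scale1,
    dim_life = round(dim_life[ci], 3),
    abortion = abortion[ci],
    stringsAsFactors = FALSE)

  lactations <- data.frame(
    cow_id = fem$id[lact_female],
    parity = lact_parity,
    calving_date = lact_calving,
    length_d = lact_length,
    my305 = pass$my305,
    stringsAsFactors = FALSE)

  # somatic-cell tests for the lactations of dams of analysis cows only
  dam_set <- unique(dam_pos[analysis])
  scc <- local({
    keep <- lact_female %in% dam_set
    lf <- lact_female[keep]; cal <- lact_calving[keep]
    len <- lact_length[keep]
    ntest <- pmax(1L, floor(len / config$scc_interval_d))
    rows <- rep(seq_along(lf), ntest)
    offs <- sequence(ntest) * config$scc_interval_d
    val <- pmin(0.98 * config$scc_threshold,
                rlnorm(length(rows), config$scc_baseline["meanlog"],
                       config$scc_baseline["sdlog"]))
    data.frame(cow_id = fem$id[lf[rows]],
               test_date = cal[rows] + offs,
               scc = round(val, 1), stringsAsFactors = FALSE)
  })
  epi <- which(mastitis == 1 & analysis)
  if (length(epi)) {
    val <- pmax(1.05 * config$scc_threshold,
                rlnorm(length(epi), config$scc_episode["meanlog"],
                       config$scc_episode["sdlog"]))
    scc <- rbind(scc, data.frame(
      cow_id = fem$dam[epi],
      test_date = conc[epi] + round(runif(length(epi), 10, 200)),
      scc = round(val, 1)))
  }
  scc <- scc[order(scc$cow_id, scc$test_date), ]
  rownames(scc) <- NULL

  truth <- list(
    u = u,
    circumstance = data.frame(
      cow_id = fem$id[ci],
      lact_group = lact_group[ci],
      yield_group = yield_group[ci],
      mastitis = mastitis[ci],
      true_top = true_top[ci],
      dam_daily_milk = pass$daily[ci],
      stringsAsFactors = FALSE),
    decile_bounds = bounds,
    maternal = config$maternal,
    fixed_effects = fx,
    sigma_u = sig_u,
    sigma_e = vapply(config$traits, function(t) t$sigma_e, 0))

  ped_out <- ped
  ped_out$birth_date <- birth[match(ped$id, fem$id)]

  structure(list(cows = cows, lactations = lactations, scc = scc,
                 pedigree = ped_out, truth = truth, config = config),
            class = "sim_herd")
}

#' Write / read the simulated herd as headered CSV files
#'
#' Emits `pedigree.csv`, `cows.csv`, `lactations.csv`, `scc.csv` and
#' `ground_truth_u.csv` (plus `truth.json` with planted effects and variance
#' components) into `dir`.
#'
#' @param herd a `sim_herd` from [simulate_herd()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(herd$pedigree, file.path(dir, "pedigree.csv"))
  write.csv(herd$cows, file.path(dir, "cows.csv"), row.names = FALSE)
  write.csv(herd$lactations, file.path(dir, "lactations.csv"),
            row.names = FALSE)
  write.csv(herd$scc, file.path(dir, "scc.csv"), row.names = FALSE)
  tu <- data.frame(id = rownames(herd$truth$u), herd$truth$u)
  write.csv(tu, file.path(dir, "ground_truth_u.csv"), row.names = FALSE)
  meta <- list(maternal = herd$truth$maternal,
               sigma_u = as.list(herd$truth$sigma_u),
               sigma_e = as.list(herd$truth$sigma_e),
               decile_bounds = herd$truth$decile_bounds)
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
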