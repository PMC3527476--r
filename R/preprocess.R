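# label helpers shared by the generator and the preprocessing step
.hy_label <- function(herd, calving_date)
  paste0("h", herd, "_y", floor(calving_date / 365.25))
.yr_label <- function(region, birth_date)
  paste0("y", floor(birth_date / 365.25), "_r", region)

#' Standardize a lactation yield to 305 days
#'
#' Linear rescaling `yield * 305 / length`; lactation lengths beyond
#' `max_length` are truncated before scaling. Identity at 305 d.
#'
#' @param yield cumulative yield over the lactation, kg.
#' @param length lactation length, days (> 0).
#' @param max_length cap applied to `length` before scaling.
#' @return 305-d standardized yield, kg.
#' @examples
#' standardize_305(4000, 152.5)  # 8000
#' @export
standardize_305 <- function(yield, length, max_length = 450) {
  if (any(length <= 0)) stop("non-positive lactation length")
  yield * 305 / pmin(length, max_length)
}

#' Apply the record filters
#'
#' Excludes cows with a registered abortion before first lactation, cows
#' whose cumulative first-lactation milk never reached 1,000 kg, cows with
#' unknown pedigree (unknown sire or dam, or parent absent from the pedigree
#' file), cows whose dam has no lactation records, and cows with a missing
#' conception date. Filtering is total and order-stable; applying it twice
#' equals applying it once.
#'
#' @param cows cow phenotype table (see [simulate_herd()] for the schema).
#' @param lactations lactation record table.
#' @param pedigree ordered pedigree.
#' @param unknown unknown-parent sentinel.
#' @return list with `cows` (retained rows) and `log`, a data.frame
#'   `(cow_id, rule, value)` with one row per excluded cow giving the first
#'   rule that removed it.
#' @export
apply_filters <- function(cows, lactations, pedigree, unknown = "0") {
  if (!nrow(cows))
    return(list(cows = cows,
                log = data.frame(cow_id = character(), rule = character(),
                                 value = character())))
  rules <- list(
    missing_conception = list(
      hit = is.na(cows$conception_date),
      value = rep("", nrow(cows))),
    abortion = list(
      hit = !is.na(cows$abortion) & cows$abortion == 1,
      value = as.character(cows$abortion)),
    below_1000kg = list(
      hit = !is.na(cows$milk_kg) & cows$milk_kg < 1000,
      value = as.character(round(cows$milk_kg, 1))),
    unknown_pedigree = list(
      hit = cows$sire_id == unknown | cows$dam_id == unknown |
        !(cows$sire_id %in% pedigree$id) | !(cows$dam_id %in% pedigree$id),
      value = paste(cows$sire_id, cows$dam_id, sep = "/")),
    dam_unrecorded = list(
      hit = !(cows$dam_id %in% lactations$cow_id),
      value = cows$dam_id)
  )
  first_rule <- rep(NA_character_, nrow(cows))
  value <- rep("", nrow(cows))
  for (rn in names(rules)) {
    new <- is.na(first_rule) & rules[[rn]]$hit
    first_rule[new] <- rn
    value[new] <- rules[[rn]]$value[new]
  }
  drop <- !is.na(first_rule)
  list(cows = cows[!drop, , drop = FALSE],
       log = data.frame(cow_id = cows$cow_id[drop], rule = first_rule[drop],
                        value = value[drop], stringsAsFactors = FALSE))
}

#' Derive the three analysis traits and environmental descriptors
#'
#' Computes 305-d standardized milk yield (MY), the fat/protein ratio in
#' percent (FP), and lifetime days in milk (DIM), plus the categorical
#' environmental descriptors used by the stage-1 adjustment (age at first
#' parity in 1-month bins, year-region of birth, herd-year of first calving).
#'
#' @param cows filtered cow table.
#' @param max_length cap for [standardize_305()].
#' @return data.frame, one row per cow: `cow_id`, `my`, `fp`, `dim_life`,
#'   `age_bin`, `year_region`, `herd_year`, `dam_id`.
#' @export
derive_traits <- function(cows, max_length = 450) {
  my <- standardize_305(cows$milk_kg, cows$length1_d, max_length)
  fat <- standardize_305(cows$fat_kg, cows$length1_d, max_length)
  prot <- standardize_305(cows$prot_kg, cows$length1_d, max_length)
  data.frame(
    cow_id = cows$cow_id,
    my = my,
    fp = fat / prot * 100,
    dim_life = cows$dim_life,
    age_bin = as.character(cows$age_first_parity_mo),
    year_region = .yr_label(cows$region, cows$birth_date),
    herd_year = .hy_label(cows$herd, cows$calving1_date),
    dam_id = cows$dam_id,
    stringsAsFactors = FALSE)
}

#' Decile boundaries of dam daily milk
#'
#' Empirical 10th..90th percentile boundaries (linear-interpolation
#' quantiles). Groups need not be equal-sized when the data are tied.
#'
#' @param x daily milk of lactating dams at conception, kg/d (>= 10 values).
#' @return non-decreasing numeric vector of 9 boundaries.
#' @export
decile_bounds <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("need at least 10 values to form decile bounds")
  quantile(x, probs = seq(0.1, 0.9, by = 0.1), names = FALSE, type = 7)
}

#' Assign decile groups with left-open, right-closed intervals
#'
#' Group 1 is `x <= b1`, group k is `b_{k-1} < x <= b_k`, group 10 is
#' `x > b9`; a value equal to a boundary falls in the lower group.
#'
#' @param x daily milk values.
#' @param bounds boundaries from [decile_bounds()].
#' @return integer groups in 1..10.
#' @export
assign_decile <- function(x, bounds) {
  findInterval(x, bounds, left.open = TRUE) + 1L
}

#' Assign every cow its maternal circumstance at conception
#'
#' A dam lactation is concurrent when it is open on the cow's conception day
#' (calving <= conception < calving + length). `lact_group` is 0 when no
#' lactation is open (heifer dam), otherwise the open lactation's parity
#' capped at 3. For lactating dams, the dam's daily milk on the conception
#' day is interpolated from the 305-d total of the open lactation with
#' [wood_daily()] and classified against the population decile boundaries;
#' non-lactating dams have `yield_group` 0. Mastitis exposure is any dam
#' somatic-cell test above `threshold` inside the gestation window.
#'
#' @param cows filtered cow table (needs `cow_id`, `dam_id`,
#'   `conception_date`).
#' @param lactations lactation records of the dams.
#' @param scc somatic-cell test table (`cow_id`, `test_date`, `scc`).
#' @param pedigree optional pedigree with `birth_date`; when present,
#'   conceptions before the dam's birth raise an error.
#' @param bounds decile boundaries; computed from the data when `NULL`.
#' @param threshold somatic-cell count defining a mastitis episode, cells/ml.
#' @param window gestation exposure window in days after conception.
#' @param wood Wood curve shape parameters, as in [sim_config()].
#' @return data.frame `(cow_id, lact_group, yield_group, mastitis,
#'   dam_daily_milk)` with attribute `"bounds"`.
#' @export
assign_circumstance <- function(cows, lactations, scc, pedigree = NULL,
                                bounds = NULL, threshold = 4e5,
                                window = c(0, 220),
                                wood = c(b = 0.2, c = 0.004)) {
  if (!is.null(pedigree) && "birth_date" %in% names(pedigree)) {
    db <- pedigree$birth_date[match(cows$dam_id, pedigree$id)]
    bad <- !is.na(db) & cows$conception_date < db
    if (any(bad))
      stop("conception before the dam's birth for cow ",
           cows$cow_id[which(bad)[1]])
  }
  m <- merge(
    data.frame(cow_id = cows$cow_id, dam_id = cows$dam_id,
               conception = cows$conception_date, stringsAsFactors = FALSE),
    lactations, by.x = "dam_id", by.y = "cow_id")
  open <- m$calving_date <= m$conception &
    m$conception < m$calving_date + m$length_d
  m <- m[open, , drop = FALSE]
  pos <- match(cows$cow_id, m$cow_id)
  lact_group <- ifelse(is.na(pos), 0L, pmin(m$parity[pos], 3L))
  dim_at_conc <- m$conception[pos] - m$calving_date[pos]
  daily <- ifelse(is.na(pos), NA_real_,
                  wood_daily(dim_at_conc, m$my305[pos],
                             wood["b"], wood["c"]))
  lactating <- lact_group > 0
  if (is.null(bounds)) {
    # with fewer lactating dams than decile groups the classification
    # degenerates to a single group
    bounds <- if (sum(lactating) >= 10) decile_bounds(daily[lactating])
      else numeric(0)
  }
  yield_group <- integer(nrow(cows))
  yield_group[lactating] <- assign_decile(daily[lactating], bounds)

  ms <- merge(
    data.frame(cow_id = cows$cow_id, dam_id = cows$dam_id,
               conception = cows$conception_date, stringsAsFactors = FALSE),
    scc, by.x = "dam_id", by.y = "cow_id")
  hit <- ms$scc > threshold &
    ms$test_date >= ms$conception + window[1] &
    ms$test_date <= ms$conception + window[2]
  mast_ids <- unique(ms$cow_id[hit])
  out <- data.frame(cow_id = cows$cow_id,
                    lact_group = as.integer(lact_group),
                    yield_group = as.integer(yield_group),
                    mastitis = as.integer(cows$cow_id %in% mast_ids),
                    dam_daily_milk = daily,
                    stringsAsFactors = FALSE)
  attr(out, "bounds") <- bounds
  out
}
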