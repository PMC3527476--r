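make_cows <- function(n = 4) {
  data.frame(
    cow_id = sprintf("c%02d", seq_len(n)),
    sire_id = "s1", dam_id = sprintf("d%02d", seq_len(n)),
    birth_date = 1000, conception_date = 718,
    herd = 1, region = 1, calving1_date = 1800,
    age_first_parity_mo = 26, length1_d = 305,
    milk_kg = 8000, fat_kg = 300, prot_kg = 256,
    dim_life = 1000, abortion = 0, stringsAsFactors = FALSE)
}
make_ped <- function(cows) {
  order_pedigree(data.frame(id = cows$cow_id, sire = cows$sire_id,
                            dam = cows$dam_id))
}

test_that("record filters exclude and log the right cows, idempotently", {
  cows <- make_cows(5)
  cows$milk_kg[2] <- 900          # stopped milking before 1,000 kg
  cows$abortion[3] <- 1
  cows$dam_id[4] <- "0"           # unknown dam
  lact <- data.frame(cow_id = cows$dam_id[c(1, 2, 3)], parity = 1,
                     calving_date = 600, length_d = 300, my305 = 8000)
  ped <- make_ped(make_cows(5))
  out <- apply_filters(cows, lact, ped)
  expect_equal(out$cows$cow_id, "c01")
  lg <- setNames(out$log$rule, out$log$cow_id)
  expect_equal(unname(lg["c02"]), "below_1000kg")
  expect_equal(unname(lg["c03"]), "abortion")
  expect_equal(unname(lg["c04"]), "unknown_pedigree")
  expect_equal(unname(lg["c05"]), "dam_unrecorded")

  twice <- apply_filters(out$cows, lact, ped)
  expect_identical(twice$cows, out$cows)
  expect_equal(nrow(twice$log), 0)

  empty <- apply_filters(cows[0, ], lact, ped)
  expect_equal(nrow(empty$cows), 0)
  expect_equal(nrow(empty$log), 0)
})

test_that("305-d standardization is the linear rescaling with a length cap", {
  expect_equal(standardize_305(8000, 305), 8000)
  expect_equal(standardize_305(4000, 152.5), 8000)
  # constant daily yield: standardized total is exactly 305 * daily yield
  daily <- 27.3
  len <- c(180, 305, 410)
  expect_equal(standardize_305(daily * len, len), rep(305 * daily, 3))
  # beyond the cap the scaling freezes at the capped length
  expect_equal(standardize_305(9000, 500, max_length = 450),
               9000 * 305 / 450)
  expect_error(standardize_305(100, 0), "length")
})

test_that("decile boundaries follow the interpolated-quantile definition", {
  b <- decile_bounds(1:100)
  expect_equal(b, seq(10.9, 90.1, by = 9.9))
  g <- assign_decile(1:100, b)
  expect_equal(as.vector(table(g)), rep(10L, 10))
  expect_true(all(diff(b) >= 0))
  expect_error(decile_bounds(1:9), "at least 10")

  # all-tied values: degenerate boundaries, everything in group 1
  expect_equal(unique(assign_decile(rep(7, 50), decile_bounds(rep(7, 50)))),
               1L)
})

test_that("a Table-2-like population reproduces the printed boundaries", {
  printed <- c(22, 25.8, 28, 30, 32, 34, 36, 38.5, 42.4)
  lo <- c(5, printed)
  hi <- c(printed, 60)
  set.seed(42)
  vals <- unlist(lapply(1:10, function(k)
    runif(3000, lo[k], hi[k])))
  b <- decile_bounds(vals)
  expect_lt(max(abs(b - printed)), 0.5)
})

test_that("maternal circumstance assignment follows the printed conventions", {
  bounds <- c(22, 25.8, 28, 30, 32, 34, 36, 38.5, 42.4)
  # right-closed groups: a dam at exactly 22 kg/d falls in group 1,
  # one at 31 kg/d in group 5
  expect_equal(assign_decile(c(22, 31), bounds), c(1L, 5L))

  cows <- make_cows(2)
  # dam of c01 lactating at conception (calving 600 <= 718 < 600+300);
  # dam of c02 calves only after the conception day
  lact <- data.frame(cow_id = c("d01", "d02"), parity = c(2, 1),
                     calving_date = c(600, 900), length_d = 300,
                     my305 = 8000)
  scc <- data.frame(cow_id = "d01", test_date = 800, scc = 5e5)
  circ <- assign_circumstance(cows, lact, scc)
  expect_equal(circ$lact_group, c(2L, 0L))
  expect_equal(circ$yield_group[2], 0L)
  expect_equal(circ$mastitis, c(1L, 0L))
  expect_equal(circ$dam_daily_milk[1],
               wood_daily(718 - 600, 8000))

  # an SCC spike outside the 220-d gestation window is not an exposure
  scc2 <- data.frame(cow_id = "d01", test_date = 718 + 240, scc = 5e5)
  expect_equal(assign_circumstance(cows, lact, scc2)$mastitis, c(0L, 0L))

  # conception before the dam's birth is a hard error
  ped <- order_pedigree(data.frame(id = c("d01", "d02", "c01", "c02"),
                                   sire = "0", dam = c("0", "0", "d01", "d02")))
  ped$birth_date <- c(800, 100, 1000, 1000)
  expect_error(assign_circumstance(cows, lact, scc, pedigree = ped),
               "before the dam's birth")
})

test_that("every retained cow gets exactly one circumstance row", {
  herd <- smoke_herd()
  flt <- apply_filters(herd$cows, herd$lactations, herd$pedigree)
  circ <- assign_circumstance(flt$cows, herd$lactations, herd$scc,
                              herd$pedigree,
                              threshold = herd$config$scc_threshold,
                              wood = herd$config$wood)
  expect_equal(circ$cow_id, flt$cows$cow_id)
  expect_equal(sum(table(circ$lact_group)), nrow(flt$cows))
  expect_true(all(diff(attr(circ, "bounds")) >= 0))
})
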