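# shared fixture builders for the test suite; everything is generated in code

# random valid pedigree: first n0 founders, later individuals draw parents
# among earlier individuals (possibly unknown)
random_pedigree <- function(n, n0 = max(10, n %/% 5), p_known = 0.9,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sire <- dam <- rep("0", n)
  ids <- sprintf("i%04d", seq_len(n))
  for (i in (n0 + 1):n) {
    if (runif(1) < p_known) sire[i] <- ids[sample.int(i - 1, 1)]
    if (runif(1) < p_known) {
      repeat {
        d <- ids[sample.int(i - 1, 1)]
        if (d != sire[i]) break
      }
      dam[i] <- d
    }
  }
  order_pedigree(data.frame(id = ids, sire = sire, dam = dam))
}

# gene-dropping Monte-Carlo oracle for inbreeding: founders receive unique
# allele labels, alleles propagate down the ordered pedigree, F is the
# probability that an individual's two alleles are identical by descent
gene_drop_F <- function(ped, ndrops = 5e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ix <- ped_indices(ped)
  s <- ix$sire + 1L; d <- ix$dam + 1L
  n <- nrow(ped)
  A1 <- vector("list", n); A2 <- vector("list", n)
  draw <- function(p, self) {
    if (p == 0) return(rep.int(self, ndrops))
    pick <- runif(ndrops) < 0.5
    ifelse(pick, A1[[p]], A2[[p]])
  }
  for (i in seq_len(n)) {
    A1[[i]] <- draw(s[i], 2L * i - 1L)
    A2[[i]] <- draw(d[i], 2L * i)
  }
  vapply(seq_len(n), function(i) mean(A1[[i]] == A2[[i]]), 0)
}

# minimal phenotype table for stage-1 models on an all-founder pedigree
founder_pheno <- function(y, ids = sprintf("i%04d", seq_along(y))) {
  data.frame(cow_id = ids, my = y, fp = rep(1, length(y)),
             dim_life = rep(1, length(y)),
             age_bin = "a", year_region = "r", herd_year = "h",
             dam_id = "0", stringsAsFactors = FALSE)
}

founder_ped <- function(n, ids = sprintf("i%04d", seq_len(n))) {
  order_pedigree(data.frame(id = ids, sire = "0", dam = "0"))
}

# small smoke-scale herd shared by several tests (cached per session)
smoke_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_herd(sim_config("smoke"), seed = 11)
    cache
  }
})
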