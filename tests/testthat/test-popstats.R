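# One dominant vote per covered sample, pooled over a population.

# 10 samples at one position: k vote the alt, the rest vote the reference.
vote_fixture <- function(n = 10L, k = 2L, ref = "A", alt = "G",
                         reads = 4L) {
  spec <- data.frame(chrom = "chr1", pos = 1L, ref = ref,
                     sample = sprintf("s%02d", 1:n),
                     A = 0L, C = 0L, G = 0L, T = 0L)
  spec[[ref]] <- c(rep(reads, n - k), rep(0L, k))
  spec[[alt]] <- c(rep(0L, n - k), rep(reads, k))
  make_pileup(spec)
}

test_that("population statistics are equal-weight dominant votes", {
  pu <- vote_fixture(n = 10L, k = 2L)
  cdps <- extract_cdps(pu)
  units <- build_units(pu)
  st <- population_stats(cdps, units, population_id = "P")
  expect_equal(nrow(st$stats), 1L)
  expect_equal(st$stats$n_covered, 10L)
  expect_equal(st$stats$major, "A")
  expect_equal(st$stats$major_prob, 0.8)
  expect_equal(st$stats$vG / st$stats$n_covered, 0.2)
  expect_equal(st$stats$pop_comentropy, comentropy(c(0.8, 0.2)))

  # equal weighting: multiplying one sample's read counts by 10 changes
  # nothing downstream of its dominant vote
  pu10 <- vote_fixture(n = 10L, k = 2L)
  cols <- c("A", "C", "G", "T", "depth")
  for (j in cols) {
    data.table::set(pu10$calls, 1L, j, pu10$calls[[j]][1L] * 10L)
  }
  st10 <- population_stats(extract_cdps(pu10), build_units(pu10),
                           population_id = "P")
  expect_equal(st10$stats$major_prob, st$stats$major_prob)
  expect_equal(st10$stats$vA, st$stats$vA)

  # all units failing the filter: position not estimable
  spec <- data.frame(chrom = "chr1", pos = 1L, ref = "A",
                     sample = c("s1", "s2"), A = c(1L, 1L), G = c(1L, 1L))
  pu2 <- make_pileup(spec)
  st2 <- population_stats(extract_cdps(pu2), build_units(pu2))
  expect_equal(nrow(st2$stats), 0L)

  # unknown sample in the population spec is a configuration error
  expect_error(population_stats(cdps, units, population = c("s01", "zz")),
               "absent from the manifest")
})

test_that("union population statistics equal statistics on the pooled sample set", {
  set.seed(17)
  ref <- c(chr1 = rand_dna(3000))
  pos <- seq(100L, 2900L, by = 200L)
  alts <- vapply(pos, function(p) setdiff(NUCS, substr(ref[1], p, p))[1], "")
  cfg <- simulation_config(seed = 18, n_samples = 24, reference = ref,
                           snvs = data.frame(chrom = "chr1", pos = pos,
                                             alt = alts,
                                             freq = rep(c(0.2, 0.5, 0.9),
                                                        5)))
  sim <- simulate_pileup(cfg)
  cdps <- extract_cdps(sim$pileup)
  units <- build_units(sim$pileup)
  chb <- sim$samples[1:10]
  chs <- sim$samples[11:24]
  chn1 <- population_stats(cdps, units, c(chb, chs), population_id = "CHN")
  chn2 <- population_stats(cdps, units, sim$samples, population_id = "CHN")
  expect_identical(as.data.frame(chn1$stats), as.data.frame(chn2$stats))
  expect_identical(as.data.frame(chn1$indels), as.data.frame(chn2$indels))
})

test_that("the four circumstances classify as specified, with inclusive boundaries", {
  cfg <- classification_config()
  # circumstance one: major allele differs from the reference
  r <- classify(c(G = 10L), ref_base = "A", config = cfg)
  expect_equal(r$categories, "MAJOR_DIFF")
  expect_true(r$in_mair)
  expect_equal(r$major_prob, 1.0)

  # circumstance four: minor allele at no more than 5% (4% here)
  r <- classify(c(A = 96L, G = 4L), ref_base = "A", config = cfg)
  expect_equal(r$categories, "RARE")
  expect_false(r$in_mair)

  # circumstance three: minor allele at more than 5% (10%)
  r <- classify(c(A = 90L, G = 10L), ref_base = "A", config = cfg)
  expect_equal(r$categories, "MINOR_COMMON")

  # the 5% boundary belongs to RARE (inclusive)
  r <- classify(c(A = 95L, G = 5L), ref_base = "A", config = cfg)
  expect_equal(r$categories, "RARE")

  # circumstance two: indel at no less than 50% of covered samples
  r <- classify(c(A = 10L), ref_base = "A", indel_probs = 0.6, config = cfg)
  expect_equal(r$categories, "INDEL_HIGH")
  expect_true(r$in_mair)
  r <- classify(c(A = 10L), ref_base = "A", indel_probs = 0.5, config = cfg)
  expect_equal(r$categories, "INDEL_HIGH")
  r <- classify(c(A = 10L), ref_base = "A", indel_probs = 0.49, config = cfg)
  expect_null(r)

  # static position: nothing applies
  expect_null(classify(c(A = 10L), ref_base = "A", config = cfg))

  # categories may co-occur
  r <- classify(c(G = 90L, C = 6L, T = 4L), ref_base = "A",
                indel_probs = 0.7, config = cfg)
  expect_setequal(r$categories,
                  c("MAJOR_DIFF", "INDEL_HIGH", "MINOR_COMMON", "RARE"))
})

test_that("vectorised classification, MAIR and rare extraction are consistent", {
  # hand-built population: 20 covered samples per position
  mk <- function(pos, ref, votes, indel = NULL) {
    n <- sum(votes)
    sm <- sprintf("s%02d", 1:n)
    spec <- do.call(rbind, lapply(seq_along(sm), function(i) {
      b <- rep(names(votes), votes)[i]
      d <- data.frame(chrom = "chr1", pos = pos, ref = ref, sample = sm[i],
                      A = 0L, C = 0L, G = 0L, T = 0L)
      d[[b]] <- 5L
      d
    }))
    spec
  }
  spec <- rbind(mk(10L, "A", c(G = 20L)),              # MAJOR_DIFF
                mk(20L, "C", c(C = 19L, T = 1L)),      # RARE (5%)
                mk(30L, "G", c(G = 16L, A = 4L)),      # MINOR_COMMON (20%)
                mk(40L, "T", c(T = 20L)))              # static w/ indel
  ind <- data.frame(chrom = "chr1", pos = 40L,
                    sample = sprintf("s%02d", 1:12), kind = "deletion",
                    seq = "", len = 2L, count = 1L)
  pu <- make_pileup(spec, indels = ind)
  st <- population_stats(extract_cdps(pu), build_units(pu),
                         population_id = "P")
  dyn <- classify_positions(st)
  p <- dyn$positions
  expect_equal(p[p$pos == 10L]$categories, "MAJOR_DIFF")
  expect_equal(p[p$pos == 20L]$categories, "RARE")
  expect_equal(p[p$pos == 30L]$categories, "MINOR_COMMON")
  expect_equal(p[p$pos == 40L]$categories, "INDEL_HIGH")  # 12/20 = 60%
  expect_equal(p$in_mair, p$major_diff | p$indel_high)

  mair <- compute_mair(dyn)
  expect_equal(nrow(mair), 2L)
  expect_equal(mair[mair$kind == "substitution"]$payload, "G")
  expect_equal(mair[mair$kind == "deletion"]$population_prob, 0.6)

  rare <- extract_rare(dyn)
  expect_equal(nrow(rare), 1L)
  expect_equal(rare$allele, "T")
  expect_equal(rare$frequency, 0.05)

  # every classified position came from the candidate set
  expect_true(all(paste(p$chrom, p$pos) %in%
                    paste(extract_cdps(pu)$keys$chrom,
                          extract_cdps(pu)$keys$pos)))

  # empty stream -> empty rare table
  expect_equal(nrow(extract_rare(classify_positions(
    population_stats(extract_cdps(vote_fixture(k = 0L)),
                     build_units(vote_fixture(k = 0L)))))), 0L)
})

test_that("frequencies referenced by categories satisfy the configured inequalities", {
  set.seed(23)
  ref <- c(chr1 = rand_dna(5000))
  pos <- seq(50L, 4950L, by = 100L)
  alts <- vapply(pos, function(p) setdiff(NUCS, substr(ref[1], p, p))[1], "")
  cfg <- simulation_config(seed = 23, n_samples = 30, reference = ref,
                           error_rate = 0.005,
                           snvs = data.frame(chrom = "chr1", pos = pos,
                                             alt = alts,
                                             freq = stats::runif(length(pos),
                                                                 0.05, 1)))
  sim <- simulate_pileup(cfg)
  st <- population_stats(extract_cdps(sim$pileup), build_units(sim$pileup))
  ccfg <- classification_config()
  dyn <- classify_positions(st, ccfg)
  al <- dyn$alleles
  expect_true(all(al$frequency[al$class == "rare"] <= ccfg$rare_max))
  expect_true(all(al$frequency[al$class == "common"] > ccfg$minor_min))
  expect_true(all(al$frequency > 0))
  p <- dyn$positions
  expect_true(all(p$major_prob > 0 & p$major_prob <= 1))
  # partition sanity: rare flag iff a rare-class allele exists at the position
  rare_pos <- unique(al[al$class == "rare", paste(chrom, pos)])
  expect_setequal(paste(p$chrom, p$pos)[p$rare], rare_pos)
})
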