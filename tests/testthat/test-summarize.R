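# Reports over classified positions: counts, histograms, comparisons,
# codon effects and catalog hits.

# Build a dynamic_positions object directly (report inputs, not pipeline).
mk_dyn <- function(positions, indels = NULL, alleles = NULL, pop = "P") {
  pos_cols <- data.table::data.table(
    population = pop, chrom = positions$chrom, pos = positions$pos,
    ref = positions$ref, major = positions$major,
    major_prob = positions$major_prob %||% 1.0,
    n_covered = positions$n_covered %||% 10L,
    major_diff = positions$major_diff %||% FALSE,
    indel_high = positions$indel_high %||% FALSE,
    minor_common = positions$minor_common %||% FALSE,
    rare = positions$rare %||% FALSE)
  pos_cols[, `:=`(categories = paste0(
    ifelse(major_diff, "MAJOR_DIFF,", ""),
    ifelse(indel_high, "INDEL_HIGH,", ""),
    ifelse(minor_common, "MINOR_COMMON,", ""),
    ifelse(rare, "RARE", "")),
    in_mair = major_diff | indel_high)]
  ind <- if (is.null(indels)) {
    data.table::data.table(population = character(0), chrom = character(0),
                           pos = integer(0), kind = character(0),
                           seq = character(0), len = integer(0),
                           support = integer(0),
                           population_prob = numeric(0), high = logical(0))
  } else {
    data.table::data.table(population = pop, chrom = indels$chrom,
                           pos = indels$pos, kind = indels$kind,
                           seq = indels$seq, len = indels$len,
                           support = indels$support %||% 5L,
                           population_prob = indels$population_prob,
                           high = indels$population_prob >= 0.5)
  }
  al <- if (is.null(alleles)) {
    data.table::data.table(population = character(0), chrom = character(0),
                           pos = integer(0), allele = character(0),
                           frequency = numeric(0), class = character(0))
  } else {
    data.table::data.table(population = pop, chrom = alleles$chrom,
                           pos = alleles$pos, allele = alleles$allele,
                           frequency = alleles$frequency,
                           class = ifelse(alleles$frequency <= 0.05,
                                          "rare", "common"))
  }
  structure(list(positions = pos_cols, alleles = al, indels = ind,
                 population_id = pop),
            class = "dynamic_positions")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("population summaries split by chromosome class and respect histogram rules", {
  empty <- mk_dyn(data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), major = character(0)))
  s0 <- summarize_population(empty)
  expect_equal(s0$counts[s0$counts$class == "total"]$dynamic_positions, 0L)
  expect_equal(sum(s0$prob_hist$count), 0L)

  dyn <- mk_dyn(
    data.frame(chrom = c("1", "2", "X"), pos = c(10L, 20L, 30L),
               ref = "A", major = "G",
               major_prob = c(1.0, 0.62, 0.97), major_diff = TRUE),
    indels = data.frame(chrom = c("1", "MT"), pos = c(40L, 50L),
                        kind = c("insertion", "deletion"),
                        seq = c("AG", ""), len = c(2L, 3L),
                        population_prob = c(0.8, 0.4)))
  s <- summarize_population(dyn)
  cnt <- s$counts
  expect_equal(cnt[cnt$class == "autosome"]$dynamic_positions, 2L)
  expect_equal(cnt[cnt$class == "heterosome"]$dynamic_positions, 1L)
  # only the >50% indel enters the indel count and length histogram
  expect_equal(cnt[cnt$class == "total"]$indels, 1L)
  expect_equal(s$indel_length_hist$len, 2L)
  expect_equal(s$indel_length_hist$kind, "insertion")
  # class splits sum to totals; histogram counts sum to category totals
  expect_equal(sum(cnt[cnt$class != "total"]$dynamic_positions),
               cnt[cnt$class == "total"]$dynamic_positions)
  expect_equal(sum(s$prob_hist$count), 3L)
  # 0.62 falls in the (0.60, 0.65] bin
  b <- s$prob_hist[abs(s$prob_hist$bin_low - 0.60) < 1e-9]
  expect_equal(b$count, 1L)
})

test_that("population intersections split shared sites into same and different alleles", {
  a <- mk_dyn(data.frame(chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A",
                         major = c("G", "G", "T", "C"), major_diff = TRUE),
              pop = "A")
  b <- mk_dyn(data.frame(chrom = "1", pos = c(2L, 3L, 9L), ref = "A",
                         major = c("G", "C", "G"), major_diff = TRUE),
              pop = "B")
  r <- intersect_populations(a, b, "major")
  expect_equal(r$a_only, 2L)
  expect_equal(r$b_only, 1L)
  expect_equal(r$shared, 2L)
  expect_equal(r$same, 1L)   # pos 2 both G
  expect_equal(r$diff, 1L)   # pos 3 T vs C
  expect_equal(r$same + r$diff, r$shared)

  # symmetry up to swapping only-counts
  rr <- intersect_populations(b, a, "major")
  expect_equal(rr$a_only, r$b_only)
  expect_equal(rr$shared, r$shared)
  expect_equal(rr$same, r$same)

  # identical sets: full intersection; disjoint: none
  r2 <- intersect_populations(a, a, "dynamic")
  expect_equal(r2$shared, 4L)
  expect_equal(r2$a_only + r2$b_only, 0L)
  d <- mk_dyn(data.frame(chrom = "1", pos = 99L, ref = "A", major = "G",
                         major_diff = TRUE), pop = "D")
  expect_equal(intersect_populations(a, d, "dynamic")$shared, 0L)

  # indels: "same" requires identical kind and sequence/length
  ia <- mk_dyn(data.frame(chrom = "1", pos = 1L, ref = "A", major = "A"),
               indels = data.frame(chrom = "1", pos = c(5L, 6L),
                                   kind = c("insertion", "deletion"),
                                   seq = c("AG", ""), len = c(2L, 1L),
                                   population_prob = 0.9), pop = "A")
  ib <- mk_dyn(data.frame(chrom = "1", pos = 1L, ref = "A", major = "A"),
               indels = data.frame(chrom = "1", pos = c(5L, 6L),
                                   kind = c("insertion", "deletion"),
                                   seq = c("CC", ""), len = c(2L, 1L),
                                   population_prob = 0.9), pop = "B")
  ri <- intersect_populations(ia, ib, "indel")
  expect_equal(ri$shared, 2L)
  expect_equal(ri$same, 1L)  # deletion of length 1 matches; insertion differs
  expect_equal(ri$diff, 1L)
})

test_that("codon effect tallies follow the genetic code on both strands", {
  #          123456789012
  ref <- c(chr1 = "ATGGGATGGTAA")  # M G W *
  ann <- data.frame(chrom = "chr1", start = 1L, end = 12L, strand = "+",
                    frame = 0L)
  mk_mair <- function(pos, alt) {
    data.table::data.table(chrom = "chr1", pos = pos, kind = "substitution",
                           ref = NA_character_, payload = alt, len = 1L,
                           population_prob = 1.0)
  }
  # ATG -> ATA : M -> I nonsynonymous
  r <- tally_effects(mk_mair(3L, "A"), ref, ann)
  expect_equal(r$details$effect, "nonsynonymous")
  # GGA -> GGG : synonymous
  r <- tally_effects(mk_mair(6L, "G"), ref, ann)
  expect_equal(r$details$effect, "synonymous")
  # TGG -> TGA : stop-gain
  r <- tally_effects(mk_mair(9L, "A"), ref, ann)
  expect_equal(r$details$effect, "stop-gain")
  # TAA -> CAA : stop-loss
  r <- tally_effects(mk_mair(10L, "C"), ref, ann)
  expect_equal(r$details$effect, "stop-loss")
  # missing frame -> unknown
  ann_nf <- transform(ann, frame = NA_integer_)
  r <- tally_effects(mk_mair(3L, "A"), ref, ann_nf)
  expect_equal(r$details$effect, "unknown")
  expect_equal(r$counts[r$counts$effect == "unknown"]$count, 1L)

  # minus strand: reference TTA CAT = reverse complement ATG TAA (M *)
  ref2 <- c(chr1 = "TTACAT")
  ann2 <- data.frame(chrom = "chr1", start = 1L, end = 6L, strand = "-",
                     frame = 0L)
  # ref pos 6 T -> C flips the coding codon ATG -> GTG : M -> V
  r <- tally_effects(mk_mair(6L, "C"), ref2, ann2)
  expect_equal(r$details$effect, "nonsynonymous")
  # TTA -> TTG is rc TAA -> CAA on the coding strand? (pos 2: TTA->TGA rc TCA: stop lost)
  r <- tally_effects(mk_mair(1L, "C"), ref2, ann2)
  # TTA -> CTA, rc = TAG : stop stays stop -> synonymous
  expect_equal(r$details$effect, "synonymous")
})

test_that("catalog hit counting uses 1-based inclusive overlap", {
  catalog <- data.frame(chrom = "chr1",
                        start = c(100L, 300L, 500L, 100L),
                        end = c(199L, 399L, 599L, 599L),
                        label = c("height", "height", "height", "bmi"))
  mk <- function(pos, kind = "substitution", len = 1L) {
    data.table::data.table(chrom = "chr1", pos = pos, kind = kind,
                           ref = NA_character_, payload = "G", len = len,
                           population_prob = 1.0)
  }
  # empty MAIR: zero hits everywhere
  r0 <- count_catalog_hits(mk(1L)[0], catalog)
  expect_equal(r0$hits, c(0L, 0L))

  # one edit inside one of three 'height' intervals
  r <- count_catalog_hits(mk(150L), catalog)
  expect_equal(r[r$label == "height"]$ratio, "1/3")
  expect_equal(r[r$label == "bmi"]$ratio, "1/1")

  # boundary: an edit exactly at an interval end still hits
  r <- count_catalog_hits(mk(199L), catalog)
  expect_equal(r[r$label == "height"]$hits, 1L)
  r <- count_catalog_hits(mk(200L), catalog)
  expect_equal(r[r$label == "height"]$hits, 0L)

  # a deletion's span is anchor+1 .. anchor+len
  r <- count_catalog_hits(mk(99L, kind = "deletion", len = 1L), catalog)
  expect_equal(r[r$label == "height"]$hits, 1L)
  r <- count_catalog_hits(mk(99L, kind = "substitution"), catalog)
  expect_equal(r[r$label == "height"]$hits, 0L)
})
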