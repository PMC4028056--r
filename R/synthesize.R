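# Seeded simulator of a diploid population sequenced at low coverage.
#
# Emulates the data regime the pipeline is designed for: N diploid samples
# at Poisson 2-4x coverage, planted SNV allele frequencies, planted
# indels, and a uniform per-base miscall rate. Genotypes are drawn at
# Hardy-Weinberg proportions (dosage ~ Binomial(2, f) per sample); each
# read at a heterozygous site picks one haplotype with equal probability.
# Indel sequencing errors and platform-specific error profiles are not
# modelled.

#' Simulation configuration
#'
#' Defaults mirror the target regime: mean per-sample depth 3 (low
#' coverage, 2-4x) and a 0.5% per-base miscall rate.
#'
#' @param seed integer RNG seed; the full run is reproducible given the
#'   seed.
#' @param n_samples number of diploid samples.
#' @param coverage_lambda mean per-sample read depth (Poisson).
#' @param error_rate per-base miscall probability; a miscalled read shows
#'   one of the three other nucleotides uniformly.
#' @param reference named character vector of sequences, or `NULL` to
#'   generate a uniform random sequence of length `ref_length`.
#' @param ref_length length of the generated reference (single chromosome
#'   `chr1`) when `reference` is `NULL`.
#' @param snvs data.frame `chrom, pos, alt, freq`: planted single
#'   nucleotide variants with population allele frequency `freq`.
#' @param indels data.frame `chrom, pos, kind` (insertion/deletion), `seq`
#'   (inserted sequence; for deletions the deleted length is `len`), `len`,
#'   `freq`.
#' @param populations named list of sample-index vectors (or sample-name
#'   vectors) partitioning or grouping the cohort; defaults to one
#'   population `ALL`.
#' @return A `simulation_config` list (validated).
#' @export
simulation_config <- function(seed, n_samples, coverage_lambda = 3,
                              error_rate = 0.005, reference = NULL,
                              ref_length = 10000L, snvs = NULL,
                              indels = NULL, populations = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_samples >= 1L, coverage_lambda > 0,
            error_rate >= 0, error_rate < 1)
  snvs <- if (is.null(snvs)) {
    data.table::data.table(chrom = character(0), pos = integer(0),
                           alt = character(0), freq = numeric(0))
  } else data.table::as.data.table(snvs)
  indels <- if (is.null(indels)) {
    data.table::data.table(chrom = character(0), pos = integer(0),
                           kind = character(0), seq = character(0),
                           len = integer(0), freq = numeric(0))
  } else data.table::as.data.table(indels)
  if (nrow(snvs)) {
    stopifnot(all(snvs$freq > 0), all(snvs$freq <= 1),
              all(toupper(snvs$alt) %in% NUCS))
    snvs[, `:=`(pos = as.integer(pos))]
  }
  if (nrow(indels)) {
    stopifnot(all(indels$freq > 0), all(indels$freq <= 1),
              all(indels$kind %in% c("insertion", "deletion")),
              all(indels$len >= 1L))
    indels[, `:=`(pos = as.integer(pos), len = as.integer(len))]
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 coverage_lambda = coverage_lambda, error_rate = error_rate,
                 reference = reference, ref_length = as.integer(ref_length),
                 snvs = snvs, indels = indels, populations = populations),
            class = "simulation_config")
}

# run expr under a private RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a multi-sample pileup from a planted truth
#'
#' Per sample and position, depth is Poisson(`coverage_lambda`); each read
#' draws one of the sample's two haplotypes with equal probability and is
#' miscalled to a uniformly chosen other base with probability
#' `error_rate`. Reads on haplotypes carrying an indel emit the indel
#' event at its anchor base; haplotypes carrying a deletion additionally
#' show deleted-base placeholders (no nucleotide) at the deleted
#' positions. Identical seed and configuration reproduce the output
#' exactly.
#'
#' @param config a [simulation_config()].
#' @return A `vcg_sim` list: `pileup` (a `pileup` object), `reference`
#'   (named character), `truth` (list with `variants` — per planted
#'   variant the drawn per-sample dosages — and `coverage`, realized mean
#'   depth per sample), `samples`, `populations`, `config`.
#' @export
simulate_pileup <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    reference <- config$reference
    if (is.null(reference)) {
      reference <- c(chr1 = paste(sample(NUCS, config$ref_length,
                                         replace = TRUE), collapse = ""))
    }
    reference <- toupper(reference)
    nS <- config$n_samples
    samples <- sprintf("S%03d", seq_len(nS))

    snvs <- data.table::copy(config$snvs)
    indels <- data.table::copy(config$indels)
    for (v in list(snvs, indels)) {
      if (nrow(v)) {
        if (any(!v$chrom %in% names(reference))) {
          stop("planted variant on unknown chromosome", call. = FALSE)
        }
        refb <- substr(reference[v$chrom], v$pos, v$pos)
        if (any(refb == "N")) {
          stop("planted variant at reference 'N' position", call. = FALSE)
        }
        if (any(v$pos < 1L | v$pos > nchar(reference[v$chrom]))) {
          stop("planted variant outside the reference", call. = FALSE)
        }
      }
    }
    if (nrow(snvs)) {
      snvs[, `:=`(ref = substr(reference[chrom], pos, pos),
                  alt = toupper(alt))]
      if (any(snvs$alt == snvs$ref)) {
        stop("planted SNV alt equals the reference base", call. = FALSE)
      }
    }
    # no overlap between deletion spans and other planted variants
    if (nrow(indels)) {
      del <- indels[indels$kind == "deletion"]
      if (nrow(del) && nrow(snvs)) {
        for (i in seq_len(nrow(del))) {
          if (any(snvs$chrom == del$chrom[i] & snvs$pos > del$pos[i] &
                    snvs$pos <= del$pos[i] + del$len[i])) {
            stop("planted SNV inside a planted deletion span", call. = FALSE)
          }
        }
      }
    }

    # dosages: variants x samples
    dos_snv <- if (nrow(snvs)) {
      matrix(stats::rbinom(nrow(snvs) * nS, 2L, rep(snvs$freq, nS)),
             nrow = nrow(snvs), ncol = nS)
    } else matrix(0L, 0L, nS)
    dos_ind <- if (nrow(indels)) {
      matrix(stats::rbinom(nrow(indels) * nS, 2L, rep(indels$freq, nS)),
             nrow = nrow(indels), ncol = nS)
    } else matrix(0L, 0L, nS)

    calls_l <- vector("list", length(reference))
    ind_l <- list()
    cov_sum <- numeric(nS)
    cov_n <- 0L
    for (ci in seq_along(reference)) {
      ch <- names(reference)[ci]
      L <- nchar(reference[[ci]])
      refv <- strsplit(reference[[ci]], "", fixed = TRUE)[[1]]
      depth <- matrix(stats::rpois(L * nS, config$coverage_lambda),
                      nrow = L, ncol = nS)
      cov_sum <- cov_sum + colMeans(depth)
      cov_n <- cov_n + 1L
      # start with all reads on the reference base
      nref <- depth
      altbase <- rep(NA_character_, L)
      nalt <- matrix(0L, nrow = L, ncol = nS)

      sv <- snvs[snvs$chrom == ch]
      if (nrow(sv)) {
        svi <- which(snvs$chrom == ch)
        for (k in seq_along(svi)) {
          p <- snvs$pos[svi[k]]
          d <- depth[p, ]
          na <- stats::rbinom(nS, d, dos_snv[svi[k], ] / 2)
          nalt[p, ] <- na
          nref[p, ] <- d - na
          altbase[p] <- snvs$alt[svi[k]]
        }
      }
      # sequencing errors: each read miscalls independently; a miscall on an
      # alt read can land on the reference base and vice versa
      counts <- array(0L, dim = c(L, nS, 4L), dimnames = list(NULL, NULL, NUCS))
      refm <- match(refv, NUCS)
      err <- config$error_rate
      add_reads <- function(nmat, base_idx) {
        # nmat reads carry true base base_idx (vector over positions)
        if (err > 0) {
          nerr <- matrix(stats::rbinom(length(nmat), as.vector(nmat), err),
                         nrow = nrow(nmat))
          ngood <- nmat - nerr
        } else {
          nerr <- matrix(0L, nrow(nmat), ncol(nmat))
          ngood <- nmat
        }
        for (s in seq_len(nS)) {
          ok <- !is.na(base_idx) & ngood[, s] > 0L
          ii <- which(ok)
          if (length(ii)) {
            idx <- cbind(ii, s, base_idx[ii])
            counts[idx] <<- counts[idx] + ngood[ii, s]
          }
          ee <- which(nerr[, s] > 0L & !is.na(base_idx))
          for (p in ee) {
            others <- setdiff(1:4, base_idx[p])
            draw <- sample(others, nerr[p, s], replace = TRUE)
            for (b in draw) counts[p, s, b] <<- counts[p, s, b] + 1L
          }
        }
      }
      add_reads(nref, refm)
      if (any(nalt > 0L)) add_reads(nalt, match(altbase, NUCS))

      # indel events and deletion placeholders
      stars <- matrix(0L, nrow = L, ncol = nS)
      iv <- which(indels$chrom == ch)
      for (k in iv) {
        p <- indels$pos[k]
        d <- depth[p, ]
        nind <- stats::rbinom(nS, d, dos_ind[k, ] / 2)
        who <- which(nind > 0L)
        if (length(who)) {
          ind_l[[length(ind_l) + 1L]] <- data.table::data.table(
            chrom = ch, pos = p, sample = samples[who],
            kind = indels$kind[k],
            seq = if (indels$kind[k] == "insertion") toupper(indels$seq[k])
                  else substr(reference[[ci]], p + 1L, p + indels$len[k]),
            len = indels$len[k], count = nind[who])
        }
        if (indels$kind[k] == "deletion") {
          span <- (p + 1L):(p + indels$len[k])
          span <- span[span <= L]
          for (q in span) {
            nstar <- stats::rbinom(nS, depth[q, ], dos_ind[k, ] / 2)
            # deleted reads show a placeholder, not a nucleotide
            base_here <- refm[q]
            take <- pmin(nstar, counts[q, , base_here])
            counts[q, , base_here] <- counts[q, , base_here] - take
            stars[q, ] <- stars[q, ] + take
          }
        }
      }

      calls_l[[ci]] <- data.table::data.table(
        chrom = ch, pos = rep(seq_len(L), nS), ref = rep(refv, nS),
        sample = rep(samples, each = L), depth = as.vector(depth),
        A = as.vector(counts[, , 1L]), C = as.vector(counts[, , 2L]),
        G = as.vector(counts[, , 3L]), T = as.vector(counts[, , 4L]))
    }
    calls <- data.table::rbindlist(calls_l)
    data.table::setkey(calls, chrom, pos, sample)
    indel_tab <- if (length(ind_l)) data.table::rbindlist(ind_l) else
      .empty_pileup_indels()
    data.table::setkey(indel_tab, chrom, pos, sample)
    pu <- .pileup(samples, calls, indel_tab,
                  sum(nchar(reference)))

    truth_variants <- data.table::rbindlist(list(
      if (nrow(snvs)) data.table::data.table(
        chrom = snvs$chrom, pos = snvs$pos, type = "snv", ref = snvs$ref,
        alt = snvs$alt, len = 1L, freq = snvs$freq,
        carriers = rowSums(dos_snv > 0L), dosage_sum = rowSums(dos_snv)),
      if (nrow(indels)) data.table::data.table(
        chrom = indels$chrom, pos = indels$pos, type = indels$kind,
        ref = NA_character_,
        alt = ifelse(indels$kind == "insertion", toupper(indels$seq),
                     as.character(indels$len)),
        len = indels$len, freq = indels$freq,
        carriers = rowSums(dos_ind > 0L), dosage_sum = rowSums(dos_ind))))
    if (nrow(truth_variants) == 0L) {
      truth_variants <- data.table::data.table(
        chrom = character(0), pos = integer(0), type = character(0),
        ref = character(0), alt = character(0), len = integer(0),
        freq = numeric(0), carriers = integer(0), dosage_sum = integer(0))
    }
    populations <- config$populations
    if (is.null(populations)) populations <- list(ALL = samples)
    populations <- lapply(populations, function(p) {
      if (is.numeric(p)) samples[p] else p
    })
    structure(list(pileup = pu, reference = reference,
                   truth = list(variants = truth_variants,
                                dosages = list(snv = dos_snv, indel = dos_ind),
                                coverage = stats::setNames(cov_sum / cov_n,
                                                           samples)),
                   samples = samples, populations = populations,
                   config = config),
              class = "vcg_sim")
  })
}

#' @export
print.vcg_sim <- function(x, ...) {
  cat(sprintf("vcg_sim: %d samples, %d bp reference, %d planted variants (seed %d)\n",
              length(x$samples), sum(nchar(x$reference)),
              nrow(x$truth$variants), x$config$seed))
  invisible(x)
}

#' Write the artifacts of a simulation to disk
#'
#' Emits the multi-sample mpileup text, the reference FASTA and a truth
#' TSV; re-running with the same configuration reproduces the files
#' byte-for-byte.
#'
#' @param sim a `vcg_sim` from [simulate_pileup()].
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pileup = file.path(dir, "samples.pileup"),
             reference = file.path(dir, "reference.fa"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "samples.txt"))
  write_pileup(sim$pileup, paths[["pileup"]])
  write_fasta(sim$reference, paths[["reference"]])
  data.table::fwrite(sim$truth$variants, paths[["truth"]], sep = "\t")
  writeLines(sim$samples, paths[["manifest"]])
  invisible(paths)
}
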