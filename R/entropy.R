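# Per-(sample, position) units and the comentropy filter.
#
# A unit is one sample's nucleotide-count distribution at one position. Its
# comentropy H = -sum p_i log2 p_i measures how ambiguous the sample's read
# evidence is; units are retained only when H is at or below an
# arity-specific threshold, and only when they carry at least `min_reads`
# mapped nucleotides.

#' Unit filter configuration
#'
#' Thresholds are inclusive (a unit is retained when `H <= threshold`) and
#' are expressed in bits. Arity-1 units always pass: their comentropy is 0.
#'
#' @param min_reads minimum mapped nucleotide count for a unit to be
#'   considered at all (default 2).
#' @param max_h2,max_h3,max_h4 comentropy ceilings for binary, ternary and
#'   quaternary units (defaults 0.95, 1.50, 1.92 bits).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_reads = 2L, max_h2 = 0.95, max_h3 = 1.50,
                          max_h4 = 1.92) {
  min_reads <- as.integer(min_reads)
  stopifnot(min_reads >= 1L,
            max_h2 > 0, max_h2 <= 1,
            max_h3 > 0, max_h3 <= log2(3),
            max_h4 > 0, max_h4 <= 2)
  structure(list(min_reads = min_reads, max_h2 = max_h2, max_h3 = max_h3,
                 max_h4 = max_h4),
            class = "filter_config")
}

#' Shannon comentropy of a probability vector, in bits
#'
#' `H(x) = -sum_i p(x_i) log2 p(x_i)`, with `0 * log2(0)` defined as 0.
#'
#' @param probs non-negative numeric vector summing to 1 (tolerance 1e-9).
#' @return Entropy in bits.
#' @examples
#' comentropy(c(0.5, 0.5))   # 1 bit
#' comentropy(c(0.75, 0.25)) # 0.811278
#' @export
comentropy <- function(probs) {
  if (!is.numeric(probs) || any(probs < 0)) {
    stop("comentropy: probabilities must be non-negative", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("comentropy: probabilities must sum to 1", call. = FALSE)
  }
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

# threshold for a given arity (1..4) under a filter_config
.arity_threshold <- function(arity, config) {
  c(Inf, config$max_h2, config$max_h3, config$max_h4)[arity]
}

#' Build a unit from one sample's counts at one position
#'
#' Returns `NULL` when the total mapped nucleotide count is below
#' `config$min_reads`: such evidence is too thin to be considered. Deletion
#' placeholders and indel events contribute neither to the count total nor
#' to arity.
#'
#' @param counts named counts over `A/C/G/T` (a `sample_call$base_counts`
#'   vector, or any named integer vector; missing names count as 0), or a
#'   `sample_call` object.
#' @param chrom,pos,sample identifiers carried on the unit.
#' @param config a [filter_config()].
#' @param ref_base optional reference base, used for dominant-allele tie
#'   breaking.
#' @return A `vcg_unit` (list with `counts`, `depth`, `arity`, `probs`,
#'   `comentropy`, `passed`, ids) or `NULL`.
#' @export
build_unit <- function(counts, chrom = NA_character_, pos = NA_integer_,
                       sample = NA_character_, config = filter_config(),
                       ref_base = NA_character_) {
  if (inherits(counts, "sample_call")) counts <- counts$base_counts
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("build_unit: negative counts", call. = FALSE)
  total <- sum(full)
  if (total < config$min_reads) return(NULL)
  obs <- full[full > 0L]
  arity <- length(obs)
  probs <- obs / total
  h <- comentropy(probs)
  structure(list(chrom = chrom, pos = pos, sample = sample,
                 counts = obs, depth = total, arity = arity, probs = probs,
                 comentropy = h,
                 passed = h <= .arity_threshold(arity, config),
                 ref_base = toupper(ref_base)),
            class = "vcg_unit")
}

#' Does a unit pass the comentropy filter?
#'
#' True iff the unit's comentropy is at or below the threshold for its
#' arity; arity-1 units always pass.
#'
#' @param unit a `vcg_unit` from [build_unit()].
#' @param config a [filter_config()].
#' @return logical(1).
#' @export
passes_unit_filter <- function(unit, config = filter_config()) {
  stopifnot(inherits(unit, "vcg_unit"))
  unit$comentropy <= .arity_threshold(unit$arity, config)
}

#' Dominant nucleotide of a retained unit
#'
#' The nucleotide with the highest count. Ties are broken toward the
#' reference base when it is among the tied maxima, otherwise
#' alphabetically (A < C < G < T) — deterministic and conservative toward
#' the reference.
#'
#' @param unit a `vcg_unit` with `passed = TRUE`.
#' @param ref_base reference base for tie breaking; defaults to the one
#'   stored on the unit.
#' @return A single nucleotide.
#' @export
dominant_nucleotide <- function(unit, ref_base = unit$ref_base) {
  stopifnot(inherits(unit, "vcg_unit"))
  if (!isTRUE(unit$passed)) {
    stop("dominant_nucleotide: unit did not pass the comentropy filter",
         call. = FALSE)
  }
  mx <- max(unit$counts)
  tied <- sort(names(unit$counts)[unit$counts == mx])  # alphabetical
  if (!is.na(ref_base) && toupper(ref_base) %in% tied) return(toupper(ref_base))
  tied[1L]
}

#' Build and filter all units of a pileup (vectorised)
#'
#' @param pileup a `pileup` object from [read_pileup()] or [simulate_pileup()].
#' @param config a [filter_config()].
#' @param keep_failed keep units that fail the comentropy filter (flagged
#'   `passed = FALSE`) instead of dropping them.
#' @return data.table with one row per retained unit: `chrom, pos, ref,
#'   sample, A, C, G, T, depth` (mapped nucleotides), `arity, comentropy,
#'   passed, dominant`.
#' @export
build_units <- function(pileup, config = filter_config(), keep_failed = FALSE) {
  calls <- pileup$calls
  A <- C <- G <- T <- NULL
  cnts <- as.matrix(calls[, list(A, C, G, T)])
  total <- rowSums(cnts)
  keep <- total >= config$min_reads
  cnts <- cnts[keep, , drop = FALSE]
  total <- total[keep]
  ut <- calls[keep, list(chrom, pos, ref, sample)]
  arity <- rowSums(cnts > 0L)
  h <- numeric(nrow(cnts))
  for (j in 1:4) {
    p <- cnts[, j] / total
    nz <- p > 0
    h[nz] <- h[nz] - p[nz] * log2(p[nz])
  }
  h[arity == 1L] <- 0
  thr <- c(Inf, config$max_h2, config$max_h3, config$max_h4)[arity]
  passed <- h <= thr
  # dominant: highest count; ties -> reference if tied, else alphabetical
  mx <- pmax(cnts[, 1], cnts[, 2], cnts[, 3], cnts[, 4])
  is_max <- cnts == mx
  dom <- NUCS[max.col(is_max, ties.method = "first")]
  refm <- match(ut$ref, NUCS)
  ok <- !is.na(refm)
  ref_is_max <- ok
  ref_is_max[ok] <- is_max[cbind(which(ok), refm[ok])]
  dom[ref_is_max] <- ut$ref[ref_is_max]
  units <- data.table::data.table(
    ut, A = cnts[, 1], C = cnts[, 2], G = cnts[, 3], T = cnts[, 4],
    depth = total, arity = arity, comentropy = h, passed = passed,
    dominant = dom)
  if (!keep_failed) units <- units[units$passed]
  data.table::setkey(units, chrom, pos, sample)
  units[]
}
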