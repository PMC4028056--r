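# Two-step candidate dynamic position (CDP) extraction: step one builds a
# non-redundant list of positions with any non-reference evidence in at
# least one sample; step two restricts the per-sample evidence stream to
# those positions. Detection is maximally inclusive (a single mismatching
# read, or a single indel read, qualifies); all stringency lives downstream
# in the comentropy filter and the population statistics.

#' Is a pileup column a candidate dynamic position?
#'
#' TRUE iff any sample shows at least one read supporting a non-reference
#' nucleotide, or at least one insertion/deletion event, at this position.
#' Positions whose reference base is not one of A/C/G/T (e.g. `N`) are
#' never candidates.
#'
#' @param column a `pileup_column` from [pileup_column()].
#' @return logical(1).
#' @export
is_candidate <- function(column) {
  stopifnot(inherits(column, "pileup_column"))
  ref <- toupper(column$ref_base)
  if (!ref %in% NUCS) return(FALSE)
  for (sc in column$samples) {
    nonref <- sum(sc$base_counts) - sc$base_counts[[ref]]
    if (nonref > 0L) return(TRUE)
    if (nrow(sc$insertions) > 0L || nrow(sc$deletions) > 0L) return(TRUE)
  }
  FALSE
}

#' Extract the candidate dynamic position set from a pileup
#'
#' Single streaming pass over all samples simultaneously; the key set is
#' identical to the deduplicated union of per-sample scans (asserted by the
#' test suite).
#'
#' @param pileup a `pileup` object.
#' @return A `cdp_set`: list with `keys` (data.table `chrom, pos, ref`,
#'   unique, sorted), `records` (the input pileup restricted to candidate
#'   positions — calls and indels), `n_total` (positions scanned) and
#'   `n_cdps`.
#' @export
extract_cdps <- function(pileup) {
  calls <- pileup$calls
  refm <- match(calls$ref, NUCS)
  cnts <- as.matrix(calls[, list(A, C, G, T)])
  total <- rowSums(cnts)
  refcnt <- rep(0L, nrow(calls))
  ok <- !is.na(refm)
  refcnt[ok] <- cnts[cbind(which(ok), refm[ok])]
  mism <- ok & (total - refcnt > 0L)
  key_mism <- unique(calls[mism, list(chrom, pos, ref)])
  # indel evidence only counts at positions whose reference base is A/C/G/T
  refs <- unique(calls[, list(chrom, pos, ref)])
  key_ind <- unique(pileup$indels[, list(chrom, pos)])
  if (nrow(key_ind)) {
    key_ind <- merge(key_ind, refs, by = c("chrom", "pos"))
    key_ind <- key_ind[key_ind$ref %in% NUCS]
  } else {
    key_ind <- key_mism[0L]
  }
  keys <- unique(data.table::rbindlist(list(key_mism, key_ind)))
  data.table::setkey(keys, chrom, pos)
  sel <- data.table::data.table(chrom = keys$chrom, pos = keys$pos)
  rec_calls <- calls[sel, on = c("chrom", "pos"), nomatch = NULL]
  rec_ind <- pileup$indels[sel, on = c("chrom", "pos"), nomatch = NULL]
  records <- .pileup(pileup$samples, rec_calls, rec_ind, nrow(keys))
  structure(list(keys = keys[], records = records,
                 n_total = pileup$n_positions, n_cdps = nrow(keys)),
            class = "cdp_set")
}

#' @export
print.cdp_set <- function(x, ...) {
  cat(sprintf("cdp_set: %d candidate positions of %d scanned (reduction %.2f%%)\n",
              x$n_cdps, x$n_total,
              100 * reduction_ratio(x$n_total, x$n_cdps)))
  invisible(x)
}

#' Data-reduction ratio achieved by candidate extraction
#'
#' `1 - n_cdps / n_total`: the fraction of scanned positions discarded as
#' static.
#'
#' @param n_total number of positions scanned (> 0).
#' @param n_cdps number of candidate positions retained.
#' @return Fraction in `[0, 1]`.
#' @export
reduction_ratio <- function(n_total, n_cdps) {
  if (n_total <= 0) stop("reduction_ratio: n_total must be positive", call. = FALSE)
  if (n_cdps < 0 || n_cdps > n_total) {
    stop("reduction_ratio: need 0 <= n_cdps <= n_total", call. = FALSE)
  }
  1 - n_cdps / n_total
}

#' Export a CDP key set as BED
#'
#' Converts the package's 1-based inclusive positions to BED's 0-based
#' half-open intervals; a header comment records the convention.
#'
#' @param cdps a `cdp_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cdp_bed <- function(cdps, path) {
  writeLines("# candidate dynamic positions; 0-based half-open (converted from 1-based inclusive)",
             path)
  if (nrow(cdps$keys)) {
    bed <- data.table::data.table(chrom = cdps$keys$chrom,
                                  start = cdps$keys$pos - 1L,
                                  end = cdps$keys$pos,
                                  name = cdps$keys$ref)
    data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}
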