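# Virtual consensus genome construction: apply a MAIR edit set to the
# linear reference and keep a monotone reference->consensus coordinate map.
#
# Indel anchoring follows the pileup convention: an insertion is placed
# after its anchor base; a deletion of length L removes bases pos+1 ..
# pos+L. The consensus is a hard major-allele sequence — no ambiguity
# codes — so it remains usable as a template by standard aligners.

#' Resolve overlapping MAIR edits
#'
#' Two edits conflict when their occupied spans overlap: a substitution
#' occupies its own base; an insertion occupies the gap after its anchor; a
#' deletion occupies the gap after its anchor plus the deleted bases and
#' the gap after the last deleted base. A substitution at a deletion's
#' anchor base does not conflict (the anchor survives). Conflicts are
#' resolved deterministically: higher population probability wins; ties go
#' to deletion over insertion over substitution, then to the leftmost
#' anchor, then to input order. Every dropped edit is reported with the
#' index of the edit that displaced it.
#'
#' @param edits a `mair_edits` table (see [compute_mair()]); rows need
#'   `chrom, pos, kind, payload, len, population_prob`.
#' @return list with `kept` and `dropped` (dropped has extra columns
#'   `reason` and `winner` row-id into the input).
#' @export
resolve_conflicts <- function(edits) {
  ed <- data.table::as.data.table(edits)
  if (nrow(ed) == 0L) return(list(kept = ed, dropped = ed))
  ed <- data.table::copy(ed)
  ed[, `:=`(.input_id = .I)]
  # occupied span on a doubled coordinate axis: base p -> 2p, gap after p -> 2p+1
  start2 <- ifelse(ed$kind == "substitution", 2L * ed$pos, 2L * ed$pos + 1L)
  end2 <- ifelse(ed$kind == "deletion", 2L * (ed$pos + ed$len) + 1L, start2)
  kind_rank <- match(ed$kind, c("deletion", "insertion", "substitution"))
  prio <- order(-ed$population_prob, kind_rank, ed$chrom, ed$pos, ed$.input_id)
  kept_idx <- integer(0)
  winner_of <- integer(nrow(ed))
  dropped_idx <- integer(0)
  # greedy acceptance in priority order; O(n * kept-per-chrom), edit sets are
  # sparse relative to genome length so this stays cheap
  occ <- list()
  for (i in prio) {
    ch <- ed$chrom[i]
    o <- occ[[ch]]
    if (!is.null(o) && any(start2[i] <= o$end & end2[i] >= o$start)) {
      w <- o$id[which(start2[i] <= o$end & end2[i] >= o$start)[1L]]
      dropped_idx <- c(dropped_idx, i)
      winner_of[i] <- w
    } else {
      kept_idx <- c(kept_idx, i)
      occ[[ch]] <- list(start = c(o$start, start2[i]),
                        end = c(o$end, end2[i]),
                        id = c(o$id, i))
    }
  }
  kept <- ed[sort(kept_idx)]
  kept[, `:=`(.input_id = NULL)]
  dropped <- ed[sort(dropped_idx)]
  if (nrow(dropped)) {
    dropped[, `:=`(reason = "overlaps higher-priority edit",
                   winner = winner_of[sort(dropped_idx)])]
    dropped[, `:=`(.input_id = NULL)]
  }
  data.table::setorder(kept, chrom, pos)
  list(kept = kept, dropped = dropped)
}

#' Build a virtual consensus genome from a reference and MAIR edits
#'
#' Applies substitutions, insertions (after their anchor base) and
#' deletions (starting at anchor + 1) to each chromosome, producing the
#' consensus sequences, a reference->consensus liftover map and an edit
#' report. Substitutions whose payload equals the reference base are
#' rejected and logged; edits beyond the chromosome end are an error.
#'
#' @param reference named character vector of uppercase sequences (see
#'   [read_reference()]).
#' @param edits a `mair_edits` table.
#' @return A `vcg` object: list with `consensus` (named character),
#'   `liftover` (a `liftover_map`), and `report` (list with `kept`,
#'   `dropped`, `rejected` tables).
#' @export
build_vcg <- function(reference, edits) {
  ed <- data.table::as.data.table(edits)
  unknown <- setdiff(unique(ed$chrom), names(reference))
  if (length(unknown)) {
    stop(sprintf("edits on chromosome(s) absent from the reference: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  chrlen <- nchar(reference)
  if (nrow(ed)) {
    maxend <- ifelse(ed$kind == "deletion", ed$pos + ed$len, ed$pos)
    bad <- maxend > chrlen[ed$chrom] | ed$pos < 1L
    if (any(bad)) {
      b <- which(bad)[1L]
      stop(sprintf("edit out of bounds: %s %s:%d", ed$kind[b], ed$chrom[b],
                   ed$pos[b]), call. = FALSE)
    }
  }
  # reject no-op substitutions (payload equals reference base)
  rejected <- ed[0L]
  if (nrow(ed)) {
    is_sub <- ed$kind == "substitution"
    refbase <- substr(reference[ed$chrom], ed$pos, ed$pos)
    noop <- is_sub & toupper(ed$payload) == refbase
    rejected <- ed[noop]
    if (nrow(rejected)) rejected[, `:=`(reason = "substitution equals reference base")]
    ed <- ed[!noop]
  }
  res <- resolve_conflicts(ed)
  kept <- res$kept

  consensus <- character(length(reference))
  names(consensus) <- names(reference)
  segs_l <- list()
  gaps_l <- list()
  for (ch in names(reference)) {
    refseq <- reference[[ch]]
    L <- nchar(refseq)
    e <- kept[kept$chrom == ch]
    # substitutions first: they do not move coordinates
    subs <- e[e$kind == "substitution"]
    if (nrow(subs)) {
      chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
      chars[subs$pos] <- toupper(subs$payload)
      refseq <- paste(chars, collapse = "")
    }
    ind <- e[e$kind != "substitution"]
    data.table::setorder(ind, pos)
    pieces <- character(0)
    segs <- list()
    gaps <- list()
    cur <- 1L       # next unconsumed reference position
    off <- 0L       # consensus offset of the current segment
    if (nrow(ind)) {
      for (i in seq_len(nrow(ind))) {
        p <- ind$pos[i]
        if (ind$kind[i] == "insertion") {
          pieces <- c(pieces, substr(refseq, cur, p), toupper(ind$payload[i]))
          segs[[length(segs) + 1L]] <- c(cur, p, off)
          off <- off + ind$len[i]
          cur <- p + 1L
        } else {  # deletion of len bases starting at p+1
          pieces <- c(pieces, substr(refseq, cur, p))
          segs[[length(segs) + 1L]] <- c(cur, p, off)
          gaps[[length(gaps) + 1L]] <- c(p + 1L, p + ind$len[i])
          off <- off - ind$len[i]
          cur <- p + ind$len[i] + 1L
        }
      }
    }
    if (cur <= L) {
      pieces <- c(pieces, substr(refseq, cur, L))
      segs[[length(segs) + 1L]] <- c(cur, L, off)
    }
    consensus[[ch]] <- paste(pieces, collapse = "")
    sm <- if (length(segs)) do.call(rbind, segs) else
      matrix(integer(0), ncol = 3L)
    gm <- if (length(gaps)) do.call(rbind, gaps) else
      matrix(integer(0), ncol = 2L)
    segs_l[[ch]] <- data.table::data.table(
      chrom = ch, ref_start = sm[, 1], ref_end = sm[, 2], offset = sm[, 3])
    gaps_l[[ch]] <- data.table::data.table(
      chrom = ch,
      start = if (nrow(gm)) gm[, 1] else integer(0),
      end = if (nrow(gm)) gm[, 2] else integer(0))
  }
  # drop zero-length segments (an insertion/deletion at position cur-1
  # boundary can create ref_start > ref_end runs)
  segments <- data.table::rbindlist(segs_l)
  segments <- segments[segments$ref_start <= segments$ref_end]
  map <- structure(list(segments = segments,
                        gaps = data.table::rbindlist(gaps_l),
                        ref_length = chrlen,
                        cons_length = nchar(consensus)),
                   class = "liftover_map")
  structure(list(consensus = consensus, liftover = map,
                 report = list(kept = kept, dropped = res$dropped,
                               rejected = rejected)),
            class = "vcg")
}

#' @export
print.vcg <- function(x, ...) {
  cat(sprintf("vcg: %d chromosome(s), %d edits applied, %d dropped, %d rejected\n",
              length(x$consensus), nrow(x$report$kept),
              nrow(x$report$dropped), nrow(x$report$rejected)))
  invisible(x)
}

#' Lift coordinates between reference and consensus
#'
#' Forward (`ref2cons`) maps 1-based reference positions to consensus
#' positions; positions inside a deleted run return `NA` (deleted). The
#' reverse direction maps consensus positions back; positions inside an
#' inserted run return `NA`. The mapping is monotone non-decreasing over
#' kept positions, and reverse(forward(p)) is the identity on every
#' unedited position.
#'
#' @param map a `liftover_map` from [build_vcg()].
#' @param chrom chromosome name (scalar).
#' @param pos integer vector of positions.
#' @param direction `"ref2cons"` or `"cons2ref"`.
#' @return Integer vector, `NA` where a position has no image.
#' @export
liftover <- function(map, chrom, pos, direction = c("ref2cons", "cons2ref")) {
  direction <- match.arg(direction)
  segs <- map$segments[map$segments$chrom == chrom]
  if (nrow(segs) == 0L) return(rep(NA_integer_, length(pos)))
  pos <- as.integer(pos)
  if (direction == "ref2cons") {
    i <- findInterval(pos, segs$ref_start)
    out <- rep(NA_integer_, length(pos))
    ok <- i >= 1L
    okk <- ok
    okk[ok] <- pos[ok] <= segs$ref_end[i[ok]]
    out[okk] <- pos[okk] + segs$offset[i[okk]]
    out
  } else {
    cs <- segs$ref_start + segs$offset
    ce <- segs$ref_end + segs$offset
    i <- findInterval(pos, cs)
    out <- rep(NA_integer_, length(pos))
    ok <- i >= 1L
    okk <- ok
    okk[ok] <- pos[ok] <= ce[i[ok]]
    out[okk] <- pos[okk] - segs$offset[i[okk]]
    out
  }
}

#' Write a liftover map as a chain-like TSV
#'
#' Columns: `chrom, ref_start, ref_end, cons_start, cons_end, offset`
#' (1-based inclusive segments), followed by deletion gap rows flagged in
#' the `type` column.
#'
#' @param map a `liftover_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_liftover <- function(map, path) {
  segs <- data.table::copy(map$segments)
  segs[, `:=`(cons_start = ref_start + offset, cons_end = ref_end + offset,
              type = "segment")]
  gaps <- data.table::copy(map$gaps)
  if (nrow(gaps)) {
    gaps <- data.table::data.table(chrom = gaps$chrom, ref_start = gaps$start,
                                   ref_end = gaps$end,
                                   cons_start = NA_integer_,
                                   cons_end = NA_integer_,
                                   offset = NA_integer_, type = "deleted")
  } else {
    gaps <- segs[0L, list(chrom, ref_start, ref_end, cons_start, cons_end,
                          offset, type)]
  }
  out <- data.table::rbindlist(list(
    segs[, list(chrom, ref_start, ref_end, cons_start, cons_end, offset,
                type)],
    gaps), use.names = TRUE)
  data.table::setorder(out, chrom, ref_start)
  writeLines("# coordinates 1-based inclusive; insertions anchored after ref position; deletions start at anchor+1",
             path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
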