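# Summary reports: category counts by chromosome class, probability and
# indel-length distributions, pairwise population comparisons with the
# same/diff allele distinction, codon-level effect tallies and interval
# catalog hit counts. All reports are pure functions of their inputs.

#' Default human chromosome class map
#'
#' Autosomes 1-22 (with and without a `chr` prefix), X/Y as heterosome,
#' MT/M as chondriosome. Any chromosome not named in a class map falls into
#' class `"other"`.
#'
#' @return Named character vector chromosome -> class.
#' @export
default_chromosome_classes <- function() {
  auto <- as.character(1:22)
  cls <- c(stats::setNames(rep("autosome", 44), c(auto, paste0("chr", auto))),
           stats::setNames(rep("heterosome", 4), c("X", "Y", "chrX", "chrY")),
           stats::setNames(rep("chondriosome", 4), c("MT", "M", "chrMT", "chrM")))
  cls
}

.chrom_class <- function(chrom, class_map) {
  cls <- class_map[chrom]
  cls[is.na(cls)] <- "other"
  unname(cls)
}

#' Summarise a classified population
#'
#' Counts of dynamic positions, high-probability indels and rare
#' variations split by chromosome class; a histogram of major-allele
#' probabilities; and an indel length histogram restricted to
#' high-probability events (population probability above 50%), split into
#' insertions and deletions.
#'
#' @param dynpos a `dynamic_positions` object.
#' @param class_map named vector chromosome -> class; default
#'   [default_chromosome_classes()].
#' @param prob_breaks major-probability histogram bin edges; default width
#'   0.05 over (0, 1].
#' @param indel_min_prob probability floor for the indel length histogram
#'   (exclusive; default 0.5).
#' @return A `vcg_summary` list: `population`, `counts` (data.table
#'   `class, dynamic_positions, indels, rare_variations` plus a `total`
#'   row), `prob_hist` (data.table `bin_low, bin_high, count`),
#'   `indel_length_hist` (data.table `kind, len, count`).
#' @export
summarize_population <- function(dynpos,
                                 class_map = default_chromosome_classes(),
                                 prob_breaks = seq(0, 1, by = 0.05),
                                 indel_min_prob = 0.5) {
  p <- dynpos$positions
  ind <- dynpos$indels
  rare <- extract_rare(dynpos)
  hi <- ind[isTRUE_vec(ind$high)]

  tab <- function(chroms) {
    if (!length(chroms)) return(stats::setNames(integer(0), character(0)))
    table(.chrom_class(chroms, class_map))
  }
  classes <- sort(unique(c(names(tab(p$chrom)), names(tab(hi$chrom)),
                           names(tab(rare$chrom)))))
  counts <- data.table::data.table(
    class = classes,
    dynamic_positions = as.integer(tab(p$chrom)[classes]),
    indels = as.integer(tab(hi$chrom)[classes]),
    rare_variations = as.integer(tab(rare$chrom)[classes]))
  for (j in names(counts)[-1L]) {
    data.table::set(counts, which(is.na(counts[[j]])), j, 0L)
  }
  counts <- data.table::rbindlist(list(
    counts,
    data.table::data.table(class = "total",
                           dynamic_positions = nrow(p),
                           indels = nrow(hi),
                           rare_variations = nrow(rare))))

  if (nrow(p)) {
    bins <- cut(p$major_prob, breaks = prob_breaks, include.lowest = FALSE)
    bc <- table(bins)
  } else {
    bc <- table(factor(character(0),
                       levels = levels(cut(numeric(0), prob_breaks))))
  }
  prob_hist <- data.table::data.table(
    bin_low = prob_breaks[-length(prob_breaks)],
    bin_high = prob_breaks[-1L],
    count = as.integer(bc))

  ih <- ind[!is.na(ind$population_prob) & ind$population_prob > indel_min_prob]
  indel_length_hist <- if (nrow(ih)) {
    ih[, list(count = .N), by = c("kind", "len")][order(kind, len)]
  } else {
    data.table::data.table(kind = character(0), len = integer(0),
                           count = integer(0))
  }
  structure(list(population = dynpos$population_id, counts = counts,
                 prob_hist = prob_hist,
                 indel_length_hist = indel_length_hist),
            class = "vcg_summary")
}

#' @export
print.vcg_summary <- function(x, ...) {
  cat(sprintf("summary for population '%s':\n", x$population))
  print(x$counts)
  invisible(x)
}

#' Compare two classified populations
#'
#' Exact set arithmetic over position keys, with the shared set split into
#' same-allele and different-allele for allele-bearing categories:
#' \describe{
#'   \item{dynamic}{all dynamic positions, keyed (chrom, pos); no
#'     same/diff split;}
#'   \item{major}{major-allele-difference positions; "same" means the two
#'     populations substituted the identical nucleotide;}
#'   \item{indel}{high-probability indel positions; "same" means identical
#'     (kind, sequence/length);}
#'   \item{rare}{rare-variation positions, keyed (chrom, pos); no
#'     same/diff split.}
#' }
#'
#' @param dynA,dynB `dynamic_positions` objects.
#' @param category one of `"dynamic"`, `"major"`, `"indel"`, `"rare"`.
#' @return An `intersection_report` list: `category, a_only, b_only,
#'   shared, same, diff` (`same`/`diff` are `NA` for position-only
#'   categories).
#' @export
intersect_populations <- function(dynA, dynB,
                                  category = c("dynamic", "major", "indel",
                                               "rare")) {
  category <- match.arg(category)
  keyed <- function(d) {
    switch(category,
      dynamic = unique(d$positions[, list(chrom, pos)]),
      major = {
        p <- d$positions[d$positions$major_diff]
        p[, list(chrom, pos, payload = major)]
      },
      indel = {
        i <- d$indels[isTRUE_vec(d$indels$high)]
        i[, list(chrom, pos,
                 payload = paste(kind, ifelse(kind == "insertion", seq,
                                              as.character(len))))]
      },
      rare = unique(extract_rare(d)[, list(chrom, pos)]))
  }
  a <- keyed(dynA)
  b <- keyed(dynB)
  ka <- unique(a[, list(chrom, pos)])
  kb <- unique(b[, list(chrom, pos)])
  shared_keys <- merge(ka, kb, by = c("chrom", "pos"))
  rep <- list(category = category,
              a_only = nrow(ka) - nrow(shared_keys),
              b_only = nrow(kb) - nrow(shared_keys),
              shared = nrow(shared_keys), same = NA_integer_,
              diff = NA_integer_)
  if (category %in% c("major", "indel") && nrow(shared_keys)) {
    pa <- merge(shared_keys, a, by = c("chrom", "pos"))
    pb <- merge(shared_keys, b, by = c("chrom", "pos"))
    same_keys <- unique(merge(pa, pb,
                              by = c("chrom", "pos", "payload"))[, list(chrom, pos)])
    rep$same <- nrow(same_keys)
    rep$diff <- nrow(shared_keys) - nrow(same_keys)
  } else if (category %in% c("major", "indel")) {
    rep$same <- 0L
    rep$diff <- 0L
  }
  structure(rep, class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("intersection (%s): A-only %d, B-only %d, shared %d",
              x$category, x$a_only, x$b_only, x$shared))
  if (!is.na(x$same)) cat(sprintf(" (same %d, diff %d)", x$same, x$diff))
  cat("\n")
  invisible(x)
}

#' Tally codon-level effects of MAIR substitutions in coding regions
#'
#' For each substitution edit falling inside a supplied coding interval,
#' the containing codon is read from the reference in the coding frame,
#' the edited codon is translated against it, and the change is classified
#' as synonymous, nonsynonymous, stop-gain or stop-loss. Substitutions in
#' intervals without frame information, or whose codon runs outside the
#' interval, are counted `unknown`. Minus-strand intervals are translated
#' on the reverse complement; the frame offset is counted from the
#' interval's 3'-most reference coordinate.
#'
#' @param mair a `mair_edits` table.
#' @param reference named reference sequences.
#' @param annotation data.frame with columns `chrom, start, end, strand`
#'   (`+`/`-`) and `frame` (0/1/2 offset of the first complete codon, `NA`
#'   for unknown).
#' @return list with `counts` (data.table `effect, count`) and `details`
#'   (one row per substitution in an interval).
#' @export
tally_effects <- function(mair, reference, annotation) {
  ann <- data.table::as.data.table(annotation)
  subs <- data.table::as.data.table(mair)
  subs <- subs[subs$kind == "substitution"]
  effects <- c("synonymous", "nonsynonymous", "stop-gain", "stop-loss",
               "unknown")
  det <- list()
  code <- Biostrings::GENETIC_CODE
  comp <- function(x) chartr("ACGT", "TGCA", x)
  revcomp <- function(x) comp(paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                    collapse = ""))
  if (nrow(subs)) {
    for (i in seq_len(nrow(subs))) {
      hits <- ann[ann$chrom == subs$chrom[i] & ann$start <= subs$pos[i] &
                    ann$end >= subs$pos[i]]
      for (k in seq_len(nrow(hits))) {
        eff <- "unknown"
        fr <- hits$frame[k]
        if (!is.na(fr)) {
          p <- subs$pos[i]
          if (identical(hits$strand[k], "-")) {
            cpos <- (hits$end[k] - fr) - p
          } else {
            cpos <- p - (hits$start[k] + fr)
          }
          if (cpos >= 0) {
            ci <- cpos %/% 3L
            within <- cpos %% 3L
            if (identical(hits$strand[k], "-")) {
              hi_ <- hits$end[k] - fr - 3L * ci
              lo_ <- hi_ - 2L
            } else {
              lo_ <- hits$start[k] + fr + 3L * ci
              hi_ <- lo_ + 2L
            }
            if (lo_ >= hits$start[k] && hi_ <= hits$end[k]) {
              refcodon <- substr(reference[[subs$chrom[i]]], lo_, hi_)
              altcodon <- refcodon
              substr(altcodon, p - lo_ + 1L, p - lo_ + 1L) <-
                toupper(subs$payload[i])
              if (identical(hits$strand[k], "-")) {
                refcodon <- revcomp(refcodon)
                altcodon <- revcomp(altcodon)
              }
              aa_ref <- unname(code[refcodon])
              aa_alt <- unname(code[altcodon])
              if (!is.na(aa_ref) && !is.na(aa_alt)) {
                eff <- if (aa_ref == aa_alt) "synonymous"
                  else if (aa_alt == "*") "stop-gain"
                  else if (aa_ref == "*") "stop-loss"
                  else "nonsynonymous"
              }
            }
          }
        }
        det[[length(det) + 1L]] <- data.table::data.table(
          chrom = subs$chrom[i], pos = subs$pos[i],
          payload = subs$payload[i], strand = hits$strand[k], effect = eff)
      }
    }
  }
  details <- if (length(det)) data.table::rbindlist(det) else
    data.table::data.table(chrom = character(0), pos = integer(0),
                           payload = character(0), strand = character(0),
                           effect = character(0))
  counts <- data.table::data.table(
    effect = effects,
    count = vapply(effects, function(e) sum(details$effect == e), integer(1)))
  list(counts = counts, details = details)
}

#' Count catalog intervals hit by MAIR edits
#'
#' For each label in a BED-like interval catalog, counts how many of its
#' intervals are overlapped by at least one MAIR edit (1-based inclusive
#' overlap; a deletion's span is anchor+1 .. anchor+length, substitutions
#' and insertions occupy their anchor base). Reported as hits / total per
#' label.
#'
#' @param mair a `mair_edits` table.
#' @param catalog data.frame with columns `chrom, start, end, label`
#'   (1-based inclusive).
#' @return data.table `label, hits, total, ratio` ("hits/total"), ordered
#'   by decreasing hits.
#' @export
count_catalog_hits <- function(mair, catalog) {
  cat_dt <- data.table::as.data.table(catalog)
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(cat_dt)))
  ed <- data.table::as.data.table(mair)
  hit <- rep(FALSE, nrow(cat_dt))
  if (nrow(ed)) {
    estart <- ifelse(ed$kind == "deletion", ed$pos + 1L, ed$pos)
    eend <- ifelse(ed$kind == "deletion", ed$pos + ed$len, ed$pos)
    for (ch in unique(cat_dt$chrom)) {
      ci <- which(cat_dt$chrom == ch)
      ei <- which(ed$chrom == ch)
      if (!length(ei)) next
      q <- IRanges::IRanges(start = cat_dt$start[ci], end = cat_dt$end[ci])
      s <- IRanges::IRanges(start = estart[ei], end = eend[ei])
      hit[ci] <- IRanges::countOverlaps(q, s) > 0L
    }
  }
  out <- cat_dt[, list(hits = sum(hit[.I]), total = .N), by = "label"]
  out[, `:=`(ratio = sprintf("%d/%d", hits, total))]
  data.table::setorder(out, -hits, label)
  out[]
}
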