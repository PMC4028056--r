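# Population-level allele statistics and the four-circumstance dynamic
# position classification.
#
# Every covered sample contributes exactly one dominant-allele vote,
# regardless of its read depth ("equal sample weighting"): the major-allele
# probability is the fraction of covered samples voting for the allele, not
# the pooled read fraction, so deeply sequenced samples cannot swamp the
# population estimate.

#' Classification thresholds for dynamic positions
#'
#' @param rare_max maximum sample fraction for the rare-variation category
#'   (inclusive; default 0.05).
#' @param minor_min sample fraction above which a minor allele is a common
#'   minor (exclusive; default 0.05). Together with `rare_max` = 0.05 this
#'   makes rare / common-minor a partition of the observed minor alleles.
#' @param indel_high_min minimum population probability for a
#'   high-probability indel (inclusive; default 0.50).
#' @return A `classification_config` list.
#' @export
classification_config <- function(rare_max = 0.05, minor_min = 0.05,
                                  indel_high_min = 0.50) {
  stopifnot(rare_max > 0, rare_max <= minor_min, minor_min < indel_high_min,
            indel_high_min <= 1)
  structure(list(rare_max = rare_max, minor_min = minor_min,
                 indel_high_min = indel_high_min),
            class = "classification_config")
}

#' Population allele statistics at candidate dynamic positions
#'
#' For each CDP and each sample of `population` whose unit at that position
#' was retained by the comentropy filter, the sample casts one dominant
#' vote. The major allele is the vote-count maximum (ties toward the
#' reference base, then alphabetical); minor-allele frequencies are vote
#' fractions of the covered samples; the population comentropy is the
#' entropy of the vote distribution. An indel event supports a sample when
#' that sample shows at least one read carrying the event and is covered;
#' its population probability is supporting / covered samples.
#'
#' @param cdps a `cdp_set` from [extract_cdps()].
#' @param units retained units from [build_units()] (rows with
#'   `passed = FALSE` are ignored).
#' @param population character vector of sample names, or `NULL` for all
#'   manifest samples.
#' @param population_id label carried on every output row.
#' @return A `pop_stats` object: list with `stats` (data.table `population,
#'   chrom, pos, ref, n_covered, vA, vC, vG, vT, pA, pC, pG, pT` (pooled
#'   read counts), `major, major_prob, pop_comentropy`) and `indels`
#'   (data.table `population, chrom, pos, kind, seq, len, support,
#'   population_prob`). Positions with no covered sample are absent (not
#'   estimable in this population).
#' @export
population_stats <- function(cdps, units, population = NULL,
                             population_id = "ALL") {
  manifest <- cdps$records$samples
  if (is.null(population)) population <- manifest
  missing <- setdiff(population, manifest)
  if (length(missing)) {
    stop(sprintf("population '%s' names samples absent from the manifest: %s",
                 population_id, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  u <- units[units$passed & units$sample %in% population]
  u <- u[cdps$keys[, list(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  if (nrow(u) == 0L) {
    return(.pop_stats(.empty_stats(), .empty_pop_indels(), population_id,
                      population))
  }
  A <- C <- G <- T <- dominant <- ref <- NULL
  st <- u[, list(
    ref = ref[1L],
    n_covered = .N,
    vA = sum(dominant == "A"), vC = sum(dominant == "C"),
    vG = sum(dominant == "G"), vT = sum(dominant == "T"),
    pA = sum(A), pC = sum(C), pG = sum(G), pT = sum(T)),
    by = c("chrom", "pos")]
  votes <- as.matrix(st[, list(vA, vC, vG, vT)])
  mx <- pmax(votes[, 1], votes[, 2], votes[, 3], votes[, 4])
  is_max <- votes == mx
  major <- NUCS[max.col(is_max, ties.method = "first")]
  refm <- match(st$ref, NUCS)
  ok <- !is.na(refm)
  ref_is_max <- ok
  ref_is_max[ok] <- is_max[cbind(which(ok), refm[ok])]
  major[ref_is_max] <- st$ref[ref_is_max]
  frac <- votes / st$n_covered
  hl <- ifelse(frac > 0, frac * log2(frac), 0)
  pop_h <- -rowSums(hl)
  major_prob <- frac[cbind(seq_len(nrow(st)), match(major, NUCS))]
  stats <- data.table::data.table(
    population = population_id, st[, list(chrom, pos, ref, n_covered)],
    st[, list(vA, vC, vG, vT, pA, pC, pG, pT)],
    major = major, major_prob = major_prob, pop_comentropy = pop_h)
  data.table::setkey(stats, chrom, pos)

  ind <- cdps$records$indels
  ind <- ind[ind$sample %in% population]
  if (nrow(ind)) {
    # one support per (sample, event); sample must be covered at the position
    cov <- u[, list(chrom, pos, sample)]
    ind <- merge(ind, cov, by = c("chrom", "pos", "sample"))
  }
  if (nrow(ind)) {
    ev <- ind[, list(support = length(unique(sample))),
              by = c("chrom", "pos", "kind", "seq", "len")]
    ev <- merge(ev, stats[, list(chrom, pos, n_covered)],
                by = c("chrom", "pos"))
    ev[, `:=`(population = population_id,
              population_prob = support / n_covered)]
    indels <- ev[, list(population, chrom, pos, kind, seq, len, support,
                        population_prob)]
    data.table::setkey(indels, chrom, pos)
  } else {
    indels <- .empty_pop_indels()
  }
  .pop_stats(stats, indels, population_id, population)
}

.pop_stats <- function(stats, indels, population_id, samples) {
  structure(list(stats = stats, indels = indels,
                 population_id = population_id, samples = samples),
            class = "pop_stats")
}

.empty_stats <- function() {
  data.table::data.table(population = character(0), chrom = character(0),
                         pos = integer(0), ref = character(0),
                         n_covered = integer(0), vA = integer(0),
                         vC = integer(0), vG = integer(0), vT = integer(0),
                         pA = integer(0), pC = integer(0), pG = integer(0),
                         pT = integer(0), major = character(0),
                         major_prob = numeric(0), pop_comentropy = numeric(0))
}

.empty_pop_indels <- function() {
  data.table::data.table(population = character(0), chrom = character(0),
                         pos = integer(0), kind = character(0),
                         seq = character(0), len = integer(0),
                         support = integer(0), population_prob = numeric(0))
}

#' @export
print.pop_stats <- function(x, ...) {
  cat(sprintf("pop_stats '%s': %d positions, %d indel events, %d samples\n",
              x$population_id, nrow(x$stats), nrow(x$indels),
              length(x$samples)))
  invisible(x)
}

#' Classify population statistics into dynamic positions
#'
#' The four circumstances, evaluated per position (categories may
#' co-occur):
#' \describe{
#'   \item{MAJOR_DIFF}{the population major allele differs from the
#'     reference base;}
#'   \item{INDEL_HIGH}{an indel event has population probability at or
#'     above `indel_high_min` (default 50\%);}
#'   \item{MINOR_COMMON}{a non-major allele has sample fraction strictly
#'     above `minor_min` (default 5\%);}
#'   \item{RARE}{a non-major allele has sample fraction in
#'     `(0, rare_max]` (default at most 5\%).}
#' }
#' Positions matching no circumstance are static and are not emitted.
#' `in_mair` marks membership of the first two categories (the edit set
#' applied to the reference by [build_vcg()]).
#'
#' @param popstats a `pop_stats` object.
#' @param config a [classification_config()].
#' @return A `dynamic_positions` object: list with `positions` (data.table
#'   `population, chrom, pos, ref, major, major_prob, n_covered,
#'   major_diff, indel_high, minor_common, rare, categories, in_mair`),
#'   `alleles` (per minor allele: `population, chrom, pos, allele,
#'   frequency, class` rare/common) and `indels` (the stats indel table
#'   plus `high` flag).
#' @export
classify_positions <- function(popstats, config = classification_config()) {
  st <- popstats$stats
  if (nrow(st) == 0L) {
    return(.dynpos(.empty_positions(), .empty_alleles(), .empty_dyn_indels(),
                   popstats$population_id))
  }
  votes <- as.matrix(st[, list(vA, vC, vG, vT)])
  frac <- votes / st$n_covered
  majm <- match(st$major, NUCS)
  minor_frac <- frac
  minor_frac[cbind(seq_len(nrow(st)), majm)] <- 0
  has_rare <- rowSums(minor_frac > 0 & minor_frac <= config$rare_max) > 0L
  has_common <- rowSums(minor_frac > config$minor_min) > 0L
  major_diff <- st$ref %in% NUCS & st$major != st$ref

  ind <- popstats$indels
  if (nrow(ind)) {
    ind <- data.table::copy(ind)
    ind[, `:=`(high = population_prob >= config$indel_high_min)]
    hi_keys <- unique(ind[ind$high, list(chrom, pos)])
  } else {
    ind <- .empty_dyn_indels()
    hi_keys <- data.table::data.table(chrom = character(0), pos = integer(0))
  }
  indel_high <- rep(FALSE, nrow(st))
  if (nrow(hi_keys)) {
    indel_high <- !is.na(
      hi_keys[st[, list(chrom, pos)], on = c("chrom", "pos"), which = TRUE])
  }

  any_cat <- major_diff | indel_high | has_common | has_rare
  cats <- apply(cbind(MAJOR_DIFF = major_diff, INDEL_HIGH = indel_high,
                      MINOR_COMMON = has_common, RARE = has_rare)[any_cat, ,
                                                                  drop = FALSE],
                1L, function(r) paste(names(r)[r], collapse = ","))
  positions <- data.table::data.table(
    st[any_cat, list(population, chrom, pos, ref, major, major_prob,
                     n_covered)],
    major_diff = major_diff[any_cat], indel_high = indel_high[any_cat],
    minor_common = has_common[any_cat], rare = has_rare[any_cat],
    categories = cats,
    in_mair = (major_diff | indel_high)[any_cat])

  # long minor-allele table
  al_list <- lapply(1:4, function(j) {
    sel <- minor_frac[, j] > 0
    data.table::data.table(
      population = st$population[sel], chrom = st$chrom[sel],
      pos = st$pos[sel], allele = NUCS[j], frequency = minor_frac[sel, j])
  })
  alleles <- data.table::rbindlist(al_list)
  if (nrow(alleles)) {
    alleles[, `:=`(class = ifelse(frequency <= config$rare_max, "rare",
                                  ifelse(frequency > config$minor_min,
                                         "common", "intermediate")))]
    data.table::setkey(alleles, chrom, pos)
  } else {
    alleles <- .empty_alleles()
  }
  .dynpos(positions, alleles, ind, popstats$population_id)
}

#' Classify a single population-statistics record
#'
#' Scalar convenience wrapper around [classify_positions()] for one
#' position, taking explicit vote counts.
#'
#' @param votes named vote counts over A/C/G/T (one vote per covered
#'   sample).
#' @param ref_base reference base.
#' @param indel_probs numeric vector of indel population probabilities at
#'   the position (may be empty).
#' @param config a [classification_config()].
#' @return `NULL` when the position is static, otherwise a list with
#'   `categories` (character vector), `major`, `major_prob`, `in_mair`.
#' @export
classify <- function(votes, ref_base, indel_probs = numeric(0),
                     config = classification_config()) {
  full <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  full[names(votes)] <- as.integer(votes)
  n_cov <- sum(full)
  stopifnot(n_cov > 0L)
  ref_base <- toupper(ref_base)
  mx <- max(full)
  tied <- sort(NUCS[full == mx])
  major <- if (ref_base %in% tied) ref_base else tied[1L]
  frac <- full / n_cov
  minor <- frac
  minor[major] <- 0
  cats <- character(0)
  if (ref_base %in% NUCS && major != ref_base) cats <- c(cats, "MAJOR_DIFF")
  if (length(indel_probs) && any(indel_probs >= config$indel_high_min)) {
    cats <- c(cats, "INDEL_HIGH")
  }
  if (any(minor > config$minor_min)) cats <- c(cats, "MINOR_COMMON")
  if (any(minor > 0 & minor <= config$rare_max)) cats <- c(cats, "RARE")
  if (!length(cats)) return(NULL)
  list(categories = cats, major = major, major_prob = frac[[major]],
       in_mair = any(cats %in% c("MAJOR_DIFF", "INDEL_HIGH")))
}

.dynpos <- function(positions, alleles, indels, population_id) {
  structure(list(positions = positions, alleles = alleles, indels = indels,
                 population_id = population_id),
            class = "dynamic_positions")
}

.empty_positions <- function() {
  data.table::data.table(population = character(0), chrom = character(0),
                         pos = integer(0), ref = character(0),
                         major = character(0), major_prob = numeric(0),
                         n_covered = integer(0), major_diff = logical(0),
                         indel_high = logical(0), minor_common = logical(0),
                         rare = logical(0), categories = character(0),
                         in_mair = logical(0))
}

.empty_alleles <- function() {
  data.table::data.table(population = character(0), chrom = character(0),
                         pos = integer(0), allele = character(0),
                         frequency = numeric(0), class = character(0))
}

.empty_dyn_indels <- function() {
  dt <- .empty_pop_indels()
  dt[, `:=`(high = logical(0))]
  dt[]
}

#' @export
print.dynamic_positions <- function(x, ...) {
  p <- x$positions
  cat(sprintf(
    "dynamic_positions '%s': %d positions (major-diff %d, indel-high %d, common-minor %d, rare %d), %d in MAIR\n",
    x$population_id, nrow(p), sum(p$major_diff), sum(p$indel_high),
    sum(p$minor_common), sum(p$rare), sum(p$in_mair)))
  invisible(x)
}

#' Rare-variation table of a classified position set
#'
#' One row per minor allele at or below the rare threshold, keyed
#' (population, chrom, pos, allele, frequency).
#'
#' @param dynpos a `dynamic_positions` object (or a list of them, which are
#'   concatenated and grouped by population).
#' @return data.table `population, chrom, pos, allele, frequency`.
#' @export
extract_rare <- function(dynpos) {
  if (inherits(dynpos, "dynamic_positions")) dynpos <- list(dynpos)
  al <- data.table::rbindlist(lapply(dynpos, `[[`, "alleles"))
  if (nrow(al) == 0L) {
    return(.empty_alleles()[, list(population, chrom, pos, allele, frequency)])
  }
  out <- al[al$class == "rare",
            list(population, chrom, pos, allele, frequency)]
  data.table::setorder(out, population, chrom, pos, allele)
  out[]
}

#' MAIR edit table of a classified position set
#'
#' The major-allele-and-indel-against-reference set: substitutions where
#' the population major allele differs from the reference, plus indel
#' events at or above the high-probability threshold. This is the edit set
#' [build_vcg()] applies to the reference.
#'
#' @param dynpos a `dynamic_positions` object.
#' @return A `mair_edits` data.table: `chrom, pos, kind`
#'   (substitution/insertion/deletion), `ref, payload` (new base or
#'   inserted sequence or deleted length as character), `len`,
#'   `population_prob`, sorted by (chrom, pos).
#' @export
compute_mair <- function(dynpos) {
  stopifnot(inherits(dynpos, "dynamic_positions"))
  p <- dynpos$positions
  subs <- p[p$major_diff,
            list(chrom, pos, kind = "substitution", ref, payload = major,
                 len = 1L, population_prob = major_prob)]
  ind <- dynpos$indels
  hi <- ind[isTRUE_vec(ind$high)]
  if (nrow(hi)) {
    inds <- hi[, list(chrom, pos, kind, ref = NA_character_,
                      payload = ifelse(kind == "insertion", seq,
                                       as.character(len)),
                      len, population_prob)]
  } else {
    inds <- subs[0L]
  }
  out <- data.table::rbindlist(list(subs, inds))
  data.table::setorder(out, chrom, pos, kind)
  data.table::setattr(out, "class", c("mair_edits", class(out)))
  out[]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write classified dynamic positions as VCF 4.2
#'
#' Site-level records: ALT is the major allele for major-difference
#' positions plus any observed minor alleles; INFO carries `POP`
#' (population), `CAT` (category set), `MAP` (major-allele probability),
#' `NCOV` (covered samples) and `AF` (per-ALT sample fractions). Indel
#' events are emitted as symbolic `<INS>`/`<DEL>` records with `SVLEN`.
#'
#' @param dynpos a `dynamic_positions` object.
#' @param path output path.
#' @param reference optional named reference sequences used to emit
#'   `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_dynamic_vcf <- function(dynpos, path, reference = NULL) {
  p <- dynpos$positions
  al <- dynpos$alleles
  hdr <- c("##fileformat=VCFv4.2",
           "##source=vcgtools",
           "##INFO=<ID=POP,Number=1,Type=String,Description=\"Population\">",
           "##INFO=<ID=CAT,Number=1,Type=String,Description=\"Dynamic position categories\">",
           "##INFO=<ID=MAP,Number=1,Type=Float,Description=\"Major allele probability (fraction of covered samples)\">",
           "##INFO=<ID=NCOV,Number=1,Type=Integer,Description=\"Covered samples\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Sample fraction per ALT allele\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Indel length\">")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          nchar(reference)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      alts <- character(0); afs <- numeric(0)
      if (p$major_diff[i]) {
        alts <- p$major[i]; afs <- p$major_prob[i]
      }
      ai <- al[al$chrom == p$chrom[i] & al$pos == p$pos[i] &
                 al$allele != p$ref[i]]
      if (nrow(ai)) {
        alts <- c(alts, ai$allele); afs <- c(afs, ai$frequency)
      }
      if (!length(alts)) next
      lines <- c(lines, sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\tPOP=%s;CAT=%s;MAP=%.6g;NCOV=%d;AF=%s",
        p$chrom[i], p$pos[i], p$ref[i], paste(alts, collapse = ","),
        p$population[i], p$categories[i], p$major_prob[i], p$n_covered[i],
        paste(sprintf("%.6g", afs), collapse = ",")))
    }
  }
  ind <- dynpos$indels
  if (nrow(ind)) {
    for (i in seq_len(nrow(ind))) {
      sym <- if (ind$kind[i] == "insertion") "<INS>" else "<DEL>"
      svlen <- if (ind$kind[i] == "insertion") ind$len[i] else -ind$len[i]
      lines <- c(lines, sprintf(
        "%s\t%d\t.\tN\t%s\t.\tPASS\tPOP=%s;CAT=%s;MAP=%.6g;NCOV=.;SVLEN=%d",
        ind$chrom[i], ind$pos[i], sym, ind$population[i],
        if (isTRUE(ind$high[i])) "INDEL_HIGH" else "INDEL",
        ind$population_prob[i], svlen))
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write the three flat tables of a classified position set
#'
#' Mirrors the three-part storage layout: dynamic positions, indels and
#' rare variations as TSV files `<prefix>_positions.tsv`,
#' `<prefix>_indels.tsv`, `<prefix>_rare.tsv`.
#'
#' @param dynpos a `dynamic_positions` object.
#' @param prefix output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_dynamic_tables <- function(dynpos, prefix) {
  paths <- paste0(prefix, c("_positions.tsv", "_indels.tsv", "_rare.tsv"))
  data.table::fwrite(dynpos$positions, paths[1L], sep = "\t")
  data.table::fwrite(dynpos$indels, paths[2L], sep = "\t")
  data.table::fwrite(extract_rare(dynpos), paths[3L], sep = "\t")
  invisible(paths)
}
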