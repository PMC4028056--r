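# Parsing of samtools-mpileup-style multi-sample text into position-based
# records. Coordinates are 1-based inclusive throughout the package.

NUCS <- c("A", "C", "G", "T")

#' Parse one mpileup base string into per-nucleotide counts and indel events
#'
#' Implements the samtools mpileup base-string dialect: `.`/`,` are
#' reference matches on the forward/reverse strand, `ACGTacgt` are
#' mismatches, `+n<seq>`/`-n<seq>` are insertion/deletion events attached to
#' the preceding read base, `^` + mapping-quality character marks a read
#' start, `$` a read end, and `*` (or `#`) is a deleted-base placeholder.
#' Strand is ignored: case and `.`/`,` are folded together. Characters
#' consumed by an indel sub-string are never counted as point bases; `*`,
#' `>`, `<` and `N` reads count toward depth but contribute no nucleotide.
#'
#' @param bases character(1), the base string for one sample at one position.
#' @param ref_base the reference nucleotide at the position (`A/C/G/T/N`).
#' @param pos,sample optional position / sample index, used only to make
#'   parse-error messages actionable.
#' @return A `sample_call`: list with `depth` (read symbols seen),
#'   `base_counts` (named integer over A/C/G/T), `insertions`
#'   (data.frame `seq`, `count`) and `deletions` (data.frame `length`,
#'   `seq`, `count`).
#' @examples
#' parse_base_string(".,.,", "A")$base_counts
#' parse_base_string(".,+2AG.,", "C")$insertions
#' @export
parse_base_string <- function(bases, ref_base, pos = NA_integer_,
                              sample = NA_integer_) {
  stopifnot(is.character(bases), length(bases) == 1L)
  ref_base <- toupper(ref_base)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  depth <- 0L
  ins <- character(0)
  del <- character(0)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i == n) {
        stop(sprintf("dangling '^' read-start marker (position %s, sample %s)",
                     pos, sample), call. = FALSE)
      }
      i <- i + 2L  # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) {
        stop(sprintf("malformed indel length prefix after '%s' (position %s, sample %s)",
                     ch, pos, sample), call. = FALSE)
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) {
        stop(sprintf("indel sequence truncated: need %d bases (position %s, sample %s)",
                     len, pos, sample), call. = FALSE)
      }
      sq <- toupper(paste(chars[j:(j + len - 1L)], collapse = ""))
      if (ch == "+") ins <- c(ins, sq) else del <- c(del, sq)
      i <- j + len
    } else {
      depth <- depth + 1L
      if (ch == "." || ch == ",") {
        if (ref_base %in% NUCS) counts[ref_base] <- counts[ref_base] + 1L
      } else {
        up <- toupper(ch)
        if (up %in% NUCS) counts[up] <- counts[up] + 1L
        # '*', '#', '>', '<', 'N': depth only
      }
      i <- i + 1L
    }
  }
  ins_tab <- if (length(ins)) {
    tb <- table(ins)
    data.frame(seq = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seq = character(0), count = integer(0))
  }
  del_tab <- if (length(del)) {
    tb <- table(del)
    data.frame(length = nchar(names(tb)), seq = names(tb),
               count = as.integer(tb), stringsAsFactors = FALSE)
  } else {
    data.frame(length = integer(0), seq = character(0), count = integer(0))
  }
  structure(list(depth = depth, base_counts = counts,
                 insertions = ins_tab, deletions = del_tab),
            class = "sample_call")
}

# Vectorised base-string parser used by read_pileup(). Strings containing
# indel events are routed through the scalar tokenizer (they are rare);
# everything else is counted with vectorised string ops.
# Returns list(counts = matrix[n x 4], indels = data.table).
.parse_base_strings <- function(bases, ref, pos = NULL, sample_id = NA) {
  n <- length(bases)
  ref <- toupper(ref)
  x <- bases
  x[is.na(x)] <- ""
  has_marker <- grepl("^", x, fixed = TRUE)
  if (any(has_marker)) x[has_marker] <- gsub("\\^.", "", x[has_marker])
  x <- gsub("$", "", x, fixed = TRUE)
  has_indel <- grepl("+", x, fixed = TRUE) | grepl("-", x, fixed = TRUE)

  counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, NUCS))
  ind_list <- list()

  if (any(!has_indel)) {
    idx <- which(!has_indel)
    xu <- chartr("acgt,", "ACGT.", x[idx])
    cnt <- function(ch) nchar(xu) - nchar(gsub(ch, "", xu, fixed = TRUE))
    dot <- cnt(".")
    for (nu in NUCS) {
      cc <- cnt(nu)
      at_ref <- ref[idx] == nu
      cc[at_ref] <- cc[at_ref] + dot[at_ref]
      counts[idx, nu] <- cc
    }
  }
  if (any(has_indel)) {
    for (k in which(has_indel)) {
      sc <- parse_base_string(x[k], ref[k],
                              pos = if (is.null(pos)) k else pos[k],
                              sample = sample_id)
      counts[k, ] <- sc$base_counts
      if (nrow(sc$insertions) || nrow(sc$deletions)) {
        rows <- list()
        if (nrow(sc$insertions)) {
          rows[[1L]] <- data.table::data.table(
            row = k, kind = "insertion", seq = sc$insertions$seq,
            len = nchar(sc$insertions$seq), count = sc$insertions$count)
        }
        if (nrow(sc$deletions)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            row = k, kind = "deletion", seq = sc$deletions$seq,
            len = sc$deletions$length, count = sc$deletions$count)
        }
        ind_list[[length(ind_list) + 1L]] <- data.table::rbindlist(rows)
      }
    }
  }
  indels <- if (length(ind_list)) {
    data.table::rbindlist(ind_list)
  } else {
    data.table::data.table(row = integer(0), kind = character(0),
                           seq = character(0), len = integer(0),
                           count = integer(0))
  }
  list(counts = counts, indels = indels)
}

#' Read a multi-sample mpileup file into a position-based pileup object
#'
#' Accepts the tab-separated samtools mpileup multi-sample layout: `chrom`,
#' `pos`, `ref` followed by per-sample column groups, auto-detected as
#' triplets (depth, bases, qualities) or pairs (depth, bases). Base-quality
#' columns are parsed but discarded; filtering in this package is by
#' comentropy, not base quality. Gzipped input is read transparently.
#'
#' @param path path to the pileup file (optionally gzipped), or a
#'   connection.
#' @param samples optional character vector naming the samples in column
#'   order (the sample manifest). Defaults to `S001`, `S002`, ...
#' @return A `pileup` object: list with `samples`, `calls` (data.table
#'   `chrom, pos, ref, sample, depth, A, C, G, T`), `indels` (data.table
#'   `chrom, pos, sample, kind, seq, len, count`) and `n_positions`.
#' @export
read_pileup <- function(path, samples = NULL) {
  if (is.character(path) && file.exists(path) &&
        isTRUE(file.size(path) == 0)) {
    return(.pileup(samples %||% character(0),
                   .empty_calls(), .empty_pileup_indels(), 0L))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "", fill = TRUE)
  if (nrow(dt) == 0L) {
    return(.pileup(samples %||% character(0),
                   .empty_calls(), .empty_pileup_indels(), 0L))
  }
  nc <- ncol(dt)
  extra <- nc - 3L
  if (extra >= 3L && extra %% 3L == 0L) {
    n_samp <- extra %/% 3L
    per <- 3L
  } else if (extra >= 2L && extra %% 2L == 0L) {
    n_samp <- extra %/% 2L
    per <- 2L
  } else {
    stop(sprintf("pileup format error: %d sample columns fit neither depth/bases/quals triplets nor depth/bases pairs", extra),
         call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- sprintf("S%03d", seq_len(n_samp))
  } else if (length(samples) != n_samp) {
    stop(sprintf("pileup format error: file has %d samples but manifest names %d",
                 n_samp, length(samples)), call. = FALSE)
  }
  chrom <- dt[[1L]]
  pos <- as.integer(dt[[2L]])
  if (anyNA(pos)) stop("pileup format error: non-integer position field", call. = FALSE)
  ref <- toupper(dt[[3L]])
  # positions strictly increasing within each chromosome
  ord_ok <- tapply(pos, chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok))) {
    bad <- names(which(!unlist(ord_ok)))[1L]
    stop(sprintf("pileup ordering error: positions not strictly increasing on %s", bad),
         call. = FALSE)
  }

  calls_l <- vector("list", n_samp)
  ind_l <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    dcol <- 3L + (s - 1L) * per + 1L
    bcol <- dcol + 1L
    depth <- as.integer(dt[[dcol]])
    bases <- dt[[bcol]]
    bases[depth == 0L] <- ""   # mpileup writes '*' placeholders at depth 0
    parsed <- .parse_base_strings(bases, ref, pos = pos, sample_id = samples[s])
    calls_l[[s]] <- data.table::data.table(
      chrom = chrom, pos = pos, ref = ref, sample = samples[s],
      depth = depth,
      A = parsed$counts[, "A"], C = parsed$counts[, "C"],
      G = parsed$counts[, "G"], T = parsed$counts[, "T"])
    if (nrow(parsed$indels)) {
      ii <- parsed$indels
      ind_l[[s]] <- data.table::data.table(
        chrom = chrom[ii$row], pos = pos[ii$row], sample = samples[s],
        kind = ii$kind, seq = ii$seq, len = ii$len, count = ii$count)
    }
  }
  calls <- data.table::rbindlist(calls_l)
  indels <- data.table::rbindlist(ind_l[!vapply(ind_l, is.null, logical(1))])
  if (nrow(indels) == 0L) indels <- .empty_pileup_indels()
  data.table::setkey(calls, chrom, pos, sample)
  .pileup(samples, calls, indels, nrow(dt))
}

.pileup <- function(samples, calls, indels, n_positions) {
  structure(list(samples = samples, calls = calls, indels = indels,
                 n_positions = n_positions),
            class = "pileup")
}

.empty_calls <- function() {
  data.table::data.table(chrom = character(0), pos = integer(0),
                         ref = character(0), sample = character(0),
                         depth = integer(0), A = integer(0), C = integer(0),
                         G = integer(0), T = integer(0))
}

.empty_pileup_indels <- function() {
  data.table::data.table(chrom = character(0), pos = integer(0),
                         sample = character(0), kind = character(0),
                         seq = character(0), len = integer(0),
                         count = integer(0))
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: %d positions x %d samples, %d indel observations\n",
              x$n_positions, length(x$samples), nrow(x$indels)))
  invisible(x)
}

#' Extract one position of a pileup as a column record
#'
#' @param pileup a `pileup` object.
#' @param chrom,pos chromosome and 1-based position.
#' @return A `pileup_column`: list with `chrom`, `pos`, `ref_base` and
#'   `samples`, a named list of `sample_call` records (one per manifest
#'   sample, in manifest order).
#' @export
pileup_column <- function(pileup, chrom, pos) {
  qchrom <- chrom
  qpos <- as.integer(pos)
  cc <- pileup$calls[pileup$calls$chrom == qchrom & pileup$calls$pos == qpos]
  if (nrow(cc) == 0L || all(is.na(cc$depth))) {
    stop(sprintf("no pileup data at %s:%d", chrom, pos), call. = FALSE)
  }
  ii <- pileup$indels[pileup$indels$chrom == chrom & pileup$indels$pos == pos]
  calls <- lapply(pileup$samples, function(s) {
    row <- cc[cc$sample == s]
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    depth <- 0L
    if (nrow(row) == 1L) {
      counts[] <- c(row$A, row$C, row$G, row$T)
      depth <- row$depth
    }
    si <- ii[ii$sample == s]
    ins <- si[si$kind == "insertion"]
    del <- si[si$kind == "deletion"]
    structure(list(
      depth = depth, base_counts = counts,
      insertions = data.frame(seq = ins$seq, count = ins$count,
                              stringsAsFactors = FALSE),
      deletions = data.frame(length = del$len, seq = del$seq,
                             count = del$count, stringsAsFactors = FALSE)),
      class = "sample_call")
  })
  names(calls) <- pileup$samples
  structure(list(chrom = chrom, pos = pos, ref_base = cc$ref[1L],
                 samples = calls),
            class = "pileup_column")
}

#' Write a pileup object back to mpileup-format text
#'
#' Reconstructs per-sample base strings from the stored counts: reference
#' reads as `.`, mismatches as upper-case letters, indel events appended to
#' the first read symbol, unaccounted depth as `*` placeholders. A constant
#' placeholder quality column is emitted so the file round-trips through
#' [read_pileup()].
#'
#' @param pileup a `pileup` object.
#' @param path output path; `.gz` suffix writes gzipped text.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  calls <- data.table::copy(pileup$calls)
  ref <- NULL; A <- C <- G <- T <- depth <- NULL  # NSE notes
  # base part: ref dots then mismatch letters (A<C<G<T), then '*' filler
  nref <- integer(nrow(calls))
  base_str <- rep("", nrow(calls))
  refv <- calls$ref
  cnts <- as.matrix(calls[, list(A, C, G, T)])
  for (nu in NUCS) {
    at <- refv == nu
    nref[at] <- cnts[at, nu]
  }
  base_str <- strrep(".", nref)
  for (nu in NUCS) {
    k <- cnts[, nu]
    k[refv == nu] <- 0L
    base_str <- paste0(base_str, strrep(nu, k))
  }
  nuc_total <- rowSums(cnts)
  base_str <- paste0(base_str, strrep("*", pmax(calls$depth - nuc_total, 0L)))

  if (nrow(pileup$indels)) {
    agg <- pileup$indels[, list(
      txt = paste0(vapply(seq_len(.N), function(i) {
        tag <- if (kind[i] == "insertion") "+" else "-"
        strrep(paste0(tag, len[i], seq[i]), count[i])
      }, character(1)), collapse = "")),
      by = c("chrom", "pos", "sample")]
    calls[, `:=`(row_id = .I)]
    m <- merge(calls[, list(chrom, pos, sample, row_id)], agg,
               by = c("chrom", "pos", "sample"))
    if (nrow(m)) {
      rid <- m$row_id
      # attach after the first read symbol
      head1 <- substr(base_str[rid], 1L, 1L)
      rest <- substr(base_str[rid], 2L, nchar(base_str[rid]))
      base_str[rid] <- paste0(head1, m$txt, rest)
    }
  }
  base_str[calls$depth == 0L] <- "*"
  qual <- strrep("I", calls$depth)
  qual[calls$depth == 0L] <- "*"

  wide <- data.table::data.table(chrom = calls$chrom, pos = calls$pos,
                                 ref = calls$ref, sample = calls$sample,
                                 depth = calls$depth, bases = base_str,
                                 qual = qual)
  data.table::setorder(wide, chrom, pos)
  out <- data.table::dcast(wide, chrom + pos + ref ~ sample,
                           value.var = c("depth", "bases", "qual"))
  data.table::setorder(out, chrom, pos)
  # interleave depth/bases/qual per sample in manifest order
  cols <- c("chrom", "pos", "ref",
            as.vector(t(cbind(paste0("depth_", pileup$samples),
                              paste0("bases_", pileup$samples),
                              paste0("qual_", pileup$samples)))))
  out <- out[, cols, with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference genome FASTA into named uppercase sequences
#'
#' @param path FASTA path (plain or gzipped), possibly multi-record.
#' @return Named character vector, one uppercase sequence per chromosome.
#'   Record names are truncated at the first whitespace.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate FASTA record name: %s", nm[duplicated(nm)][1L]),
         call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA with 60-column wrapping
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
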