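# Fixture builders and independent oracles used across the suite. All
# fixtures are generated in code; nothing is read from disk.

NUCS <- c("A", "C", "G", "T")

# Build a pileup object directly from a per-(position, sample) count spec.
# spec: data.frame chrom, pos, ref, sample, A, C, G, T (depth defaults to
# the nucleotide total). indels: optional data.frame chrom, pos, sample,
# kind, seq, len, count.
make_pileup <- function(spec, indels = NULL, samples = NULL) {
  dt <- data.table::as.data.table(spec)
  for (nu in NUCS) if (is.null(dt[[nu]])) dt[[nu]] <- 0L
  if (is.null(dt$depth)) dt$depth <- dt$A + dt$C + dt$G + dt$T
  if (is.null(samples)) samples <- sort(unique(dt$sample))
  # complete missing (position, sample) cells with zero depth
  keys <- unique(dt[, list(chrom, pos, ref)])
  full <- keys[, list(sample = samples), by = list(chrom, pos, ref)]
  calls <- merge(full, dt, by = c("chrom", "pos", "ref", "sample"),
                 all.x = TRUE)
  for (j in c("depth", NUCS)) {
    data.table::set(calls, which(is.na(calls[[j]])), j, 0L)
    calls[[j]] <- as.integer(calls[[j]])
  }
  calls[, `:=`(pos = as.integer(pos))]
  data.table::setkey(calls, chrom, pos, sample)
  ind <- if (is.null(indels)) {
    data.table::data.table(chrom = character(0), pos = integer(0),
                           sample = character(0), kind = character(0),
                           seq = character(0), len = integer(0),
                           count = integer(0))
  } else {
    ii <- data.table::as.data.table(indels)
    ii[, `:=`(pos = as.integer(pos), len = as.integer(len),
              count = as.integer(count))]
    ii
  }
  structure(list(samples = samples, calls = calls, indels = ind,
                 n_positions = nrow(keys)),
            class = "pileup")
}

# Independent high-precision comentropy: algebraically different route,
# H = log2(total) - (1/total) * sum(c_i * log2(c_i)).
oracle_entropy <- function(counts) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  log2(total) - sum(counts * log2(counts)) / total
}

# Independent reference tokenizer for mpileup base strings, regex-driven
# (the package parser is a character loop). Returns counts + depth.
oracle_tokenize <- function(bases, ref_base) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  depth <- 0L
  x <- bases
  repeat {
    if (nchar(x) == 0L) break
    m <- regmatches(x, regexpr("^(\\^.|\\$|[+-][0-9]+)", x))
    if (length(m)) {
      if (grepl("^[+-]", m)) {
        len <- as.integer(sub("^[+-]", "", m))
        x <- substr(x, nchar(m) + len + 1L, nchar(x))
      } else {
        x <- substr(x, nchar(m) + 1L, nchar(x))
      }
      next
    }
    ch <- substr(x, 1L, 1L)
    depth <- depth + 1L
    up <- toupper(ch)
    if (ch %in% c(".", ",")) up <- toupper(ref_base)
    if (up %in% NUCS) counts[up] <- counts[up] + 1L
    x <- substr(x, 2L, nchar(x))
  }
  list(base_counts = counts, depth = depth)
}

# Generate a random valid mpileup base string together with its expected
# counts (uses the current RNG stream).
rand_base_string <- function(ref_base) {
  n_ev <- sample(0:8, 1L)
  parts <- character(0)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  depth <- 0L
  for (k in seq_len(n_ev)) {
    kind <- sample(c("ref", "mis", "ins", "del", "star"), 1L,
                   prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
    start <- if (stats::runif(1) < 0.3) paste0("^", rawToChar(as.raw(sample(33:126, 1L)))) else ""
    end <- if (stats::runif(1) < 0.2) "$" else ""
    if (kind == "ref") {
      sym <- sample(c(".", ","), 1L)
      counts[toupper(ref_base)] <- counts[toupper(ref_base)] + 1L
      depth <- depth + 1L
    } else if (kind == "mis") {
      b <- sample(setdiff(NUCS, toupper(ref_base)), 1L)
      sym <- sample(c(b, tolower(b)), 1L)
      counts[b] <- counts[b] + 1L
      depth <- depth + 1L
    } else if (kind == "star") {
      sym <- "*"
      depth <- depth + 1L
      end <- ""  # '*' never carries an end marker mid-parse ambiguity
    } else {
      len <- sample(1:4, 1L)
      sq <- paste(sample(NUCS, len, replace = TRUE), collapse = "")
      sym <- paste0(".", if (kind == "ins") "+" else "-", len, sq)
      counts[toupper(ref_base)] <- counts[toupper(ref_base)] + 1L
      depth <- depth + 1L
    }
    parts <- c(parts, paste0(start, sym, end))
  }
  list(str = paste(parts, collapse = ""), counts = counts, depth = depth)
}

# Naive string-rewriting oracle for consensus construction. edits must be
# non-overlapping (e.g. the `kept` set of resolve_conflicts/build_vcg).
# Returns the consensus string and the per-reference-position consensus
# coordinate (NA where deleted).
naive_apply_edits <- function(refseq, edits) {
  chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  deleted <- rep(FALSE, length(chars))
  if (nrow(edits)) {
    # substitutions first: a substitution and an insertion may legally share
    # an anchor base (the insertion sits in the gap after it)
    edits <- edits[order(edits$kind != "substitution"), ]
    for (i in seq_len(nrow(edits))) {
      p <- edits$pos[i]
      if (edits$kind[i] == "substitution") {
        chars[p] <- toupper(edits$payload[i])
      } else if (edits$kind[i] == "insertion") {
        chars[p] <- paste0(chars[p], toupper(edits$payload[i]))
      } else {
        span <- (p + 1L):(p + edits$len[i])
        chars[span] <- ""
        deleted[span] <- TRUE
      }
    }
  }
  width <- nchar(chars)
  cons_pos <- cumsum(c(1L, width[-length(width)]))
  cons_pos[deleted] <- NA_integer_
  list(seq = paste(chars, collapse = ""), cons_pos = cons_pos)
}

# Random edit set over a reference sequence (possibly overlapping);
# conflict resolution is the implementation's job.
rand_edit_set <- function(refseq, n_edits) {
  L <- nchar(refseq)
  kind <- sample(c("substitution", "insertion", "deletion"), n_edits,
                 replace = TRUE)
  pos <- sample.int(L - 6L, n_edits, replace = TRUE)
  payload <- character(n_edits)
  len <- integer(n_edits)
  for (i in seq_len(n_edits)) {
    if (kind[i] == "substitution") {
      rb <- substr(refseq, pos[i], pos[i])
      payload[i] <- sample(setdiff(NUCS, rb), 1L)
      len[i] <- 1L
    } else if (kind[i] == "insertion") {
      len[i] <- sample(1:5, 1L)
      payload[i] <- paste(sample(NUCS, len[i], replace = TRUE),
                          collapse = "")
    } else {
      len[i] <- sample(1:5, 1L)
      payload[i] <- as.character(len[i])
    }
  }
  data.table::data.table(chrom = "chr1", pos = pos, kind = kind,
                         ref = NA_character_, payload = payload, len = len,
                         population_prob = round(stats::runif(n_edits), 3))
}

rand_dna <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")
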