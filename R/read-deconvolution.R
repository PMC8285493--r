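READ_CLASSES <- c("WT", "UNINTENDED", "MULTI", "UNALIGNABLE", "LOW_QUALITY")

#' Merge a read pair into a consensus read
#'
#' Mate 2 is reverse-complemented, trailing (3') bases below `min_qual` are
#' trimmed from each mate, and the mates are merged at the overlap offset
#' with the most agreeing bases. Disagreements within the overlap are
#' resolved to the higher-quality base. The pair is rejected as low quality
#' when no overlap of at least `min_overlap` bases exists after trimming, or
#' when the mean consensus quality falls below `min_qual`.
#'
#' @param seq1,seq2 mate sequences (mate 2 in sequencing orientation, i.e.
#'   reverse strand).
#' @param qual1,qual2 integer Phred scores, same lengths as the sequences.
#' @param min_qual Phred threshold for 3' trimming and for the mean consensus
#'   quality (default 20).
#' @param min_overlap minimum overlap length in bases (default 20); an
#'   overlap offset is only eligible when at least 90\% of its overlapping
#'   bases agree.
#' @return list with `status` (`"ok"` or `"low_quality"`) and, when ok,
#'   `seq` and `qual` of the consensus.
#' @export
merge_read_pair <- function(seq1, qual1, seq2, qual2,
                            min_qual = 20L, min_overlap = 20L) {
  stopifnot(nchar(seq1) == length(qual1), nchar(seq2) == length(qual2))
  trim3 <- function(s, q) {
    keep <- length(q)
    while (keep > 0L && q[keep] < min_qual) keep <- keep - 1L
    list(s = substr(s, 1L, keep), q = q[seq_len(keep)])
  }
  m1 <- trim3(seq1, qual1)
  m2 <- trim3(seq2, qual2)
  if (nchar(m1$s) < min_overlap || nchar(m2$s) < min_overlap) {
    return(list(status = "low_quality"))
  }
  b1 <- strsplit(m1$s, "")[[1L]]
  q1 <- m1$q
  b2 <- rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(m2$s, "")[[1L]]])
  q2 <- rev(m2$q)
  n1 <- length(b1); n2 <- length(b2)
  # mate 2 (reverse-complemented) starts at 0-based offset s on the fragment
  best <- NULL
  for (s in 0:(n1 - min_overlap)) {
    ov <- min(n1 - s, n2)
    if (ov < min_overlap) break
    i1 <- (s + 1L):(s + ov)
    i2 <- seq_len(ov)
    matches <- sum(b1[i1] == b2[i2])
    # an overlap only counts if it is near-identical (>= 90% agreement);
    # otherwise the mates do not genuinely overlap at this offset
    if (matches < 0.9 * ov) next
    if (is.null(best) || matches > best$matches) {
      best <- list(s = s, ov = ov, matches = matches)
    }
  }
  if (is.null(best)) return(list(status = "low_quality"))
  s <- best$s; ov <- best$ov
  flen <- max(n1, s + n2)
  cons <- character(flen)
  cq <- integer(flen)
  cons[seq_len(n1)] <- b1
  cq[seq_len(n1)] <- q1
  if (ov < n2) {
    tail2 <- (ov + 1L):n2
    cons[s + tail2] <- b2[tail2]
    cq[s + tail2] <- q2[tail2]
  }
  for (k in seq_len(ov)) {
    i <- s + k
    if (b1[i] != b2[k] && q2[k] > q1[i]) {
      cons[i] <- b2[k]
      cq[i] <- q2[k]
    } else if (b1[i] == b2[k]) {
      cq[i] <- max(q1[i], q2[k])
    }
  }
  if (mean(cq) < min_qual) return(list(status = "low_quality"))
  list(status = "ok", seq = paste(cons, collapse = ""), qual = cq)
}

# Exact k-mer index of the reference: environment mapping k-mer -> 1-based
# start positions. Built once per reference and reused across reads.
build_kmer_index <- function(refseq, k) {
  idx <- new.env(parent = emptyenv(), size = 4L * nchar(refseq))
  n <- nchar(refseq) - k + 1L
  if (n < 1L) stop("reference shorter than seed length")
  kmers <- substring(refseq, seq_len(n), seq_len(n) + k - 1L)
  for (i in seq_len(n)) {
    km <- kmers[i]
    idx[[km]] <- c(idx[[km]], i)
  }
  idx
}

#' Call the codon-level variant carried by a consensus read
#'
#' The read is anchored to the reference by exact k-mer seeding followed by
#' ungapped extension (amplicon data; reads with indels fail to anchor and
#' are reported unalignable). Mismatches are grouped by reference codon:
#' no changed codon is wild type; exactly one changed codon is either a
#' designed variant (the observed codon equals a designed `alt_codon` at that
#' position) or an unintended variant; two or more changed codons are a
#' multi-variant read.
#'
#' @param read consensus read sequence (from [merge_read_pair()]).
#' @param orf reference [orf_sequence()].
#' @param design the [library_design()] whose variants are being counted.
#' @param max_mismatch maximum tolerated mismatches over the whole read
#'   (default 6).
#' @param k seed k-mer length (default 20).
#' @param index optional precomputed k-mer index (see
#'   [tally_counts()] which builds it once per sample set).
#' @return list with `status` (one of `wild_type`, `designed_variant`,
#'   `unintended_variant`, `multi_variant`, `unalignable`) and `variant_id`
#'   (non-`NA` only for designed variants).
#' @export
call_read <- function(read, orf, design, max_mismatch = 6L, k = 20L,
                      index = NULL) {
  refseq <- orf$nucleotides
  L <- nchar(refseq)
  rl <- nchar(read)
  if (rl < k || rl > L) return(list(status = "unalignable", variant_id = NA_character_))
  if (is.null(index)) index <- build_kmer_index(refseq, k)
  rb <- strsplit(read, "")[[1L]]
  refb <- strsplit(refseq, "")[[1L]]
  seed_pos <- unique(c(seq.int(1L, rl - k + 1L, by = k), rl - k + 1L))
  offsets <- integer(0)
  for (sp in seed_pos) {
    hits <- index[[substr(read, sp, sp + k - 1L)]]
    if (!is.null(hits)) offsets <- c(offsets, hits - sp + 1L)
  }
  offsets <- unique(offsets)
  offsets <- offsets[offsets >= 1L & offsets + rl - 1L <= L]
  if (length(offsets) == 0L) {
    return(list(status = "unalignable", variant_id = NA_character_))
  }
  best_off <- NA_integer_
  best_mm <- Inf
  for (off in offsets) {
    mm <- sum(rb != refb[off:(off + rl - 1L)])
    if (mm < best_mm) { best_mm <- mm; best_off <- off }
  }
  if (best_mm > max_mismatch) {
    return(list(status = "unalignable", variant_id = NA_character_))
  }
  if (best_mm == 0L) return(list(status = "wild_type", variant_id = NA_character_))
  mm_pos <- best_off - 1L + which(rb != refb[best_off:(best_off + rl - 1L)])
  codon_idx <- unique((mm_pos - 1L) %/% 3L)           # 0-based codon index
  if (length(codon_idx) >= 2L) {
    return(list(status = "multi_variant", variant_id = NA_character_))
  }
  ci <- codon_idx
  codon_number <- orf$codon_offset + ci
  # observed codon: read bases where covered, reference bases elsewhere
  nt <- 3L * ci + 1L
  obs <- refb[nt:(nt + 2L)]
  cover <- (nt:(nt + 2L)) >= best_off & (nt:(nt + 2L)) <= best_off + rl - 1L
  obs[cover] <- rb[(nt:(nt + 2L))[cover] - best_off + 1L]
  obs <- paste(obs, collapse = "")
  hit <- design$variants$codon_number == codon_number &
    design$variants$alt_codon == obs
  if (any(hit)) {
    list(status = "designed_variant",
         variant_id = design$variants$variant_id[which(hit)[1L]])
  } else {
    list(status = "unintended_variant", variant_id = NA_character_)
  }
}

#' Tally per-variant read counts across samples
#'
#' Runs [merge_read_pair()] and [call_read()] over every read pair of every
#' sample and accumulates a variant-by-sample counts matrix. Rows are all
#' designed variant ids plus the reserved classes `WT`, `UNINTENDED`,
#' `MULTI`, `UNALIGNABLE` and `LOW_QUALITY`; column sums equal the number of
#' input read pairs per sample (every read is accounted for exactly once).
#'
#' @param samples named list; each element is a list of read pairs, each pair
#'   a list with `seq1`, `qual1`, `seq2`, `qual2` (see [read_fastq_pairs()]).
#' @param orf reference [orf_sequence()].
#' @param design the [library_design()].
#' @param min_qual,min_overlap,max_mismatch,k see [merge_read_pair()] and
#'   [call_read()].
#' @return Integer matrix, variants + reserved classes by samples, with
#'   attribute `total_reads` (per-sample input read-pair counts).
#' @export
tally_counts <- function(samples, orf, design, min_qual = 20L,
                         min_overlap = 20L, max_mismatch = 6L, k = 20L) {
  stopifnot(!is.null(names(samples)), !anyDuplicated(names(samples)))
  rows <- c(design$variants$variant_id, READ_CLASSES)
  counts <- matrix(0L, nrow = length(rows), ncol = length(samples),
                   dimnames = list(rows, names(samples)))
  index <- build_kmer_index(orf$nucleotides, k)
  for (s in names(samples)) {
    for (pair in samples[[s]]) {
      merged <- merge_read_pair(pair$seq1, pair$qual1, pair$seq2, pair$qual2,
                                min_qual = min_qual, min_overlap = min_overlap)
      if (merged$status == "low_quality") {
        counts["LOW_QUALITY", s] <- counts["LOW_QUALITY", s] + 1L
        next
      }
      cl <- call_read(merged$seq, orf, design, max_mismatch = max_mismatch,
                      k = k, index = index)
      row <- switch(cl$status,
                    wild_type = "WT",
                    designed_variant = cl$variant_id,
                    unintended_variant = "UNINTENDED",
                    multi_variant = "MULTI",
                    unalignable = "UNALIGNABLE")
      counts[row, s] <- counts[row, s] + 1L
    }
  }
  attr(counts, "total_reads") <- vapply(samples, length, integer(1))
  counts
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2 (gz transparent).
#' @return List of read pairs in the format consumed by [tally_counts()].
#' @export
read_fastq_pairs <- function(path1, path2) {
  # suppress the benign Biostrings note about dropped metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  q1 <- as(Biostrings::quality(r1), "IntegerList")
  q2 <- as(Biostrings::quality(r2), "IntegerList")
  lapply(seq_along(r1), function(i) {
    list(id = names(r1)[i],
         seq1 = as.character(r1[[i]]), qual1 = q1[[i]],
         seq2 = as.character(r2[[i]]), qual2 = q2[[i]])
  })
}

#' Write a counts matrix as TSV (and read it back)
#'
#' Wide format: first column `variant_id`, one column per sample.
#' @param counts matrix from [tally_counts()] or
#'   [simulate_screen()].
#' @param path output TSV path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(variant_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$variant_id
  m
}
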