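# Shared fixtures and independent oracles used across the suite.

# ORF from an explicit codon vector
toy_orf <- function(codons, id = "toy", codon_offset = 1L,
                    check_internal_stop = TRUE) {
  orf_sequence(paste(codons, collapse = ""), id = id,
               codon_offset = codon_offset,
               check_internal_stop = check_internal_stop)
}

# naive all-offset degenerate-pattern scan (oracle for find_restriction_sites)
naive_site_scan <- function(dna, recognition) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
             W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
             V = "ACG", N = "ACGT")
  pb <- strsplit(recognition, "")[[1L]]
  db <- strsplit(dna, "")[[1L]]
  m <- length(pb); n <- length(db)
  hits <- integer(0)
  for (off in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!grepl(db[off + j], iupac[[pb[j]]], fixed = TRUE)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# naive both-strand guide scan (oracle for find_guide_matches)
naive_guide_scan <- function(dna, guide, pam = "NGG") {
  n_hits <- 0L
  starts <- integer(0); strands <- character(0)
  scan_one <- function(s) {
    pat <- paste0(guide, pam)
    found <- integer(0)
    for (off in 0:(nchar(s) - nchar(pat))) {
      win <- substr(s, off + 1L, off + nchar(pat))
      ok <- all(mapply(function(a, b) b == "N" || a == b,
                       strsplit(win, "")[[1L]], strsplit(pat, "")[[1L]]))
      if (ok) found <- c(found, off)
    }
    found
  }
  fw <- scan_one(dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  rv <- scan_one(rc)
  list(n = length(fw) + length(rv), fwd = fw,
       rev_plus_start = nchar(dna) - rv - nchar(guide))
}

# brute-force ungapped aligner (oracle for call_read): best Hamming offset
# over all full-containment placements
naive_align <- function(read, refseq) {
  rb <- strsplit(read, "")[[1L]]
  fb <- strsplit(refseq, "")[[1L]]
  rl <- length(rb); L <- length(fb)
  if (rl > L) return(list(offset = NA_integer_, mismatches = Inf))
  best_off <- NA_integer_; best_mm <- Inf
  for (off in 1:(L - rl + 1L)) {
    mm <- sum(rb != fb[off:(off + rl - 1L)])
    if (mm < best_mm) { best_mm <- mm; best_off <- off }
  }
  list(offset = best_off, mismatches = best_mm)
}

# classify a read with the naive aligner + the documented codon rules
naive_call <- function(read, orf, design, max_mismatch = 6L) {
  al <- naive_align(read, orf$nucleotides)
  if (is.infinite(al$mismatches) || al$mismatches > max_mismatch) {
    return("unalignable")
  }
  if (al$mismatches == 0L) return("wild_type")
  rb <- strsplit(read, "")[[1L]]
  fb <- strsplit(orf$nucleotides, "")[[1L]]
  pos <- al$offset - 1L + which(rb != fb[al$offset:(al$offset + length(rb) - 1L)])
  cidx <- unique((pos - 1L) %/% 3L)
  if (length(cidx) >= 2L) return("multi_variant")
  nt <- 3L * cidx + 1L
  obs <- fb[nt:(nt + 2L)]
  cover <- (nt:(nt + 2L)) >= al$offset & (nt:(nt + 2L)) <= al$offset + length(rb) - 1L
  obs[cover] <- rb[(nt:(nt + 2L))[cover] - al$offset + 1L]
  cn <- orf$codon_offset + cidx
  if (any(design$variants$codon_number == cn &
          design$variants$alt_codon == paste(obs, collapse = ""))) {
    "designed_variant"
  } else {
    "unintended_variant"
  }
}

# minimal PDB writer for synthetic coordinate fixtures
write_toy_pdb <- function(atoms, path) {
  # atoms: data.frame(type, serial, name, resn, chain, resno, x, y, z, elem)
  name4 <- sprintf("%-4s", paste0(" ", atoms$name))
  lines <- sprintf(
    "%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$type, atoms$serial, name4, "",
    atoms$resn, atoms$chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    1, 0, atoms$elem)
  writeLines(c(lines, "END"), path)
  path
}

# brute-force all-pairs contact oracle
naive_contacts <- function(atoms_a, atoms_b, cutoff) {
  res <- integer(0)
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                (atoms_a$y[i] - atoms_b$y[j])^2 +
                (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d <= cutoff) res <- c(res, atoms_a$resno[i])
    }
  }
  sort(unique(res))
}
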