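# Standard genetic code keyed by DNA codon, "*" for stop.
CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stopifnot(length(gc) == 64L)
  as.character(gc)
})
names(CODON_TABLE) <- names(Biostrings::GENETIC_CODE)

AA_STANDARD <- sort(setdiff(unique(CODON_TABLE), "*"))

# Isotope-averaged residue masses (Da); free water added once per chain.
RESIDUE_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2099, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.0153

IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Construct an ORF sequence
#'
#' An `orf_sequence` couples a protein-coding nucleotide sequence with the
#' codon number assigned to its first codon, so that codon numbers printed in
#' variant identifiers match protein residue numbers (e.g. a catalytic-domain
#' sub-ORF may start at codon 668).
#'
#' @param nucleotides DNA string over \{A,C,G,T\}; length must be a multiple
#'   of 3. Lower case is accepted and upper-cased.
#' @param id text label.
#' @param codon_offset codon number of the first codon (1-based).
#' @param check_internal_stop error if the translation contains an internal
#'   stop codon (a terminal stop is allowed). Set `FALSE` for variant
#'   sequences that legitimately carry premature stops.
#' @return An object of class `orf_sequence` with fields `id`, `nucleotides`
#'   and `codon_offset`.
#' @examples
#' orf <- orf_sequence("ATGGGATGA", id = "toy")
#' translate_orf(orf)
#' @export
orf_sequence <- function(nucleotides, id = "orf", codon_offset = 1L,
                         check_internal_stop = TRUE) {
  nucleotides <- toupper(as.character(nucleotides))
  if (grepl("[^ACGT]", nucleotides)) {
    stop("ORF sequence contains characters outside {A,C,G,T}")
  }
  n <- nchar(nucleotides)
  if (n == 0L || n %% 3L != 0L) {
    stop("ORF length must be a positive multiple of 3, got ", n)
  }
  x <- structure(
    list(id = as.character(id), nucleotides = nucleotides,
         codon_offset = as.integer(codon_offset)),
    class = "orf_sequence"
  )
  if (check_internal_stop) {
    aa <- translate_dna(nucleotides)
    internal <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", internal, fixed = TRUE)) {
      stop("ORF '", id, "' translation contains an internal stop codon")
    }
  }
  x
}

#' @export
print.orf_sequence <- function(x, ...) {
  cat(sprintf("orf_sequence '%s': %d nt / %d codons (codons %d-%d)\n",
              x$id, nchar(x$nucleotides), n_codons(x),
              x$codon_offset, last_codon(x)))
  invisible(x)
}

n_codons <- function(orf) nchar(orf$nucleotides) %/% 3L

last_codon <- function(orf) orf$codon_offset + n_codons(orf) - 1L

#' Split an ORF into codons
#'
#' @param orf an [orf_sequence()].
#' @return Character vector of codons named by codon number.
#' @export
orf_codons <- function(orf) {
  n <- nchar(orf$nucleotides)
  starts <- seq.int(1L, n, by = 3L)
  cod <- substring(orf$nucleotides, starts, starts + 2L)
  names(cod) <- seq.int(orf$codon_offset, length.out = length(cod))
  cod
}

# 1-based nucleotide start of a codon number within the ORF string
codon_nt_start <- function(orf, codon_number) {
  idx <- codon_number - orf$codon_offset
  if (any(idx < 0L | idx >= n_codons(orf))) {
    stop("codon number outside ORF range")
  }
  3L * idx + 1L
}

#' Translate DNA with the standard genetic code
#'
#' @param dna DNA string, length a multiple of 3, alphabet \{A,C,G,T\}.
#' @return One-letter protein string, `*` for stop codons.
#' @examples
#' translate_dna("ATGGGA")
#' @export
translate_dna <- function(dna) {
  dna <- toupper(as.character(dna))
  if (grepl("[^ACGT]", dna)) stop("non-ACGT character in sequence")
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  paste(CODON_TABLE[substring(dna, starts, starts + 2L)], collapse = "")
}

#' @rdname translate_dna
#' @param orf an [orf_sequence()].
#' @export
translate_orf <- function(orf) translate_dna(orf$nucleotides)

#' Reverse-complement a DNA string
#'
#' @param dna DNA string (IUPAC letters allowed).
#' @return The reverse complement, upper case.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}

#' Isotope-averaged protein mass
#'
#' Sums standard average residue masses and adds one water. This is the
#' "theoretical mass" convention used when comparing constructs with
#' solution-mass measurements such as SEC-MALS.
#'
#' @param protein one-letter protein string over the 20 standard residues
#'   (no stop symbol).
#' @return Mass in Daltons. Divide by 1000 for kDa.
#' @examples
#' average_protein_mass("G")   # 75.07 Da
#' average_protein_mass("GG")  # 132.12 Da
#' @export
average_protein_mass <- function(protein) {
  protein <- as.character(protein)
  if (nchar(protein) == 0L) stop("empty protein sequence")
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  m <- RESIDUE_AVG_MASS[res]
  if (anyNA(m)) {
    bad <- unique(res[is.na(m)])
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  }
  sum(m) + WATER_AVG_MASS
}

#' Define a restriction site
#'
#' @param name enzyme name, e.g. `"NheI"`.
#' @param recognition recognition sequence, IUPAC degeneracy allowed,
#'   length >= 4.
#' @return An object of class `restriction_site`.
#' @export
restriction_site <- function(name, recognition) {
  recognition <- toupper(as.character(recognition))
  if (nchar(recognition) < 4L) stop("recognition sequence must be >= 4 nt")
  if (!all(strsplit(recognition, "")[[1L]] %in% names(IUPAC_CLASS))) {
    stop("recognition sequence contains non-IUPAC characters")
  }
  structure(list(name = as.character(name), recognition = recognition),
            class = "restriction_site")
}

#' Cloning enzymes used for fragment-library ligation
#'
#' NheI (GCTAGC) and BamHI (GGATCC); the default forbidden sites for
#' [design_saturation_library()].
#' @return List of two [restriction_site()] objects.
#' @export
default_forbidden_sites <- function() {
  list(restriction_site("NheI", "GCTAGC"),
       restriction_site("BamHI", "GGATCC"))
}

iupac_regex <- function(pattern) {
  paste(IUPAC_CLASS[strsplit(toupper(pattern), "")[[1L]]], collapse = "")
}

#' Find restriction-site matches
#'
#' Degeneracy-aware exact matching of a recognition sequence; overlapping
#' matches are all reported.
#'
#' @param dna DNA string over \{A,C,G,T\}.
#' @param site a [restriction_site()].
#' @return Sorted integer vector of 0-based start offsets (empty when the
#'   site is absent).
#' @examples
#' find_restriction_sites("AAGCTAGCAA", restriction_site("NheI", "GCTAGC"))
#' @export
find_restriction_sites <- function(dna, site) {
  stopifnot(inherits(site, "restriction_site"))
  dna <- toupper(as.character(dna))
  if (nchar(dna) < nchar(site$recognition)) return(integer(0))
  m <- Biostrings::matchPattern(site$recognition, Biostrings::DNAString(dna),
                                fixed = FALSE)
  sort(BiocGenerics::start(m) - 1L)
}

#' Find CRISPR guide matches with an NGG PAM
#'
#' Scans both strands for an exact protospacer match immediately 5' of a
#' PAM-pattern hit. Coordinates are reported on the plus strand: `start` is
#' the 0-based offset of the leftmost nucleotide of the protospacer footprint.
#'
#' @param dna DNA string over \{A,C,G,T\}.
#' @param guide protospacer sequence, length >= 15.
#' @param pam_pattern PAM in IUPAC letters, default `"NGG"`.
#' @return data.frame with columns `start`, `strand`, `protospacer`, `pam`;
#'   zero rows when there is no match.
#' @export
find_guide_matches <- function(dna, guide, pam_pattern = "NGG") {
  dna <- toupper(as.character(dna))
  guide <- toupper(as.character(guide))
  if (nchar(guide) < 15L) stop("guide must be >= 15 nt")
  g <- nchar(guide)
  p <- nchar(pam_pattern)
  pat <- paste0(guide, pam_pattern)
  L <- nchar(dna)
  out <- list()
  if (L >= g + p) {
    fwd <- Biostrings::matchPattern(pat, Biostrings::DNAString(dna), fixed = FALSE)
    for (s in BiocGenerics::start(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        start = s - 1L, strand = "+",
        protospacer = substr(dna, s, s + g - 1L),
        pam = substr(dna, s + g, s + g + p - 1L),
        stringsAsFactors = FALSE)
    }
    rcdna <- reverse_complement(dna)
    rev <- Biostrings::matchPattern(pat, Biostrings::DNAString(rcdna), fixed = FALSE)
    for (s in BiocGenerics::start(rev)) {
      # protospacer occupies rc positions [s, s+g-1] -> plus-strand
      # positions [L-s-g+2, L-s+1]; report the leftmost (0-based)
      out[[length(out) + 1L]] <- data.frame(
        start = L - s - g + 1L, strand = "-",
        protospacer = substr(rcdna, s, s + g - 1L),
        pam = substr(rcdna, s + g, s + g + p - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings I/O. Sequences are upper-cased and written
#' wrapped at 60 columns.
#'
#' @param path file path.
#' @param id,codon_offset passed to [orf_sequence()]; when `id` is `NULL` the
#'   first record's header is used.
#' @return `read_orf_fasta`: an [orf_sequence()] from the first record.
#' @export
read_orf_fasta <- function(path, id = NULL, codon_offset = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  orf_sequence(as.character(set[[1L]]),
               id = if (is.null(id)) names(set)[1L] else id,
               codon_offset = codon_offset)
}

#' @rdname read_orf_fasta
#' @param sequences named character vector of DNA sequences.
#' @export
write_dna_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
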