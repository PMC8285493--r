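# Human codon usage, frequency per 1000 codons (standard GenBank-derived
# table). Used only as a deterministic tie-break when ranking candidate
# codons; small inaccuracies do not affect correctness.
HUMAN_CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA =  7.7, TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA =  7.2, CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA =  7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA =  7.1, GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG =  4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG =  6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG =  6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG =  7.4,
  TAT = 12.2, TAC = 15.3, TAA =  1.0, TAG =  0.8,
  CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGA =  1.6, TGG = 13.2,
  CGT =  4.5, CGC = 10.4, CGA =  6.2, CGG = 11.4,
  AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5
)

codon_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Rank candidate codons for a target amino acid
#'
#' Candidates encoding `target_aa` (excluding the wild-type codon itself) are
#' ordered by descending nucleotide Hamming distance from the wild-type codon
#' — the design deliberately minimizes use of codons one nucleotide away from
#' the template, so that single sequencing errors are not mistaken for
#' designed variants — with ties broken by descending human codon usage, then
#' alphabetically.
#'
#' @param wt_codon wild-type codon (DNA triplet).
#' @param target_aa one-letter target amino acid, `"*"` for stop.
#' @return Character vector of candidate codons, best first (possibly empty).
#' @export
rank_codons <- function(wt_codon, target_aa) {
  wt_codon <- toupper(wt_codon)
  cands <- names(CODON_TABLE)[CODON_TABLE == target_aa]
  cands <- setdiff(cands, wt_codon)
  if (length(cands) == 0L) return(character(0))
  d <- vapply(cands, codon_hamming, integer(1), a = wt_codon)
  usage <- HUMAN_CODON_USAGE[cands]
  cands[order(-d, -usage, cands)]
}

#' Design constraints for a codon-saturation library
#'
#' @param region_start,region_end first and last codon number (inclusive) of
#'   the mutagenized region.
#' @param forbidden_sites list of [restriction_site()] objects that no
#'   variant sequence may contain (default the NheI/BamHI cloning sites).
#' @param silent_count number of silent (synonymous) control variants to
#'   place, evenly spaced across the region.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(region_start, region_end,
                               forbidden_sites = default_forbidden_sites(),
                               silent_count = 0L) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (region_start > region_end) stop("region_start must be <= region_end")
  if (silent_count < 0L) stop("silent_count must be non-negative")
  stopifnot(all(vapply(forbidden_sites, inherits, logical(1), "restriction_site")))
  structure(list(region_start = region_start, region_end = region_end,
                 forbidden_sites = forbidden_sites,
                 silent_count = as.integer(silent_count)),
            class = "design_constraints")
}

# Does `window` (a short string around the edited codon) contain any
# forbidden site? Sites are checked with IUPAC-aware regexes.
window_has_site <- function(windows, site_regexes) {
  hit <- rep(FALSE, length(windows))
  for (rx in site_regexes) {
    hit <- hit | grepl(rx, windows, perl = TRUE)
  }
  hit
}

variant_id_for <- function(wt_aa, codon_number, alt_aa, alt_codon, var_class) {
  base <- sprintf("%s%d%s", wt_aa, codon_number, alt_aa)
  ifelse(var_class == "silent", paste0(base, ".", alt_codon), base)
}

#' Design a codon-saturation variant library
#'
#' For every codon in the constrained region the design attempts 19 missense
#' substitutions and 1 nonsense substitution (one per non-wild-type target
#' amino acid, stop included). Candidate codons per target are ranked by
#' [rank_codons()]; a candidate whose substitution creates a forbidden
#' restriction site within the local window around the codon is rejected in
#' favor of the next-ranked candidate, and targets with no surviving
#' candidate are recorded as dropped with reason `"restriction_site"`.
#' Silent control variants are placed at `silent_count` evenly spaced
#' positions, each receiving its top-ranked synonymous alternative codon;
#' positions with no usable synonymous alternative (Met, Trp) are skipped in
#' favor of the next position.
#'
#' The design is a pure function of its inputs: repeated runs are identical.
#'
#' @param orf reference [orf_sequence()]; must itself be free of the
#'   forbidden sites.
#' @param constraints a [design_constraints()].
#' @return An object of class `library_design`: list with `reference`, a
#'   `variants` data.frame (`variant_id`, `codon_number`, `wt_codon`,
#'   `alt_codon`, `wt_aa`, `alt_aa`, `var_class`, `nt_distance`) and a
#'   `dropped` data.frame (`codon_number`, `alt_aa`, `reason`).
#' @export
design_saturation_library <- function(orf, constraints) {
  stopifnot(inherits(orf, "orf_sequence"), inherits(constraints, "design_constraints"))
  if (constraints$region_start < orf$codon_offset ||
      constraints$region_end > last_codon(orf)) {
    stop("design region lies outside the ORF codon range")
  }
  sites <- constraints$forbidden_sites
  for (s in sites) {
    if (length(find_restriction_sites(orf$nucleotides, s)) > 0L) {
      stop("reference ORF already contains forbidden site ", s$name)
    }
  }
  site_regexes <- vapply(sites, function(s) iupac_regex(s$recognition), character(1))
  max_site <- if (length(sites)) max(vapply(sites, function(s) nchar(s$recognition), integer(1))) else 0L
  flank <- max(0L, max_site - 1L)
  seqstr <- orf$nucleotides
  L <- nchar(seqstr)
  codons <- orf_codons(orf)
  region <- seq.int(constraints$region_start, constraints$region_end)

  # memoized candidate rankings: one per (wt codon, target aa)
  rank_cache <- new.env(parent = emptyenv())
  ranked <- function(wt, aa) {
    key <- paste0(wt, aa)
    if (is.null(rank_cache[[key]])) rank_cache[[key]] <- rank_codons(wt, aa)
    rank_cache[[key]]
  }

  # pick the best candidate codon that does not create a forbidden site in
  # the local window; NA if none survives
  pick_codon <- function(codon_number, cands) {
    if (length(cands) == 0L) return(NA_character_)
    if (length(site_regexes) == 0L) return(cands[[1L]])
    nt <- codon_nt_start(orf, codon_number)
    left <- substr(seqstr, max(1L, nt - flank), nt - 1L)
    right <- substr(seqstr, nt + 3L, min(L, nt + 2L + flank))
    windows <- paste0(left, cands, right)
    ok <- !window_has_site(windows, site_regexes)
    if (!any(ok)) return(NA_character_)
    cands[which(ok)[1L]]
  }

  nmax <- length(region) * 21L
  v_cn <- integer(nmax); v_wtc <- character(nmax); v_alt <- character(nmax)
  v_wta <- character(nmax); v_alta <- character(nmax); v_cls <- character(nmax)
  d_cn <- integer(0); d_aa <- character(0)
  k <- 0L
  targets_all <- c(AA_STANDARD, "*")
  for (cn in region) {
    wt_codon <- codons[[as.character(cn)]]
    wt_aa <- CODON_TABLE[[wt_codon]]
    for (aa in setdiff(targets_all, wt_aa)) {
      alt <- pick_codon(cn, ranked(wt_codon, aa))
      if (is.na(alt)) {
        d_cn <- c(d_cn, cn); d_aa <- c(d_aa, aa)
      } else {
        k <- k + 1L
        v_cn[k] <- cn; v_wtc[k] <- wt_codon; v_alt[k] <- alt
        v_wta[k] <- wt_aa; v_alta[k] <- aa
        v_cls[k] <- if (aa == "*") "nonsense" else "missense"
      }
    }
  }

  # silent controls at evenly spaced positions
  if (constraints$silent_count > 0L) {
    has_syn <- vapply(region, function(cn) {
      wt <- codons[[as.character(cn)]]
      !is.na(pick_codon(cn, ranked(wt, CODON_TABLE[[wt]])))
    }, logical(1))
    if (constraints$silent_count > sum(has_syn)) {
      stop("silent_count (", constraints$silent_count,
           ") exceeds the number of positions with a usable synonymous alternative (",
           sum(has_syn), ")")
    }
    want <- unique(round(seq(1L, length(region), length.out = constraints$silent_count)))
    used <- logical(length(region))
    chosen <- integer(0)
    for (w in want) {
      i <- w
      repeat {
        if (i > length(region)) i <- 1L  # wrap; capacity checked above
        if (!used[i] && has_syn[i]) break
        i <- i + 1L
      }
      used[i] <- TRUE
      chosen <- c(chosen, i)
    }
    # top-up in case rounding collapsed spaced positions onto each other
    while (length(chosen) < constraints$silent_count) {
      i <- which(!used & has_syn)[1L]
      used[i] <- TRUE
      chosen <- c(chosen, i)
    }
    for (i in sort(chosen)) {
      cn <- region[i]
      wt_codon <- codons[[as.character(cn)]]
      wt_aa <- CODON_TABLE[[wt_codon]]
      if (k + 1L > nmax) {  # grow (silent rows exceed preallocation margin)
        nmax <- nmax + constraints$silent_count
        length(v_cn) <- nmax; length(v_wtc) <- nmax; length(v_alt) <- nmax
        length(v_wta) <- nmax; length(v_alta) <- nmax; length(v_cls) <- nmax
      }
      k <- k + 1L
      v_cn[k] <- cn; v_wtc[k] <- wt_codon
      v_alt[k] <- pick_codon(cn, ranked(wt_codon, wt_aa))
      v_wta[k] <- wt_aa; v_alta[k] <- wt_aa; v_cls[k] <- "silent"
    }
  }

  idx <- seq_len(k)
  nt_distance <- integer(k)
  for (p in 1:3) {
    nt_distance <- nt_distance +
      (substr(v_wtc[idx], p, p) != substr(v_alt[idx], p, p))
  }
  variants <- data.frame(
    variant_id = character(k), codon_number = v_cn[idx],
    wt_codon = v_wtc[idx], alt_codon = v_alt[idx],
    wt_aa = v_wta[idx], alt_aa = v_alta[idx], var_class = v_cls[idx],
    nt_distance = as.integer(nt_distance), stringsAsFactors = FALSE)
  variants$variant_id <- variant_id_for(variants$wt_aa, variants$codon_number,
                                        variants$alt_aa, variants$alt_codon,
                                        variants$var_class)
  ord <- order(variants$codon_number, variants$alt_aa, variants$alt_codon)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dropped <- data.frame(codon_number = d_cn, alt_aa = d_aa,
                        reason = rep("restriction_site", length(d_cn)),
                        stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  structure(list(reference = orf, variants = variants, dropped = dropped),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cls <- table(x$variants$var_class)
  cat(sprintf("library_design on '%s': %d variants (%s), %d dropped\n",
              x$reference$id, nrow(x$variants),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", "),
              nrow(x$dropped)))
  invisible(x)
}

#' Full-length nucleotide sequence of designed variants
#'
#' @param design a [library_design()].
#' @param variant_id one or more variant identifiers (default: all).
#' @return Named character vector of full-length variant sequences, each
#'   differing from the reference in exactly one codon.
#' @export
variant_sequences <- function(design, variant_id = design$variants$variant_id) {
  v <- design$variants[match(variant_id, design$variants$variant_id), , drop = FALSE]
  if (anyNA(v$codon_number)) stop("unknown variant_id")
  ref <- design$reference$nucleotides
  out <- vapply(seq_len(nrow(v)), function(i) {
    nt <- codon_nt_start(design$reference, v$codon_number[i])
    paste0(substr(ref, 1L, nt - 1L), v$alt_codon[i],
           substr(ref, nt + 3L, nchar(ref)))
  }, character(1))
  names(out) <- v$variant_id
  out
}

#' Synonymously recode CRISPR PAM/protospacer matches out of an ORF
#'
#' Used to make a rescue cDNA resistant to the knockout guide: each detected
#' guide match is destroyed by a single synonymous codon change inside the
#' protospacer/PAM footprint, preferring the codon closest to the PAM (the
#' seed region, where mismatches are least tolerated by Cas9).
#'
#' @param orf an [orf_sequence()].
#' @param guide protospacer sequence (>= 15 nt).
#' @param pam_pattern PAM pattern, default `"NGG"`.
#' @return An object of class `recoded_orf`: list with `orf` (the recoded
#'   [orf_sequence()]) and `edits` data.frame (`codon_number`, `wt_codon`,
#'   `new_codon`).
#' @export
recode_pam_sites <- function(orf, guide, pam_pattern = "NGG") {
  stopifnot(inherits(orf, "orf_sequence"))
  seqstr <- orf$nucleotides
  edits <- list()
  aa_ref <- translate_dna(orf$nucleotides)
  repeat {
    matches <- find_guide_matches(seqstr, guide, pam_pattern)
    if (nrow(matches) == 0L) break
    m <- matches[1L, ]
    # footprint (1-based, plus strand): PAM sits 3' of the protospacer, i.e.
    # right of it for '+' matches and left of it for '-' matches
    if (m$strand == "+") {
      foot_start <- m$start + 1L
      foot_end <- m$start + nchar(guide) + nchar(pam_pattern)
    } else {
      foot_start <- max(1L, m$start + 1L - nchar(pam_pattern))
      foot_end <- m$start + nchar(guide)
    }
    # codon indices overlapping the footprint
    first_ci <- (foot_start - 1L) %/% 3L
    last_ci <- min((foot_end - 1L) %/% 3L, n_codons(orf) - 1L)
    cis <- first_ci:last_ci
    # seed-proximal ordering: PAM is at the right end for '+' matches and at
    # the left end (in plus coordinates) for '-' matches
    cis <- if (m$strand == "+") rev(cis) else cis
    fixed <- FALSE
    for (ci in cis) {
      nt <- 3L * ci + 1L
      wt_codon <- substr(seqstr, nt, nt + 2L)
      for (alt in rank_codons(wt_codon, CODON_TABLE[[wt_codon]])) {
        cand <- paste0(substr(seqstr, 1L, nt - 1L), alt,
                       substr(seqstr, nt + 3L, nchar(seqstr)))
        if (nrow(find_guide_matches(cand, guide, pam_pattern)) < nrow(matches)) {
          edits[[length(edits) + 1L]] <- data.frame(
            codon_number = orf$codon_offset + ci,
            wt_codon = wt_codon, new_codon = alt, stringsAsFactors = FALSE)
          seqstr <- cand
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      stop(sprintf(paste0("guide match at offset %d (%s strand) cannot be ",
                          "recoded: no synonymous codon change in its ",
                          "footprint removes it"), m$start, m$strand))
    }
  }
  out <- orf_sequence(seqstr, id = paste0(orf$id, "_recoded"),
                      codon_offset = orf$codon_offset,
                      check_internal_stop = FALSE)
  stopifnot(translate_dna(out$nucleotides) == aa_ref)
  structure(list(orf = out,
                 edits = if (length(edits)) do.call(rbind, edits) else
                   data.frame(codon_number = integer(0), wt_codon = character(0),
                              new_codon = character(0), stringsAsFactors = FALSE)),
            class = "recoded_orf")
}

#' Write and read a library design
#'
#' `write_library` writes a TSV of the variant table (deterministic row
#' order) plus a FASTA of full-length variant sequences; `read_library`
#' reconstructs an equal `library_design` from the TSV and the reference ORF.
#'
#' @param design a [library_design()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.fasta`.
#' @return `write_library`: invisibly, the two paths written.
#' @export
write_library <- function(design, prefix) {
  tsv <- paste0(prefix, ".tsv")
  fa <- paste0(prefix, ".fasta")
  write.table(design$variants, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_dna_fasta(variant_sequences(design), fa)
  invisible(c(tsv, fa))
}

#' @rdname write_library
#' @param path path to a variant-table TSV written by `write_library`.
#' @param orf the reference [orf_sequence()] the table refers to.
#' @export
read_library <- function(path, orf) {
  v <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(variant_id = "character", codon_number = "integer",
                                 wt_codon = "character", alt_codon = "character",
                                 wt_aa = "character", alt_aa = "character",
                                 var_class = "character", nt_distance = "integer"))
  structure(list(reference = orf, variants = v,
                 dropped = data.frame(codon_number = integer(0),
                                      alt_aa = character(0), reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "library_design")
}

#' Read a design configuration file
#'
#' YAML with keys `region_start`, `region_end`, `silent_count`, optional
#' `forbidden_sites` (list of `name`/`recognition` pairs) and optional
#' `guide` (protospacer for PAM recoding).
#'
#' @param path YAML file.
#' @return list with `constraints` (a [design_constraints()]) and `guide`
#'   (character or `NULL`).
#' @export
read_design_config <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- if (is.null(y$forbidden_sites)) default_forbidden_sites() else
    lapply(y$forbidden_sites, function(s) restriction_site(s$name, s$recognition))
  list(constraints = design_constraints(
         region_start = y$region_start, region_end = y$region_end,
         forbidden_sites = sites,
         silent_count = if (is.null(y$silent_count)) 0L else y$silent_count),
       guide = y$guide)
}
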