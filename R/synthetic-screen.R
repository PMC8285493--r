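#' Generate a synthetic reference ORF
#'
#' Draws random sense codons (weighted by human codon usage) and removes any
#' occurrence of the forbidden restriction sites by resampling the codons
#' that overlap them, so the result is a valid saturation-design reference.
#' The sequence is synthetic: it emulates the length and codon numbering of a
#' real ORF (e.g. a 1141-codon full-length cDNA) without being one.
#'
#' @param n_codons number of (sense) codons.
#' @param codon_offset codon number of the first codon.
#' @param forbidden_sites sites to exclude from the sequence.
#' @param seed RNG seed (`NULL` = use the current stream).
#' @param id sequence label.
#' @return An [orf_sequence()].
#' @export
synthetic_orf <- function(n_codons, codon_offset = 1L,
                          forbidden_sites = default_forbidden_sites(),
                          seed = NULL, id = "synthetic_orf") {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(CODON_TABLE)[CODON_TABLE != "*"]
  w <- HUMAN_CODON_USAGE[sense]
  codons <- sample(sense, n_codons, replace = TRUE, prob = w)
  seqstr <- paste(codons, collapse = "")
  repeat {
    offs <- unlist(lapply(forbidden_sites, function(s)
      find_restriction_sites(seqstr, s)))
    if (length(offs) == 0L) break
    ci <- unique((offs[1L]) %/% 3L) + 1L   # codon overlapping the site start
    codons[ci] <- sample(sense, 1L, prob = w)
    seqstr <- paste(codons, collapse = "")
  }
  orf_sequence(seqstr, id = id, codon_offset = codon_offset,
               check_internal_stop = TRUE)
}

#' Rule-based fitness model for the synthetic screen
#'
#' Selection emulates a drug that kills cells expressing functional protein:
#' loss-of-function variants carry weight 1 under the drug conditions while
#' functional variants carry a small residual survival weight `delta`; every
#' variant has weight 1 under T0, DMSO and the non-cytotoxic inhibitor arm.
#' Ground-truth loss of function is (i) a nonsense variant upstream of the
#' last `tail_codons` codons (a premature stop in the C-terminal tail leaves
#' the protein functional) or (ii) membership in a programmed resistance set
#' of missense variants.
#'
#' @param design a [library_design()].
#' @param resistance_set data.frame with columns `codon_number` and `alt_aa`
#'   naming programmed resistance missense variants (default: none).
#' @param delta residual survival weight of functional variants under drug
#'   (default 0.05).
#' @param tail_codons length of the C-terminal tail where stops are
#'   tolerated (default 59).
#' @return list of class `fitness_model` with per-variant `lof` flags.
#' @export
fitness_model <- function(design, resistance_set = NULL, delta = 0.05,
                          tail_codons = 59L) {
  stopifnot(delta >= 0, delta <= 1)
  v <- design$variants
  boundary <- last_codon(design$reference) - tail_codons
  lof <- v$var_class == "nonsense" & v$codon_number <= boundary
  if (!is.null(resistance_set)) {
    key <- paste(v$codon_number, v$alt_aa)
    lof <- lof | key %in% paste(resistance_set$codon_number, resistance_set$alt_aa)
  }
  names(lof) <- v$variant_id
  structure(list(lof = lof, delta = delta, boundary = boundary),
            class = "fitness_model")
}

# per-entry survival weights for a named abundance vector (variants + "WT")
fitness_weights <- function(fitness, condition, ids) {
  if (!condition %in% SCREEN_CONDITIONS) stop("unknown condition: ", condition)
  if (!condition %in% c("DNMDP10", "DNMDP100")) return(rep(1, length(ids)))
  lof <- fitness$lof[ids]
  lof[is.na(lof)] <- FALSE      # WT carrier and any unknown id: functional
  ifelse(lof, 1, fitness$delta)
}

#' Synthetic screen configuration
#'
#' @param depth sequencing reads per sample.
#' @param replicates replicates per condition (>= 2).
#' @param sigma log-normal sigma of library representation.
#' @param dropout fraction of variants set to near-zero representation
#'   (exercises the bottom-percentile T0 filter).
#' @param error_rate per-base substitution sequencing error rate.
#' @param read_length read length in nt for simulated FASTQ.
#' @param wt_fraction abundance share of the unmutated carrier clone.
#' @param seed RNG seed; every downstream artifact is reproducible from
#'   (config, seed).
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(depth = 1e6, replicates = 2L, sigma = 1,
                              dropout = 0.05, error_rate = 0.001,
                              read_length = 150L, wt_fraction = 0.01,
                              seed = 1L) {
  stopifnot(depth > 0, replicates >= 2L, error_rate >= 0, error_rate <= 0.05,
            dropout >= 0, dropout < 1, wt_fraction >= 0, wt_fraction < 1)
  structure(list(depth = depth, replicates = as.integer(replicates),
                 sigma = sigma, dropout = dropout, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 wt_fraction = wt_fraction, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate library representation at T0
#'
#' Variant abundances are i.i.d. log-normal, a `dropout` fraction of variants
#' is crushed to near-zero representation, the wild-type carrier receives a
#' fixed `wt_fraction` share, and the vector is renormalized to sum to 1.
#'
#' @param design a [library_design()].
#' @param config a [screen_sim_config()].
#' @param seed RNG seed (`NULL` = current stream; [simulate_screen()] seeds
#'   once and passes `NULL`).
#' @return Named abundance vector over variant ids plus `"WT"`, summing to 1.
#' @export
simulate_representation <- function(design, config = screen_sim_config(),
                                    seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design$variants)
  stopifnot(n > 0L)
  a <- rlnorm(n, meanlog = 0, sdlog = config$sigma)
  n_drop <- floor(config$dropout * n)
  if (n_drop > 0L) {
    drop_idx <- sample.int(n, n_drop)
    a[drop_idx] <- a[drop_idx] * 1e-4
  }
  a <- a / sum(a) * (1 - config$wt_fraction)
  out <- c(a, WT = config$wt_fraction)
  names(out) <- c(design$variants$variant_id, "WT")
  out / sum(out)
}

#' Apply one round of proportional selection
#'
#' `abundance'(v) = abundance(v) * weight(v, condition) / sum(...)`.
#'
#' @param abundances named, normalized abundance vector (ids + `"WT"`).
#' @param fitness a [fitness_model()].
#' @param condition screen condition name.
#' @return Renormalized post-selection abundances.
#' @export
apply_selection <- function(abundances, fitness, condition) {
  w <- fitness_weights(fitness, condition, names(abundances))
  a <- abundances * w
  a / sum(a)
}

#' Multinomial sequencing counts
#'
#' @param abundances normalized abundance vector.
#' @param depth total reads to draw.
#' @param seed RNG seed (`NULL` = current stream).
#' @return Named integer counts summing to `depth`.
#' @export
simulate_counts <- function(abundances, depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.vector(rmultinom(1L, size = depth, prob = abundances))
  names(counts) <- names(abundances)
  counts
}

#' Ground-truth table of a synthetic screen
#'
#' @param design a [library_design()].
#' @param fitness a [fitness_model()].
#' @param t0_abundance from [simulate_representation()].
#' @return data.frame with per-variant T0 abundance, expected post-selection
#'   abundance per condition, and the `lof` ground-truth flag.
#' @export
truth_table <- function(design, fitness, t0_abundance) {
  out <- data.frame(variant_id = names(t0_abundance),
                    t0 = as.numeric(t0_abundance),
                    stringsAsFactors = FALSE)
  for (cond in setdiff(SCREEN_CONDITIONS, "T0")) {
    out[[paste0("expected_", tolower(cond))]] <-
      as.numeric(apply_selection(t0_abundance, fitness, cond))
  }
  lof <- fitness$lof[out$variant_id]
  lof[is.na(lof)] <- FALSE
  out$lof <- as.logical(lof)
  out
}

#' Simulate a full selection screen at the counts level
#'
#' Seeds the generator once from the config, draws the T0 representation,
#' applies the fitness rule per condition, and draws one multinomial count
#' vector per sample (T0 and all four arms, `replicates` each). Reserved
#' read-class rows are present (zero: counts-level simulation produces no
#' discarded reads) so the matrix satisfies the counts-conservation contract.
#'
#' @param design a [library_design()].
#' @param fitness a [fitness_model()] (default: no programmed missense
#'   resistance, nonsense-only loss of function).
#' @param config a [screen_sim_config()].
#' @param conditions arms to draw (default all five).
#' @return list with `counts` (matrix), `sheet` ([sample_sheet()]), `truth`
#'   ([truth_table()]) and `config`.
#' @export
simulate_screen <- function(design, fitness = fitness_model(design),
                            config = screen_sim_config(),
                            conditions = SCREEN_CONDITIONS) {
  set.seed(config$seed)
  t0_abund <- simulate_representation(design, config, seed = NULL)
  truth <- truth_table(design, fitness, t0_abund)
  sheet_rows <- expand.grid(replicate = seq_len(config$replicates),
                            condition = conditions,
                            stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_rep%d", sheet_rows$condition, sheet_rows$replicate)
  rows <- c(design$variants$variant_id, READ_CLASSES)
  counts <- matrix(0L, nrow = length(rows), ncol = length(sample_ids),
                   dimnames = list(rows, sample_ids))
  for (i in seq_along(sample_ids)) {
    abund <- apply_selection(t0_abund, fitness, sheet_rows$condition[i])
    cts <- simulate_counts(abund, config$depth, seed = NULL)
    counts[names(cts)[names(cts) != "WT"], i] <- cts[names(cts) != "WT"]
    counts["WT", i] <- cts[["WT"]]
  }
  attr(counts, "total_reads") <- setNames(rep(config$depth, length(sample_ids)),
                                          sample_ids)
  list(counts = counts,
       sheet = sample_sheet(sample_ids, sheet_rows$condition,
                            sheet_rows$replicate),
       truth = truth, config = config)
}

random_base_error <- function(bases, error_rate) {
  n <- length(bases)
  err <- runif(n) < error_rate
  if (any(err)) {
    alts <- c("A", "C", "G", "T")
    bases[err] <- vapply(bases[err], function(b)
      sample(setdiff(alts, b), 1L), character(1))
  }
  bases
}

#' Simulate paired amplicon reads for counted variants
#'
#' For every counted variant (and the wild-type carrier) the requested number
#' of read pairs is drawn from random fragments of the variant's full-length
#' sequence. Fragments always cover the variant's mutated codon, so an
#' error-free simulation round-trips exactly through
#' [tally_counts()]. Substitution errors are applied per base at
#' the configured rate; qualities are written as a constant Q37.
#'
#' @param design a [library_design()].
#' @param counts named integer vector (variant ids, optionally `"WT"`) of
#'   read-pair counts for one sample.
#' @param config a [screen_sim_config()].
#' @param seed RNG seed (`NULL` = current stream).
#' @return List of read pairs in the format consumed by
#'   [tally_counts()].
#' @export
simulate_reads <- function(design, counts, config = screen_sim_config(),
                           seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[counts > 0]
  L <- config$read_length
  ref <- design$reference$nucleotides
  amp <- nchar(ref)
  if (L > amp) stop("read length exceeds amplicon length")
  min_flen <- L
  max_flen <- min(2L * L - 40L, amp)
  pairs <- list()
  for (vid in names(counts)) {
    if (vid %in% READ_CLASSES && vid != "WT") next
    full <- if (vid == "WT") ref else variant_sequences(design, vid)[[1L]]
    if (vid == "WT") {
      nt <- 1L + 3L * sample.int(n_codons(design$reference), 1L)  # arbitrary anchor
      nt <- min(nt, amp - 2L)
    } else {
      nt <- codon_nt_start(design$reference,
                           design$variants$codon_number[
                             match(vid, design$variants$variant_id)])
    }
    for (r in seq_len(counts[[vid]])) {
      flen <- sample(min_flen:max_flen, 1L)
      lo <- max(1L, nt + 2L - flen + 1L)
      hi <- min(nt, amp - flen + 1L)
      if (hi < lo) { lo <- 1L; hi <- amp - flen + 1L }
      start <- if (hi > lo) sample(lo:hi, 1L) else lo
      frag <- strsplit(substr(full, start, start + flen - 1L), "")[[1L]]
      frag <- random_base_error(frag, config$error_rate)
      s1 <- paste(frag[seq_len(L)], collapse = "")
      s2 <- reverse_complement(paste(frag[(flen - L + 1L):flen], collapse = ""))
      pairs[[length(pairs) + 1L]] <- list(
        id = sprintf("%s_%d", vid, r),
        seq1 = s1, qual1 = rep(37L, L),
        seq2 = s2, qual2 = rep(37L, L))
    }
  }
  pairs
}

#' Write read pairs as paired FASTQ
#'
#' @param pairs list of read pairs (from [simulate_reads()]).
#' @param path1,path2 output FASTQ paths for mate 1 / mate 2.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  to_set <- function(field, qfield) {
    s <- Biostrings::DNAStringSet(vapply(pairs, `[[`, character(1), field))
    names(s) <- vapply(pairs, `[[`, character(1), "id")
    q <- Biostrings::PhredQuality(vapply(pairs, function(p)
      paste(rawToChar(as.raw(p[[qfield]] + 33L)), collapse = ""), character(1)))
    Biostrings::QualityScaledDNAStringSet(s, q)
  }
  Biostrings::writeQualityScaledXStringSet(to_set("seq1", "qual1"), path1)
  Biostrings::writeQualityScaledXStringSet(to_set("seq2", "qual2"), path2)
  invisible(c(path1, path2))
}

#' Residues used as the programmed-resistance exemplar set
#'
#' Five residues of the PDE3A catalytic domain representative of the three
#' structural hit categories: the homodimer interface (867), the
#' SLFN12-binding surface (914) and the active site (961, 1001, 1004). The
#' default programmed resistance set of the synthetic screen comprises every
#' missense variant at these residues.
#' @return Integer vector of residue numbers.
#' @export
example_resistance_residues <- function() c(867L, 914L, 961L, 1001L, 1004L)

#' @rdname example_resistance_residues
#' @param design a [library_design()].
#' @param residues residue numbers (default [example_resistance_residues()]).
#' @return `example_resistance_set`: data.frame (`codon_number`, `alt_aa`) of
#'   all missense variants at those residues, for [fitness_model()].
#' @export
example_resistance_set <- function(design,
                                   residues = example_resistance_residues()) {
  v <- design$variants
  sel <- v$codon_number %in% residues & v$var_class == "missense"
  data.frame(codon_number = v$codon_number[sel], alt_aa = v$alt_aa[sel],
             stringsAsFactors = FALSE)
}
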