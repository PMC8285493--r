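SCREEN_CONDITIONS <- c("T0", "DMSO", "DNMDP10", "DNMDP100", "TREQ100")

#' Screen sample sheet
#'
#' @param sample_id unique sample identifiers matching counts-matrix columns.
#' @param condition one of `T0`, `DMSO`, `DNMDP10`, `DNMDP100`, `TREQ100`.
#' @param replicate integer replicate index within condition.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, replicate) {
  stopifnot(!anyDuplicated(sample_id), all(condition %in% SCREEN_CONDITIONS))
  if (!any(condition == "T0")) stop("sample sheet must contain at least one T0 sample")
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = as.character(condition),
                   replicate = as.integer(replicate),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param path TSV with columns sample_id, condition, replicate.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sample_sheet(df$sample_id, df$condition, df$replicate)
}

#' Scoring parameters
#'
#' @param t0_percentile percentile of the T0-fraction distribution below
#'   which variants are flagged low confidence (default 8, i.e. the bottom
#'   8\% are excluded).
#' @param pseudocount reads added to every count before fractions (default
#'   0.5; guards against zero post-selection counts of dying variants).
#' @param hit_sd_multiplier resistance threshold in standard deviations of
#'   the LFC distribution (default 1).
#' @param control_condition compound control arm, `"DMSO"` (default) or
#'   `"TREQ100"`.
#' @param t0_pooling `"pooled"` (default: each day-5 replicate is normalized
#'   by the mean T0 fraction, matching a screen where T0 was harvested before
#'   the split into arms) or `"matched"` (replicate-matched T0).
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(t0_percentile = 8, pseudocount = 0.5,
                           hit_sd_multiplier = 1, control_condition = "DMSO",
                           t0_pooling = c("pooled", "matched")) {
  stopifnot(t0_percentile > 0, t0_percentile < 100, pseudocount >= 0,
            control_condition %in% c("DMSO", "TREQ100"))
  structure(list(t0_percentile = t0_percentile, pseudocount = pseudocount,
                 log_base = 2, hit_sd_multiplier = hit_sd_multiplier,
                 control_condition = control_condition,
                 t0_pooling = match.arg(t0_pooling)),
            class = "scoring_params")
}

# rows of a counts matrix that represent assigned reads (designed variants
# plus the wild-type carrier); discard classes are excluded from the
# denominator
assigned_rows <- function(counts) {
  setdiff(rownames(counts), setdiff(READ_CLASSES, "WT"))
}

#' Per-sample variant fractions
#'
#' `fraction(v, s) = (count(v, s) + pseudocount) / (assigned(s) + pseudocount)`
#' where `assigned(s)` is the sample's total over the wild-type row and all
#' designed variants (discard classes excluded).
#'
#' @param counts variant-by-sample integer matrix (reserved rows allowed).
#' @param pseudocount see [scoring_params()].
#' @return Matrix of fractions over the assigned rows.
#' @export
compute_fractions <- function(counts, pseudocount = 0.5) {
  rows <- assigned_rows(counts)
  m <- counts[rows, , drop = FALSE]
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero assigned reads: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  }
  sweep(m + pseudocount, 2L, tot + pseudocount, "/")
}

#' Nearest-rank bottom-percentile filter on T0 fractions
#'
#' The threshold is the nearest-rank p-th percentile (the smallest observed
#' value such that at least p\% of observations are <= it); every variant at
#' or below the threshold is flagged, so ties at the threshold are all
#' excluded. With all-distinct fractions over n variants exactly
#' `ceiling(p/100 * n)` are flagged.
#'
#' @param t0_fraction numeric vector of mean T0 fractions.
#' @param t0_percentile percentile p in (0, 100), default 8.
#' @return Logical vector: `TRUE` = low confidence.
#' @export
filter_low_t0 <- function(t0_fraction, t0_percentile = 8) {
  n <- length(t0_fraction)
  if (n < 1L) stop("need at least one variant")
  rank <- ceiling(t0_percentile / 100 * n)
  threshold <- sort(t0_fraction)[rank]
  t0_fraction <= threshold
}

#' Survival log2 fold change, treatment versus control
#'
#' Per replicate, each day-5 fraction is normalized to the T0 fraction
#' (pooled or replicate-matched, see [scoring_params()]); normalized
#' abundances are averaged across replicates, and
#' `lfc = log2(mean_treatment / mean_control)`.
#'
#' @param fractions matrix from [compute_fractions()].
#' @param sheet a [sample_sheet()].
#' @param treatment,control condition names present in the sheet.
#' @param params a [scoring_params()].
#' @return Named numeric LFC vector over the rows of `fractions`.
#' @export
survival_lfc <- function(fractions, sheet, treatment, control = NULL,
                         params = scoring_params()) {
  if (is.null(control)) control <- params$control_condition
  for (cond in c(treatment, control)) {
    if (!any(sheet$condition == cond)) stop("condition absent from sheet: ", cond)
  }
  norm_mean <- function(cond) {
    reps <- sheet[sheet$condition == cond, , drop = FALSE]
    t0 <- sheet[sheet$condition == "T0", , drop = FALSE]
    norms <- vapply(seq_len(nrow(reps)), function(i) {
      f <- fractions[, reps$sample_id[i]]
      t0f <- if (params$t0_pooling == "matched") {
        j <- match(reps$replicate[i], t0$replicate)
        if (is.na(j)) stop("no matched T0 replicate ", reps$replicate[i])
        fractions[, t0$sample_id[j]]
      } else {
        rowMeans(fractions[, t0$sample_id, drop = FALSE])
      }
      f / t0f
    }, numeric(nrow(fractions)))
    rowMeans(matrix(norms, nrow = nrow(fractions)))
  }
  lfc <- log2(norm_mean(treatment) / norm_mean(control))
  names(lfc) <- rownames(fractions)
  lfc
}

#' Standardize LFCs to z-scores
#'
#' @param lfc numeric vector (no NAs) over retained variants.
#' @return `(lfc - mean) / sd` with the sample (n-1) standard deviation.
#' @export
z_scores <- function(lfc) {
  if (length(lfc) < 2L) stop("need >= 2 retained variants")
  s <- sd(lfc)
  if (s == 0) stop("zero standard deviation: z-scores undefined")
  (lfc - mean(lfc)) / s
}

#' Call resistance hits
#'
#' A variant is a hit when its LFC exceeds the mean by more than
#' `hit_sd_multiplier` standard deviations *and* is positive (enriched under
#' treatment relative to control).
#'
#' @param lfc numeric LFC vector over retained variants.
#' @param hit_sd_multiplier see [scoring_params()].
#' @return Logical hit flags.
#' @export
call_hits <- function(lfc, hit_sd_multiplier = 1) {
  s <- sd(lfc)
  if (is.na(s) || s == 0) return(rep(FALSE, length(lfc)))
  lfc > mean(lfc) + hit_sd_multiplier * s & lfc > 0
}

#' Score a screen end to end
#'
#' Computes fractions, applies the bottom-percentile T0 filter, forms
#' treatment-versus-control LFCs for 100 nM drug against both compound
#' controls, standardizes the drug-versus-DMSO LFC over retained variants
#' and calls resistance hits. Low-confidence variants carry `NA` LFC/z/hit.
#'
#' @param counts variant-by-sample counts matrix (reserved rows allowed).
#' @param sheet a [sample_sheet()].
#' @param design the [library_design()] (adds codon/class annotation).
#' @param params a [scoring_params()].
#' @param exclusion optional character vector of variant ids to exclude from
#'   hit calling (e.g. substitutions independently predicted to destabilize
#'   the protein fold); they retain scores but are never flagged.
#' @return data.frame of class `score_table` with columns `variant_id`,
#'   `codon_number`, `alt_aa`, `var_class`, `t0_fraction`, `low_confidence`,
#'   `lfc_dnmdp100_vs_dmso`, `lfc_dnmdp100_vs_treq`, `z`, `resistance_hit`.
#' @export
score_screen <- function(counts, sheet, design, params = scoring_params(),
                         exclusion = character(0)) {
  stopifnot(all(sheet$sample_id %in% colnames(counts)))
  fr <- compute_fractions(counts, params$pseudocount)
  vids <- design$variants$variant_id
  fr <- fr[intersect(rownames(fr), vids), , drop = FALSE]
  t0_samples <- sheet$sample_id[sheet$condition == "T0"]
  t0_fraction <- rowMeans(fr[, t0_samples, drop = FALSE])
  low <- filter_low_t0(t0_fraction, params$t0_percentile)
  keep <- !low
  lfc_dmso <- rep(NA_real_, nrow(fr))
  lfc_treq <- rep(NA_real_, nrow(fr))
  z <- rep(NA_real_, nrow(fr))
  hit <- rep(NA, nrow(fr))
  if (sum(keep) >= 2L) {
    frk <- fr[keep, , drop = FALSE]
    lfc_dmso[keep] <- survival_lfc(frk, sheet, "DNMDP100", "DMSO", params)
    if (any(sheet$condition == "TREQ100")) {
      lfc_treq[keep] <- survival_lfc(frk, sheet, "DNMDP100", "TREQ100", params)
    }
    primary <- if (params$control_condition == "DMSO") lfc_dmso else lfc_treq
    if (sd(primary[keep]) > 0) z[keep] <- z_scores(primary[keep])
    hit[keep] <- call_hits(primary[keep], params$hit_sd_multiplier)
    hit[keep & rownames(fr) %in% exclusion] <- FALSE
  }
  idx <- match(rownames(fr), vids)
  out <- data.frame(
    variant_id = rownames(fr),
    codon_number = design$variants$codon_number[idx],
    alt_aa = design$variants$alt_aa[idx],
    var_class = design$variants$var_class[idx],
    t0_fraction = t0_fraction,
    low_confidence = low,
    lfc_dnmdp100_vs_dmso = lfc_dmso,
    lfc_dnmdp100_vs_treq = lfc_treq,
    z = z,
    resistance_hit = hit,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Write a score table as TSV
#'
#' @param scores a `score_table` from [score_screen()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
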