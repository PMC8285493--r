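REGION_CATEGORIES <- c("active_site", "dimer_interface", "slfn12_interface")

#' Named residue sets for structural classification of hits
#'
#' @param active_site,dimer_interface,slfn12_interface integer vectors of
#'   residue numbers (sets may overlap; classification priority is
#'   active site > dimer interface > SLFN12 interface).
#' @param excluded_fold_set residues whose substitutions are believed to act
#'   by destabilizing the protein fold; removed before classification.
#' @return list of class `region_definition`.
#' @export
region_definition <- function(active_site = integer(0),
                              dimer_interface = integer(0),
                              slfn12_interface = integer(0),
                              excluded_fold_set = integer(0)) {
  structure(list(active_site = as.integer(active_site),
                 dimer_interface = as.integer(dimer_interface),
                 slfn12_interface = as.integer(slfn12_interface),
                 excluded_fold_set = as.integer(excluded_fold_set)),
            class = "region_definition")
}

#' @rdname region_definition
#' @param path YAML file with keys `active_site`, `dimer_interface`,
#'   `slfn12_interface` and optionally `excluded_fold_set`, each a list of
#'   residue numbers.
#' @export
read_region_definition <- function(path) {
  y <- yaml::read_yaml(path)
  region_definition(
    active_site = unlist(y$active_site),
    dimer_interface = unlist(y$dimer_interface),
    slfn12_interface = unlist(y$slfn12_interface),
    excluded_fold_set = if (is.null(y$excluded_fold_set)) integer(0) else
      unlist(y$excluded_fold_set))
}

#' Classify resistance-hit residues into structural categories
#'
#' Hit variants are aggregated by residue (any flagged variant at a codon
#' makes that residue a hit residue); residues in the excluded fold set are
#' removed, and each remaining residue receives the first matching category
#' in priority order active site > dimer interface > SLFN12 interface, or
#' `unassigned`.
#'
#' @param scores a `score_table` from [score_screen()] (or any data.frame
#'   with `variant_id`, `codon_number`, `resistance_hit`).
#' @param regions a [region_definition()].
#' @return data.frame `annotated_hits`: one row per hit residue with columns
#'   `residue`, `category`, `variant_ids` (comma-separated supporting
#'   variants).
#' @export
classify_hits <- function(scores, regions) {
  stopifnot(inherits(regions, "region_definition"))
  hits <- scores[!is.na(scores$resistance_hit) & scores$resistance_hit, , drop = FALSE]
  hits <- hits[!(hits$codon_number %in% regions$excluded_fold_set), , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(residue = integer(0), category = character(0),
                      variant_ids = character(0), stringsAsFactors = FALSE))
  }
  residues <- sort(unique(hits$codon_number))
  category <- vapply(residues, function(r) {
    if (r %in% regions$active_site) "active_site"
    else if (r %in% regions$dimer_interface) "dimer_interface"
    else if (r %in% regions$slfn12_interface) "slfn12_interface"
    else "unassigned"
  }, character(1))
  variant_ids <- vapply(residues, function(r) {
    paste(sort(hits$variant_id[hits$codon_number == r]), collapse = ",")
  }, character(1))
  data.frame(residue = residues, category = category,
             variant_ids = variant_ids, stringsAsFactors = FALSE)
}

# heavy atoms of a bio3d atom table, optionally restricted to chains/resid
atom_subset <- function(atoms, chains = NULL, resid = NULL, hetatm = NA) {
  keep <- !(atoms$elesy %in% c("H", "D"))
  if (!is.null(chains)) keep <- keep & atoms$chain %in% chains
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.na(hetatm)) {
    keep <- keep & (atoms$type == if (hetatm) "HETATM" else "ATOM")
  }
  atoms[keep, , drop = FALSE]
}

# residue numbers of `rec` atoms with any heavy atom within `cutoff` of any
# atom in `other` (vectorized squared-distance scan, chunked by residue)
residues_within <- function(rec, other, cutoff) {
  if (nrow(rec) == 0L || nrow(other) == 0L) return(integer(0))
  rx <- as.matrix(rec[, c("x", "y", "z")])
  ox <- as.matrix(other[, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rep(1, nrow(ox))) +
    outer(rep(1, nrow(rx)), rowSums(ox^2)) - 2 * rx %*% t(ox)
  near <- rowSums(d2 <= cutoff^2 + 1e-9) > 0L
  sort(unique(rec$resno[near]))
}

#' Derive structural region sets from a coordinate file
#'
#' Reads a PDB/mmCIF structure and derives, by heavy-atom distance cutoff:
#' the active site (receptor residues contacting the ligand), the homodimer
#' interface (receptor residues contacting the other receptor chain; the
#' union over receptor chains, so the definition is symmetric), and the
#' partner-binding site (receptor residues contacting any partner chain).
#'
#' @param path PDB or mmCIF file.
#' @param ligand ligand residue name (3-letter HET code), e.g. the bound
#'   compound; `NULL` to skip the active-site set.
#' @param receptor_chains chain identifiers of the receptor (e.g.
#'   `c("A", "B")` for a homodimer).
#' @param partner_chains chain identifiers of the bound partner protein
#'   (`NULL` to skip the partner-interface set).
#' @param cutoff heavy-atom distance cutoff in Angstroms (default 4.5).
#' @return A [region_definition()].
#' @export
derive_regions <- function(path, ligand = NULL, receptor_chains,
                           partner_chains = NULL, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  rec <- atom_subset(atoms, chains = receptor_chains, hetatm = FALSE)
  if (nrow(rec) == 0L) stop("no receptor atoms for chain(s) ",
                            paste(receptor_chains, collapse = ","))
  active <- integer(0)
  if (!is.null(ligand)) {
    lig <- atom_subset(atoms, resid = ligand)
    if (nrow(lig) == 0L) stop("ligand '", ligand, "' not found in structure")
    active <- residues_within(rec, lig, cutoff)
  }
  dimer <- integer(0)
  if (length(receptor_chains) >= 2L) {
    for (ch in receptor_chains) {
      self <- atom_subset(atoms, chains = ch, hetatm = FALSE)
      mates <- atom_subset(atoms, chains = setdiff(receptor_chains, ch),
                           hetatm = FALSE)
      dimer <- union(dimer, residues_within(self, mates, cutoff))
    }
    dimer <- sort(dimer)
  }
  partner <- integer(0)
  if (!is.null(partner_chains)) {
    part <- atom_subset(atoms, chains = partner_chains)
    if (nrow(part) == 0L) stop("no atoms for partner chain(s) ",
                               paste(partner_chains, collapse = ","))
    partner <- residues_within(rec, part, cutoff)
  }
  region_definition(active_site = active, dimer_interface = dimer,
                    slfn12_interface = partner)
}

#' Write annotated hits as TSV
#'
#' @param annotated data.frame from [classify_hits()].
#' @param path output path.
#' @export
write_annotated_hits <- function(annotated, path) {
  write.table(annotated, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
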