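test_that("unconstrained saturation design makes exactly 20 substitutions per codon", {
  orf <- toy_orf(c("ATG", "TTT", "GGA", "CAT", "AAA"))
  d <- design_saturation_library(
    orf, design_constraints(1, 5, forbidden_sites = list(), silent_count = 0))
  expect_equal(nrow(d$variants), 100L)
  expect_equal(nrow(d$dropped), 0L)
  per_codon <- table(d$variants$codon_number)
  expect_true(all(per_codon == 20L))
  cls <- table(d$variants$var_class)
  expect_equal(unname(cls[["missense"]]), 95L)
  expect_equal(unname(cls[["nonsense"]]), 5L)
  # one variant per (codon, target aa), wt amino acid never a target
  expect_false(any(duplicated(paste(d$variants$codon_number, d$variants$alt_aa))))
  expect_false(any(d$variants$wt_aa == d$variants$alt_aa))
})

test_that("candidate codons are ranked by descending distance from the template", {
  # wt TTT (Phe) -> Leu candidates: CTC/CTA/CTG at distance 2, TTA/TTG/CTT at 1;
  # CTG wins the distance tie on usage
  r <- rank_codons("TTT", "L")
  expect_equal(r[1], "CTG")
  d <- vapply(r, function(c) sum(strsplit(c, "")[[1]] != c("T", "T", "T")), 1L)
  expect_true(all(diff(d) <= 0))
  # with no constraints every chosen codon attains the maximum distance
  orf <- toy_orf(c("TTT", "ATG", "CAA", "GGC"))
  des <- design_saturation_library(
    orf, design_constraints(1, 4, forbidden_sites = list()))
  for (i in seq_len(nrow(des$variants))) {
    v <- des$variants[i, ]
    cands <- rank_codons(v$wt_codon, v$alt_aa)
    dmax <- max(vapply(cands, function(c)
      sum(strsplit(c, "")[[1]] != strsplit(v$wt_codon, "")[[1]]), 1L))
    expect_equal(v$nt_distance, dmax)
  }
})

test_that("forbidden-site constraints reject candidates exactly as brute force does", {
  # GC|xxx|GC context: several candidate codons complete GCTAGC (NheI)
  orf <- toy_orf(c("ATG", "AGC", "TTT", "GCA", "AAA", "TGC", "CAT"))
  nhe <- restriction_site("NheI", "GCTAGC")
  d <- design_saturation_library(
    orf, design_constraints(1, 7, forbidden_sites = list(nhe)))
  # oracle: first-ranked candidate whose full mutated sequence is site-free
  ref <- orf$nucleotides
  for (cn in 1:7) {
    wt_codon <- orf_codons(orf)[[as.character(cn)]]
    wt_aa <- dmscreen:::CODON_TABLE[[wt_codon]]
    for (aa in setdiff(c(dmscreen:::AA_STANDARD, "*"), wt_aa)) {
      expected <- NA_character_
      for (cand in rank_codons(wt_codon, aa)) {
        nt <- 3L * (cn - 1L) + 1L
        mut <- paste0(substr(ref, 1, nt - 1), cand, substr(ref, nt + 3, nchar(ref)))
        if (length(naive_site_scan(mut, "GCTAGC")) == 0L) { expected <- cand; break }
      }
      got <- d$variants$alt_codon[d$variants$codon_number == cn &
                                  d$variants$alt_aa == aa]
      if (is.na(expected)) {
        expect_length(got, 0L)
        expect_true(any(d$dropped$codon_number == cn & d$dropped$alt_aa == aa))
      } else {
        expect_equal(got, expected)
      }
    }
  }
  # every emitted variant sequence is site-free end to end
  for (s in variant_sequences(d)) {
    expect_length(find_restriction_sites(s, nhe), 0L)
  }
})

test_that("every variant sequence differs from the reference in exactly one codon", {
  orf <- synthetic_orf(30, seed = 13)
  d <- design_saturation_library(
    orf, design_constraints(5, 25, silent_count = 4))
  seqs <- variant_sequences(d)
  ref_cod <- orf_codons(orf)
  for (i in seq_along(seqs)) {
    v <- d$variants[i, ]
    cod <- substring(seqs[[v$variant_id]], seq(1, nchar(orf$nucleotides), 3),
                     seq(3, nchar(orf$nucleotides), 3))
    diff <- which(cod != ref_cod)
    expect_length(diff, 1L)
    expect_equal(unname(diff), v$codon_number - orf$codon_offset + 1L)
    expect_equal(cod[diff], v$alt_codon)
  }
})

test_that("silent controls are synonymous, evenly spread, and skip Met/Trp positions", {
  # Met/Trp codons interleaved: silent placement must walk past them
  orf <- toy_orf(rep(c("ATG", "CTG", "TGG", "AAA"), 10))
  d <- design_saturation_library(
    orf, design_constraints(1, 40, forbidden_sites = list(), silent_count = 12))
  sil <- d$variants[d$variants$var_class == "silent", ]
  expect_equal(nrow(sil), 12L)
  expect_true(all(sil$wt_aa == sil$alt_aa))
  expect_true(all(sil$wt_aa != "*"))
  expect_false(any(sil$wt_aa %in% c("M", "W")))
  expect_false(any(duplicated(sil$codon_number)))
  expect_true(all(sil$alt_codon != sil$wt_codon))
  # translation unchanged by each silent edit
  for (s in variant_sequences(d, sil$variant_id)) {
    expect_equal(translate_dna(s), translate_orf(orf))
  }
  expect_error(
    design_saturation_library(
      orf, design_constraints(1, 40, forbidden_sites = list(),
                              silent_count = 25)),
    "exceeds")
})

test_that("the design is a pure function of its inputs", {
  orf <- synthetic_orf(60, seed = 21)
  c1 <- design_constraints(10, 50, silent_count = 10)
  expect_identical(design_saturation_library(orf, c1),
                   design_saturation_library(orf, c1))
})

test_that("library tables round-trip through TSV and FASTA", {
  orf <- synthetic_orf(25, seed = 3)
  d <- design_saturation_library(
    orf, design_constraints(1, 25, silent_count = 3))
  prefix <- tempfile()
  write_library(d, prefix)
  tab <- read.delim(paste0(prefix, ".tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tab), nrow(d$variants))
  back <- read_library(paste0(prefix, ".tsv"), orf)
  expect_equal(back$variants, d$variants)
  fa <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  expect_equal(length(fa), nrow(d$variants))
  expect_equal(names(fa), d$variants$variant_id)
  expect_equal(as.character(fa[[1]]), unname(variant_sequences(d)[1]))
  # empty design: header-only table, empty FASTA
  d0 <- d; d0$variants <- d$variants[0, ]
  prefix0 <- tempfile()
  write_library(d0, prefix0)
  expect_equal(nrow(read.delim(paste0(prefix0, ".tsv"))), 0L)
  expect_length(Biostrings::readDNAStringSet(paste0(prefix0, ".fasta")), 0L)
})

test_that("PAM recoding removes guide matches with minimal synonymous edits", {
  guide <- "GTGGCAGACCATATTTCCCAA"
  set.seed(9)
  orf0 <- synthetic_orf(40, seed = 9)
  s <- orf0$nucleotides
  emb <- paste0(substr(s, 1, 30), guide, "AGG", substr(s, 55, nchar(s)))
  orf <- orf_sequence(emb, id = "embedded", check_internal_stop = FALSE)
  expect_gte(nrow(find_guide_matches(orf$nucleotides, guide)), 1L)
  rec <- recode_pam_sites(orf, guide)
  expect_equal(nrow(rec$edits), 1L)
  expect_equal(nrow(find_guide_matches(rec$orf$nucleotides, guide)), 0L)
  expect_equal(translate_orf(rec$orf), translate_orf(orf))

  # no matches: identity
  clean <- synthetic_orf(40, seed = 15)
  expect_equal(nrow(find_guide_matches(clean$nucleotides, guide)), 0L)
  rec2 <- recode_pam_sites(clean, guide)
  expect_equal(nrow(rec2$edits), 0L)
  expect_equal(rec2$orf$nucleotides, clean$nucleotides)

  # footprint of Met/Trp codons only: no synonymous move exists
  stuck <- orf_sequence(paste(rep(c("ATG", "TGG"), 4), collapse = ""),
                        id = "stuck")
  expect_error(recode_pam_sites(stuck, "ATGTGGATGTGGATG"),
               "no synonymous codon")
})

test_that("design configuration files round-trip through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("region_start: 3", "region_end: 12", "silent_count: 4",
               "guide: GTGGCAGACCATATTTCCCAA",
               "forbidden_sites:",
               "  - name: NheI", "    recognition: GCTAGC"), cfg)
  got <- read_design_config(cfg)
  expect_equal(got$constraints$region_start, 3L)
  expect_equal(got$constraints$region_end, 12L)
  expect_equal(got$constraints$silent_count, 4L)
  expect_equal(got$guide, "GTGGCAGACCATATTTCCCAA")
  expect_equal(got$constraints$forbidden_sites[[1]]$recognition, "GCTAGC")
})
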