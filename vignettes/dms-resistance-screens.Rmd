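---
title: "Designing and scoring codon-saturation resistance screens with dmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring codon-saturation resistance screens with dmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

## The experiment this package models

Deep mutational scanning (DMS) of a drug-response gene asks, for every
possible amino-acid substitution in a region of interest, whether cells
carrying that variant survive drug treatment. The motivating application is
a screen of the PDE3A catalytic domain for mutations conferring resistance to
DNMDP, a "velcrin" compound that kills cells by gluing PDE3A to SLFN12.
Because the drug's toxicity requires a *functional* PDE3A surface, variants
that break the drug-induced complex — at the catalytic pocket, at the
PDE3A homodimer interface, or at the SLFN12-binding surface — survive
treatment and enrich in the pool, as do simple loss-of-function variants
such as premature stop codons. Stops near the C terminus are the
instructive exception: a protein truncated only in its final tail is still
functional, so nonsense variants in the last 59 codons behave like wild
type and die.

The package implements the full dry-lab side of such a screen as five
cooperating stages:

1. **Library design** (`design_saturation_library`): at every codon of the
   region, one codon for each of the 19 non-wild-type amino acids plus one
   stop, under restriction-site constraints, plus evenly spaced silent
   controls.
2. **Rescue-construct recoding** (`recode_pam_sites`): synonymous removal of
   CRISPR guide/PAM matches so the screening cDNA resists the knockout
   guide.
3. **Read deconvolution** (`merge_read_pair`, `call_read`, `tally_counts`):
   paired amplicon reads to a variant-by-sample counts matrix.
4. **Survival scoring** (`score_screen`): T0-normalized log2 fold changes,
   z-scores and SD-threshold hit calls.
5. **Structural annotation** (`classify_hits`, `derive_regions`): hit
   residues to active-site / dimer-interface / partner-interface categories.

A synthetic-screen generator (`simulate_screen` and friends) provides
ground truth for every stage.

## The scoring model

Let $c_{vs}$ be the read count of variant $v$ in sample $s$ and let the
*assigned* total of a sample be the sum over designed variants and the
wild-type carrier (discarded read classes are not part of the denominator,
so junk rates that differ between samples do not bias fractions). With
pseudocount $\epsilon$,

$$f_{vs} = \frac{c_{vs} + \epsilon}{\sum_{v'} c_{v's} + \epsilon}.$$

Variants whose mean T0 fraction falls at or below the nearest-rank 8th
percentile are *low confidence* and take no further part in the analysis
(the nearest-rank rule makes the count exact: with distinct values over
$n$ variants, exactly $\lceil 0.08\,n\rceil$ are flagged; ties at the
threshold are all flagged, which errs toward exclusion).

For a day-5 arm, each replicate's fraction is normalized to the pooled-T0
fraction (T0 is harvested once, before the split into arms; a
replicate-matched mode is available), replicate means are taken, and

$$\mathrm{LFC}_v = \log_2
  \frac{\overline{f_{v,\mathrm{treat}}/f_{v,T0}}}
       {\overline{f_{v,\mathrm{ctrl}}/f_{v,T0}}},$$

with DMSO as the default control and the inactive PDE3A inhibitor
trequinsin as the alternative. Z-scores standardize the drug-versus-DMSO
LFC over retained variants with the sample SD, and a variant is a
**resistance hit** when its LFC exceeds the mean by more than one SD *and*
is positive. Both clauses matter: in a screen where most of the library
dies, the LFC distribution is centered well below zero and the SD clause
alone would flag variants that merely die more slowly.

Fold-destabilizing substitutions are *not* predicted by this package;
`score_screen` accepts a user-supplied exclusion list instead, because any
in-house stability predictor would be a second, unvalidated model layered
on the first.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `t0_percentile` | 8 | representation floor below which fractions are sampling noise |
| `pseudocount` | 0.5 reads | post-selection zeros are expected for dying variants; keeps logs finite |
| `hit_sd_multiplier` | 1 | SD threshold used for the published hit class |
| forbidden sites | NheI, BamHI | the fragment-library cloning enzymes; any variant creating one is uncloneable |
| codon ranking | max Hamming distance, then codon usage, then alphabetical | maximizing nucleotide distance from the template keeps single sequencing errors from mimicking designed variants; the usage/alphabetical tie-break is arbitrary but fixed, so the design is a pure function of its inputs |
| `max_mismatch` | 6 | tolerates a 3-nt codon swap plus sparse sequencing errors |
| seed k-mer | 20 nt | anchors 120–300 nt consensus reads uniquely in a ≤ 3.5 kb amplicon |
| contact cutoff | 4.5 Å | standard heavy-atom contact definition |

Silent controls are placed at evenly spaced codons (the region description
gives no finer placement rule); positions whose codon has no synonymous
alternative (Met, Trp) are skipped in favor of the next position.

## What the simulator emulates — and what it does not

`simulate_screen` draws library representation as i.i.d. log-normal
(sigma 1) abundances with a 5% dropout fraction crushed to near zero
(to exercise the representation filter), gives the wild-type carrier a 1%
share, applies one deterministic proportional-growth step per arm — weight
1 for loss-of-function variants under DNMDP, a residual survival weight
`delta = 0.05` for functional variants (killing is strong but not
absolute), weight 1 for everything under T0/DMSO/trequinsin — and draws one
multinomial count vector per sample. Ground-truth loss of function is
"nonsense at codon ≤ last codon − 59, or membership in the programmed
resistance set"; the default programmed set is every missense variant at
five exemplar residues spanning the three structural categories (867 at the
dimer interface, 914 at the SLFN12 surface, 961/1001/1004 in the active
site). `simulate_reads` additionally emits paired reads from random
fragments of each variant's full sequence — always covering the mutated
codon, so an error-free simulation round-trips exactly through the tally —
with uniform substitution errors.

Deliberately not modeled: PCR jackpotting and chimeras, coverage bias,
growth stochasticity (selection is one deterministic step), indel
sequencing errors, and reads that miss the mutated codon. Passing the
end-to-end recovery test therefore demonstrates that the scoring
machinery is correct under clean sampling noise, not that a real screen of
equal depth would achieve the same sensitivity; real data add the failure
modes listed above, and the deconvolution stage here is an explicitly
simplified stand-in for the unpublished original tool (ungapped alignment,
exact k-mer seeding, documented filter rules).

At study scale (a 1141-codon ORF, 474-codon region, 9,668 designed
variants, depth $10^6$ reads per sample, two replicates, five arms) the
counts-level simulation and full scoring run in seconds, which is what the
test suite and the acceptance script use. Read-level simulations are run at
hundreds-to-thousands of reads because the pure-R caller processes roughly
a thousand reads per second; that is ample to verify exact round-trips.

With those settings the end-to-end recovery is characteristic: essentially
every *assessable* programmed resistance variant is called (sensitivity
among retained variants ≈ 1, false-discovery proportion ≲ 0.01), while
overall sensitivity sits near 0.92 because the 8% representation filter
excludes variants blindly with respect to their fitness — exactly as the
real screen excluded low-representation variants before hit calling. The
nonsense hit/non-hit boundary lands exactly at codon 1082 (1141 − 59).

## Numerical and degenerate-input choices

* Nucleotide coordinates are 0-based half-open internally; codon numbers
  are 1-based and equal protein residue numbers in all user-facing output
  (an ORF can start at any codon offset, e.g. 668).
* Restriction-site checking during candidate ranking uses the local window
  codon ± (site length − 1) nt — a single codon edit can only create sites
  overlapping it — and the emitted library is additionally checked
  full-length in the tests. The reference itself must be free of forbidden
  sites, otherwise no variant could satisfy the constraint and the design
  aborts with an error.
* IUPAC degeneracy is honored in site patterns but not in input sequences
  (inputs are resolved cDNAs).
* Protein masses are isotope-averaged residue masses plus one water, the
  "theoretical mass" convention used alongside SEC-MALS solution masses.
* Mate merging accepts the overlap offset with the most agreeing bases,
  requiring ≥ 90% agreement and ≥ 20 nt; overlap disagreements resolve to
  the higher-quality base; a pair with no eligible overlap, or a consensus
  whose mean quality is below Q20, is `LOW_QUALITY`.
* Reads covering only unmutated codons count as wild type with no
  positional down-weighting — the simplest defensible rule; a fraction
  denominator restricted to reads overlapping each codon would be the
  refinement if this mattered in practice.
* `z_scores` refuses a zero-SD vector; `score_screen` degrades gracefully
  (NA z, no hits) for degenerate screens where all retained LFCs are equal.
* Hit-category overlaps resolve by priority active site > dimer interface >
  partner interface: active-site membership is the most specific mechanistic
  claim about a resistance mutation.
* All randomness flows through R's generator, seeded once per simulation;
  every artifact is byte-reproducible from (config, seed).

## Worked example

```{r example, eval = FALSE}
orf <- synthetic_orf(1141, seed = 2026, id = "synthetic_full_orf")
design <- design_saturation_library(
  orf, design_constraints(668, 1141, silent_count = 188))
design

fit <- fitness_model(design, example_resistance_set(design))
sim <- simulate_screen(design, fit, screen_sim_config(depth = 1e6, seed = 99))
scores <- score_screen(sim$counts, sim$sheet, design)
table(hit = scores$resistance_hit, lof = fit$lof[scores$variant_id],
      useNA = "ifany")

regions <- region_definition(active_site = c(961, 968, 1001, 1004),
                             dimer_interface = 867,
                             slfn12_interface = 914)
head(classify_hits(scores, regions))
```

## Known limitations

* The seven-variant shortfall of the published library (9,668 designed −
  7 infeasible = 9,661) is not reproducible without the authors' exact cDNA
  and tie-break policy; the package reproduces the arithmetic and produces
  dropped records whenever constraints genuinely bind.
* The published theoretical construct masses (57.3 kDa, 67.3 kDa) can only
  be recomputed from the deposited construct sequences, which ship as
  supplementary data outside this package; `average_protein_mass` is
  validated against an independent oracle instead.
* The deconvolution stage is a simplified, documented re-implementation of
  an unpublished tool; absolute counts from real FASTQs will differ in the
  discard classes even if designed-variant calls agree.
* Whether the original bottom-8% filter pooled T0 replicates, and how
  fold-destabilizing hits were predicted, are not stated in the source
  material; the package takes the pooled-percentile reading and a
  user-supplied exclusion list, respectively.
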