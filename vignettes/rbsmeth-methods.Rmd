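---
title: "Calling m5C in tRNAs and rRNAs from RNA bisulfite sequencing"
author: "rbsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m5C in tRNAs and rRNAs from RNA bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbsmeth)
```

## The measurement model

Sodium bisulfite deaminates unmethylated cytosine to uracil, which is read
as T after cDNA synthesis; 5-methylcytosine (m5C) resists deamination and is
still read as C. Deep-sequencing a bisulfite-converted RNA library and
aligning the reads against references in which every C has been replaced by
T ("three-letter" or C/T-collapsed space) therefore turns methylation
detection into counting: at each original cytosine position of a reference,
the methylation level is estimated as

$$\hat{m} = \frac{n_C}{n_C + n_T}$$

where `n_C` and `n_T` are the mapped cytosines and thymines at that
position. Bases other than C or T at such positions (sequencing errors) are
tallied but excluded from the denominator. Because conversion is imperfect,
the expected *observed* methylation at a site with true methylation $m$ is

$$E[\hat m] = m\,(1 - o) + (1 - m)\,(1 - e)$$

with $e$ the conversion efficiency (probability an unmethylated C reads as
T) and $o$ the over-conversion rate (probability a methylated C reads as
T). `expected_observed_methylation()` implements this closed form, and the
simulator's output converges to it — this is one of the package's core
validation properties.

Two hard thresholds turn estimates into calls, applied inclusively
(≥): a site needs at least **5 reads** of C+T coverage (below which it is
`no_call`, rendered blank/white in heatmaps) and at least **20 %**
methylation to be called methylated. Called sites are *candidate* m5C
sites: other cytosine modifications can also resist bisulfite conversion,
and sequencing alone cannot distinguish them.

## Conversion-efficiency QC on a spike-in

Every bisulfite library carries an in vitro transcribed, methylation-free
spike-in control. Because none of its cytosines are methylated, any C read
at a control position is a conversion failure. The QC statistic is the
aggregate conversion rate over all covered control cytosines,
$\sum n_T / \sum (n_C + n_T)$, and a library passes only at ≥ 98 %. We read
the threshold as an aggregate rate rather than a per-cytosine minimum: at
realistic per-site depths a per-cytosine 98 % requirement would fail on
sampling noise alone. Per-cytosine rates are still reported for inspection.
Libraries failing QC are halted before site calling (`call_sites()` refuses
a failing `conversion_qc`), because a global conversion deficit inflates
every site estimate by roughly $1 - e$.

## Reference construction

Plant genomes encode several hundred tRNA genes across nucleus, chloroplast
and mitochondrion, many of them identical or nearly so. Aligning short
reads against all of them individually produces unresolvable multimapping,
so genes are collapsed per (amino acid, anticodon) group by single-linkage
clustering at ≥ 95 % global identity; each cluster becomes one consensus
(per-position majority base, IUPAC codes on ties). The identity threshold
is a package decision: it keeps truly diverged minority isodecoders — named
`<aa>-<anticodon>-1`, `-2`, … in decreasing cluster-size order — as separate
references while absorbing allelic and near-identical copies. A consensus
carries the union of its members' genomes of origin, so a sequence present
in two genomes is represented once with an ambiguous origin rather than
twice. Consensus references exclude introns and any 3' CCA not present in
the annotated mature sequence; coordinates are 1-based on the sense strand
and references are stored as DNA (T, not U). N bases never count as
cytosines.

For species without a deposited rRNA sequence, `derive_species_rrna()`
aligns non-bisulfite RNA-seq reads to the corresponding anchor rRNA and
replaces each position covered at ≥ `min_depth` by the majority read base,
recovering species-specific SNPs; positions below the depth floor keep the
anchor base and are flagged.

## Alignment

`align_reads()` C→T collapses each read (the reference set is already
converted) and scans it ungapped over every offset of every reference,
returning the minimal-mismatch alignment(s) up to `max_mismatch`
(default 2). Ties across references return all cochampions flagged
ambiguous; ties within a reference keep the leftmost offset; cochampions
are ordered by reference id so results never depend on input order. The
scan is implemented in compiled code and is exhaustive rather than
heuristic: at tRNA/rRNA reference scale an exact scan is fast, and
exactness lets a brute-force pure-R scorer serve as a genuinely independent
oracle in the tests (the two must agree perfectly, including ambiguity
sets). Ungapped alignment is a deliberate restriction — the analysis is
substitution-based and the references are short structural RNAs — so
indel-containing reads count as unalignable. Only read-side C→T equivalence
is honoured (stranded, sense-strand libraries); a read C over a reference
non-C position is a mismatch.

Multimapped reads contribute fractionally, `1/|cochampions|`, to each
cochampion's pileup. This preserves total counts and reflects that
ambiguous-origin tRNAs cannot be attributed to a single genome; the
alternative (discarding multimappers) would silently delete exactly the
shared isodecoders the consensus construction is designed to keep.

## Structural coordinates

Sites in tRNAs of different lengths are compared on the canonical
72-position cloverleaf (acceptor stem 1–7/66–72, anticodon 34–36, variable
region after 45, T-arm 49–65). `assign_trna_structure()` anchors the
anticodon at 34–36 and assigns the remaining labels by a deterministic
length-based template: upstream bases count back from 33, the 24
acceptor-proximal downstream bases take 49–72, the bases immediately after
the anticodon take 37 upward, and any overflow between those blocks (a long
variable loop) is unmapped; short arms skip labels. We deliberately do not
score letter similarity against any single scaffold sequence: tRNA bodies
diverge freely, so a sequence-scored global alignment would make the
numbering depend on alignment noise, whereas the length-anchored rule is
deterministic, satisfies label monotonicity, and reproduces the expected
mapping for canonical-architecture molecules exactly. Sprinzl-style
insertion labels (e.g. 47a) are collapsed into "unmapped" rather than
sub-numbered. When the anticodon string occurs more than once, the
occurrence that best fits the canonical layout wins and an exact tie is an
error, never a silent choice.

rRNA sites are numbered on the corresponding anchor (Arabidopsis) sequence:
`lift_rrna_position()` globally aligns species to anchor (match +1,
mismatch −1, gap open −5, extend −1, via Biostrings), maps match/mismatch
columns, flags gap columns unmappable, and warns when alignment identity
falls below 50 % (wrong subunit).

## Conservation classes

For each structural position methylated in at least one species,
`build_conservation_table()` records per species the base state (C, a SNP
base, absent, or ambiguous) and the methylation call, then classifies:
**class 1** — methylated in every classifiable species; **class 2** —
methylated in all but one, which carries a SNP at the position; **class 3**
— methylated in ≥ 1 species while ≥ 1 other species has an unmethylated
cytosine there. "Methylated" uses the same 20 % calling threshold — no
separate conservation threshold is introduced. Species without confident
coverage are *excluded* from the decision rather than counted unmethylated
(a depth artifact must not demote a class), and a site classifiable in
fewer than three species is `unclassified`. An ambiguous base (C-or-T)
likewise excludes its species. Colour bins for plotting follow the
0–40 % (low) / 80–100 % (high) scheme with a linear gradient between.

## In-silico methyl-chop PCR

`assay_report()` predicts the orthogonal wet-lab validation: bisulfite
conversion of the template under both methylation states of the assayed
cytosine, PCR amplicon extraction with primer-base incorporation, and
restriction digestion. PCR is modeled as deterministic single-amplicon
extraction — the assay is qualitative (cut vs uncut), so no
efficiency or mispriming model is warranted. Primers may carry up to two
mismatches but none in the 3'-terminal two bases; deliberate dCAPS
mismatches are overwritten into the product, which is how a primer G placed
four bases from the 3' end can complete a HinfI site (G^ANTC) whose fifth
base is the assayed cytosine — present only when methylation protected it
from conversion. Recognition sites are matched as IUPAC patterns on both
strands of the product (conversion asymmetry is preserved by converting
only the sense-strand template before amplification). On the bundled
synthetic tRNA-Asp(GTC), HpyCH4IV (A^CGT over C38) cuts the 72 bp product
into 35 + 37 bp only when C38 is methylated; on the bundled synthetic 25S
molecule, HinfI cuts the 155 bp dCAPS product into 29 + 126 bp only when
C2268 is methylated. The bundled sequences are constructed to this
architecture and labelled synthetic; they are not database sequences.

## The simulator and what it does (not) show

`simulate_bisulfite_reads()` emulates a stranded, single-end,
size-selected library: read lengths uniform in 65–95 nt (full-length when
the reference is shorter, as all tRNAs are), uniform start positions,
per-site methylation fractions, conversion efficiency (default 0.99, above
the 0.98 QC gate), over-conversion (default 0.01 — no empirical rate is
available for this, it is a free parameter), per-base substitution error
(default 0.001), constant quality strings (the pipeline ignores base
quality), and a configurable spike-in fraction. Identical seed and
configuration give byte-identical output. `calibrate_spikein()`
rejection-samples generator seeds to produce a control with an exact
cytosine inventory (default 178 cytosines at 1068 nt).

The simulator deliberately omits PCR duplicates, adapters, indels,
paired-end structure, coverage biases from structured RNA, and bisulfite
degradation. Green tests therefore demonstrate that the *computational*
chain — conversion model, three-letter alignment, fractional pileups,
thresholds, QC gate, structural mapping, classification — is correct under
its stated model; they do not certify behaviour on real libraries with
secondary-structure-driven non-conversion (a known source of clustered
false positives) or alignment artifacts from RNA edits.

## Problem sizes and numerical choices

The bundled validation runs at desk scale, chosen so the statistical checks
are sharp while the suite stays quick: parameter recovery uses 1,000 sites
(50 references × 20 cytosines) at ≈ 100× depth, where the binomial standard
error of a site estimate is at most 0.05 and the mean absolute error lands
near 0.025; QC gating and the closed-form limit use 10⁴ reads, making the
conversion-rate standard error ≪ the 95 %/99 % separation; the aligner
oracle uses 50 references × 500 reads with an exact-equality contract; and
the invariants (conversion round-trip, digest fragment sums) run on 10⁴
random inputs. Degenerate inputs fail loudly rather than silently: empty
reference sets, methylation positions that are not cytosines, spike-in
controls without cytosines, primers annealing at zero or multiple sites,
and anticodon placement ties are all errors. A zero C+T denominator yields
an undefined (NA) methylation value, never 0. The 20 % and coverage
thresholds are applied with ≥ at the boundary.

## Known limitations

- Hard thresholds, no per-site statistical test: the calling rule is
  reproduced as specified; a binomial test against the (1 − e) null could
  be layered on the pileups but is not part of the calling path.
- Ungapped alignment discards indel-containing reads.
- The three-class conservation scheme requires a lifted coordinate for
  every species; positions unmappable to the anchor are reported but cannot
  be classified.
- m5C cannot be distinguished from other bisulfite-resistant cytosine
  modifications by this assay at all — calls are candidates by design.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
asp <- synthetic_asp_trna()
cfg <- run_config(
  references = data.frame(id = asp$consensus_id, sequence = asp$sequence,
                          category = "tRNA"),
  samples = data.frame(sample_id = c("wt_1", "mut_1"),
                       genotype = c("wt", "mutant"),
                       library = "BS", n_reads = 3000),
  methylation_maps = list(
    wt = data.frame(id = asp$consensus_id, position = c(38, 48),
                    fraction = c(0.66, 0.90)),
    mutant = data.frame(id = asp$consensus_id, position = c(38, 48),
                        fraction = c(0.02, 0.55))),
  out_dir = tempfile("run_"), seed = 101)
res <- run_pipeline(cfg)
res$differential$mut_1
```
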