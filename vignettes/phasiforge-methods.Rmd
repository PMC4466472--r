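---
title: "Models and methods behind phasiforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phasiforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phasiforge` annotates plant small regulatory RNAs from collapsed
sRNA-seq libraries mapped to a reference sequence set. This vignette
explains the statistical models and procedures module by module, the
parameters that matter, the design decisions taken where several
reasonable conventions exist, and what the synthetic study used by the
test-suite does and does not establish.

## Read handling

Reads are collapsed to unique sequences carrying one count per library,
filtered to 18–26 nt (the Dicer product range), and mapped by *exact*
matching on both strands of the reference; a perfect-match contract
keeps the mapping unambiguous and is enforced by Aho–Corasick
dictionary matching (one dictionary per read length). Reads with more
than `max_loci = 500` perfect hits are flagged hyper-repetitive and
excluded from discovery: at that multiplicity a read is almost surely a
repeat/heterochromatic product whose locus assignment is meaningless.
Internal coordinates are 0-based half-open; GFF3 output converts to
1-based closed. `N` in the reference matches nothing.

RPM normalization divides by the per-library total of 18–26 nt
reference-matching reads (the "putative sRNA" set). This denominator is
a choice — raw totals before mapping would also be defensible — and it
is configurable at the `rpm_normalize()` call; the mapped-read total
makes RPM values comparable across libraries with different adapter or
contamination rates.

## miRNA discovery

Candidate loci are seeded by reads with total abundance ≥ 10. Seeds
within 450 nt cluster into one locus; the most abundant read anchors
the putative mature (its placement may shift up to 3 nt). Around each
anchor, precursor windows of 100–420 nt are extracted in both flank
orders (mature on the 5′ or the 3′ arm), keeping a 10 nt flank beyond
the mature; windows are capped at 450 nt so the mature/star span bound
is structural.

Two cheap read-composition filters run *before* folding, per candidate
window: single-strand bias (sense reads over all reads, ≥ 0.9 — miRNA
loci are transcribed one way) and abundance bias (top three reads over
all reads, ≥ 0.6 — discrete Dicer products, not a smear). Surviving
windows are folded in one batch. The default backend is ViennaRNA's
`RNAfold` (thermodynamic MFE); a Nussinov-style base-pair-maximizing
fallback with a crude per-pair energy (GC −3, AU −2, GU −1 kcal/mol) is
bundled so the package runs without ViennaRNA, but the energy filters
below are calibrated for the thermodynamic backend and the fallback is
intended for tests and demonstration.

From the fold we compute MFE, GC%, AMFE = −MFE/L·100, MFEI = AMFE/GC%,
and the duplex mismatch count: the star arm is the region paired with
the mature; every unpaired mature position (including bulged mature
bases, one each) counts one mismatch, and G:U wobbles count as paired —
the standard plant-annotation convention. Acceptance requires, with all
bounds inclusive: mismatches ≤ 4, MFE ≤ −30 kcal/mol, AMFE ≥ 22,
0.30 ≤ MFEI ≤ 1.80, GC ≥ 25 %, and the two bias bounds. Rejected
candidates carry the complete list of failed-rule codes. Per locus the
smallest accepted window is kept; identical matures from several loci
aggregate into one annotation listing all precursors.

Conservation uses an end-anchored ungapped distance: the best alignment
over shifts of ≤ 3 nt, counting mismatches plus one per unaligned
overhang base (length differences > 3 nt are infinitely distant, and
ties prefer the smaller shift). A mature within distance 3 of any known
plant miRNA — or whose star sequence is — is conserved (cs), otherwise
lineage-specific (ls). Matures ≤ 22 nt are canonical; 23–24 nt matures
are long/noncanonical.

## isomiR classification

All mapped reads inside an accepted precursor window (sense strand)
that are not the annotated mature or star are classified by their end
offsets against the mature: 5′-only, 3′-only, or both-end variants;
the `(0, 0)` offset pair is the mature itself. Offsets beyond 5 nt
demote a read to "other locus read" — beyond that it is no longer
meaningfully a variant of the same Dicer product. Only templated
variants exist here by construction (exact mapping); non-templated
tailing is out of scope. Reads varying around the star arm instead are
classified against the star and reported separately, since their
biology (passenger-strand products) differs. Each isomiR lists every
accepted precursor whose sequence contains it, because identical
variants frequently have several genomic sources; summaries tabulate
count, summed RPM and mean RPM per length (17–27 nt) and class, for all
isomiRs and for the ≥ 10 RPM subset.

## Phased siRNA detection

The detector works on reads with total abundance ≥ 2 that do not derive
from accepted miRNA loci. Windows of `window_len = 189` nt (9 cycles of
21; both configurable, with 24-nt phasing supported via `cycle = 24`)
slide in steps of one cycle. Within a window there are M = 2·189
candidate 5′ positions (both strands). A sense read occupies its
leftmost coordinate; an antisense read occupies the coordinate of its
5′ nucleotide, and participates in a register with a **+2 nt offset**
— the fixed antisense register convention mirroring the 2-nt 3′
overhang that DCL processing leaves on duplexes. The generator plants
antisense phased reads under the same convention, so the two sides of
the package agree by construction; any fixed offset convention works as
long as generator and detector share it.

With m in-register slots (18 per window), n distinct occupied positions
and k of them in register, the window statistic is the hypergeometric
tail P(X ≥ k). Occupancy is binary — a position with one read counts
like a position with a thousand — so the statistic measures the
*geometry* of 5′ ends and abundance enters only through the locus
filters. The register maximizing k is reported. That maximization over
21 registers makes the reported p anti-conservative under the null
(roughly a union bound, ≤ 21α); the test-suite verifies that the
fixed-register variant (`best_register = FALSE`) is calibrated, that
the best-register inflation stays within the union bound, and that
background-only simulations produce zero locus calls — the calls, not
the window p-values, are the inferential output, and they are protected
by the downstream filters.

Overlapping significant windows (p < 0.01, strict) sharing a register
class merge into maximal loci with the minimum window p. A locus is
kept iff at least one phased read has total count ≥ 10 (raw counts, not
RPM — a deliberate resolution of an ambiguity, configurable), the
RPM-weighted phased fraction is ≥ 50 %, and strand bias is < 0.9
(strict; a dsRNA intermediate yields both strands, unlike a hairpin).
Locus reads are then partitioned into phased (in-register, with the
antisense offset) and non-phased sets; the sets are disjoint by
construction.

## Target scoring, triggers, cis/trans cleavage

Target sites use the classic plant penalty scheme: over every ungapped
complementary window, mismatch 1.0, G:U wobble 0.5, penalties doubled
at sRNA positions 2–13 from the 5′ end; sites with expectation ≤ 3.0
are reported. The 2–13 doubling encodes the seed-proximal region whose
pairing AGO-catalyzed cleavage requires; the 3.0 cutoff is the scheme's
conventional default and is deliberately prominent in the
configuration, since no single value is canonical. Gapped alignments
are not searched (the 2.0 gap penalty is part of the scheme's
definition but cleavage-competent plant sites are overwhelmingly
ungapped); the scorer is verified against a brute-force window-penalty
oracle. The cleavage position is the transcript base opposite sRNA
position 10 — the first base of the downstream fragment.

A candidate sRNA (annotated miRNA, isomiR, phased or non-phased siRNA;
isomiRs are scored independently of their parent miRNAs) is a trigger
of a locus when some site's cleavage position falls in the locus
register, exactly by default (`tolerance = 0`, ±1 supported), and the
candidate itself is expressed (total count ≥ 2). The hit model is
`two_hit` when the same sRNA has qualifying sites on both sides of the
register origin. Cleavage modes: per transcript, the primary register
is the lowest-p locus having a miRNA/isomiR trigger; a miRNA/isomiR
trigger there is the **initiator**; a phased/non-phased siRNA trigger
originating from the same transcript is **cis**; everything else —
siRNAs from other PGTs, and miRNAs/isomiRs acting on secondary
registers — is **trans**. The resulting sRNA → transcript edges form a
directed network (igraph) that may legitimately contain cycles
(cascades can feed back); serialization (GraphML and edge-list TSV) is
deterministic.

## Differential expression

Kal's pooled two-proportion Z-test compares a tag's raw counts between
two libraries against the library totals:
\(z = (\hat p_a - \hat p_b)/\sqrt{p_0(1-p_0)(1/N_a + 1/N_b)}\), with a
two-sided normal p-value; degenerate pooled proportions give p = 1 by
convention. The test runs on raw counts (the statistically meaningful
scale); RPM is reported descriptively. Benjamini–Hochberg FDR is
applied within each pair; a sequence is `significant` below FDR 0.05 in
any pair, `likely` when not significant but ≥ 5 RPM somewhere and
changed ≥ 2-fold in some pair (fold changes are RPM ratios, with a 0.1
pseudo-RPM flagged when the denominator is zero), else `ns`.
Significant sequences are standardized per row (sample SD; constant
rows become zeros) and clustered by complete-linkage on Euclidean
distance into 5 groups by default. The test assumes only sampling
variance; with one library per tissue, biological overdispersion
inflates the significant set, which is why the planted-effect recall —
not the raw significant count — is the evaluated quantity.

## The synthetic study

The generator builds: hairpin contigs (mature + 48 nt loop + star with
1–3 planted duplex mismatches, inside 150 nt flanks); PGT-like 900 nt
transcripts with a trigger target site whose cleavage position equals
the register and 8 cycles of sense/antisense phased reads; a second,
well-separated register on cis transcripts triggered by one of their
own phased siRNAs; trans transcripts triggered by a phased siRNA
exported from another PGT; two end-variant isomiRs per hairpin (3′
variation twice as likely as 5′, mirroring the observed dominance of 3′
variants); a known-miRNA library relating half the matures within 0–3
substitutions (the cs/ls truth); planted 4-fold tissue effects; and
uniform reference-derived background (50 % of depth) whose length
profile peaks at 24 nt, over 400 decoy contigs of 2 kb. Counts are
negative binomial (dispersion 0.1) around expected RPM; each library
draws from its own derived RNG stream. Defaults were chosen once as a
realistic desk-scale study: planted mature abundances
(lognormal, clamped to 800–20000 RPM) sit where real miRNAs do relative
to a 10⁵-read library, and the reference is large enough that
background does not pile on planted loci more densely than in real
data.

Two structural points are deliberate. Planted duplex mismatches are
spread so that no mature sub-window remains exactly complementary to
the star arm; an exactly complementary stretch would cross-map between
the arms and wreck the strand-bias signal — an artifact of perfect
complementarity that real precursors (whose arms always mismatch
somewhere) do not show. And the secondary cis register is placed more
than one scan window downstream of the primary read block so the two
loci are separable by the detector, as they are on real TAS-like
transcripts where secondary registers arise downstream of the primary
cascade.

What passing the planted-recovery tests shows: the pipeline's stages
compose correctly, every filter admits true signal at realistic
abundance, and the cis/trans logic labels known cascades correctly.
What it does not show: performance on real libraries with sequencing
error, non-templated tailing, RNA editing, repeat-driven multi-mapping,
fragmented assemblies, or hairpins at the edge of the fold filters —
the generator does not emulate these.

## Numerical and engineering choices

* Hypergeometric tails come from `phyper`; the test-suite checks them
  against placement enumeration over every (M ≤ 40, n ≤ 10)
  configuration to 10⁻⁹, with literal subset enumeration on small grids.
* BH FDR delegates to `p.adjust(method = "BH")` behind the `bh_fdr()`
  surface and is checked against the step-up definition.
* All threshold comparisons are inclusive on the cited bound except the
  phasing p-value (< 0.01) and the PGT strand bias (< 0.9), which are
  strict.
* Ties: the candidate anchor is the most abundant read (then leftmost,
  then lexicographic); the reported register is the smallest among those
  maximizing k; multi-locus lists are sorted.
* Degenerate inputs (empty libraries, background-only datasets, zero
  phasing input, loci with no reads) flow through every stage and yield
  empty, well-typed results.
* Outputs carry no timestamps and use fixed formatting, so identical
  configuration and seed give byte-identical run directories; a
  completed output directory with the same configuration digest is
  reused rather than recomputed (resumption is at run granularity —
  stages exchange in-memory objects, so per-stage caching would buy
  little here).
* The test-suite exercises the full default study (30 hairpins, 18
  planted registers, 3 × 10⁵ nominal depth) once, and a reduced study
  (6 hairpins, 6 registers, 2 × 10⁴) for the many per-module checks —
  sizes chosen to keep the suite quick while leaving every filter's
  operating point unchanged.

## Known limitations

Exact matching only (no mismatch mapping mode); no adapter trimming or
quality filtering; no degradome/PARE validation of cleavage sites; no
AGO-sorting rules or 22-nt-trigger enforcement; miRBase-style family
nomenclature is not assigned; the two-proportion test cannot model
biological replicates (none exist in the intended single-library-per-
tissue design); and the bundled base-pair-maximization fold is not a
thermodynamic model — conclusions about MFE-based filters require the
ViennaRNA backend.
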