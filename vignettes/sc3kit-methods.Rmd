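---
title: "sc3kit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sc3kit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sc3kit)
```

## The problem

3'-end tag counting (SC3-seq) sequences a short fragment adjacent to each
transcript's poly-A site, so reads pile up within roughly 300 bp upstream
of the transcription termination site (TTS) — and, when the annotated TTS
falls short of the true 3' end, just *downstream* of it. Quantifying such
libraries against an unmodified annotation silently loses those genes.
sc3kit implements the downstream computational method for this protocol:

1. **Annotation rewrite** — extend every gene's TTS by up to 10 kb under
   strand-aware collision rules, after removing pseudogenes/tRNAs/ncRNAs
   and collapsing genes that share an identical TTS.
2. **Quantification** — strand-matched read-to-gene assignment over the
   extended exonic spans, with ERCC spike-in separation, and conversion
   to RPM (reads per million) and log2(RPM+1).
3. **Quality control** — read-category accounting, the TTS meta-profile,
   qPCR concordance, housekeeping-Ct prescreen, and per-cell expression
   percentiles over the expressed-gene subset.
4. **Cell annotation** — unsupervised hierarchical clustering (Pearson
   correlation distance, Ward ward.D2 linkage), seeded t-SNE, and
   boolean marker-combination classification into embryonic lineages.
5. **Simulation** — seeded generators for toy genomes, 3'-biased reads
   and cell-type-structured expression matrices, so that every stage is
   testable without any external download.

## The extension rules

For a gene with TTS $t$ on strand $s$, let $W$ be the 10 kb window
immediately 3' of $t$ (configurable via `extension_config()`). The new
TTS is the most restrictive of:

* $t + 10\,\mathrm{kb}$ in the 3' direction (no neighbour in $W$);
* for a same-strand gene with TSS inside $W$: 1 bp upstream of that TSS;
* for an opposite-strand (convergent) gene with TTS $u$ inside $W$:
  the midpoint — $\lfloor (t+u)/2 \rfloor$ for the lower-coordinate
  gene and $\lfloor (t+u)/2 \rfloor + 1$ for the other, so the two
  extensions are always disjoint;
* 1 bp short of any other retained gene body intruding into $W$;
* the chromosome end.

Coordinates are 1-based closed (GFF3). All collision tests use the
**original** coordinates of the other genes, never already-extended
ones; this makes `extend_all()` independent of gene processing order.
Re-running the extension on its own output can extend further (the
blockers moved); this non-idempotence is intentional and tested.

Decisions the rule statement leaves open, and what this package does:

* **Which gene survives a shared TTS.** The longest gene body (it
  captures the most signal); ties break to the smallest `gene_id` so the
  result is deterministic and order-independent.
* **Bodies without a terminus in the window.** A gene body can span the
  whole window while presenting neither a TSS nor a TTS inside it. Only
  terminus hits are enumerated by the rules; we close the gap
  conservatively — any intruding body caps the extension 1 bp before
  its first intruding base. For terminus hits this body cap coincides
  with (TSS) or is dominated by (TTS midpoint) the explicit rules, so
  the closure changes nothing in the enumerated cases.
* **Do pseudogenes block extension?** Listing the biotype removal last
  would let removed genes block their neighbours. The default is
  `biotype_filter_order = "before_extension"` (removed genes do not
  constrain anyone); `"after_extension"` reproduces the literal rule
  order. Both are tested.
* A neighbouring body starting 1 bp after the TTS yields a zero-length
  extension, not an error; extension at a chromosome edge clamps.

## Quantification choices

* A read is assigned to a gene when at least 1 bp intersects the gene's
  extended *exonic* span on the **same strand** (the library is
  strand-preserving, second-strand orientation). `use_gene_span = TRUE`
  switches to whole-span overlap.
* Reads hitting more than one gene are dropped as `AMBIGUOUS` (never
  fractionally split); reads on `ERCC-*` chromosomes are tallied
  separately as spike-ins and excluded from gene counts.
* **RPM denominator.** The published description does not state whether
  the per-cell denominator is gene-assigned or genome-mapped reads. The
  default is the gene-assigned total, which makes "each cell's RPM sums
  to $10^6$" an exact invariant; `denominator = "genome_mapped"` is
  available. The choice scales each cell by a constant and does not
  affect within-cell rankings.
* Expressed genes: log2(RPM+1) strictly greater than 4 in at least one
  cell — the same cutoff the cohort QC uses.

## QC statistics

* `check_tally()` verifies that the five read categories (gene-mapped,
  mapped elsewhere, spike-in control, low-quality/adaptor/poly-A,
  unmapped) sum exactly to the total — the invariant that holds on every
  row of the shipped 474-sample cohort table.
* `prescreen_ct()` applies the strict cDNA-quality bounds Ct(GAPDH) < 19
  and Ct(PPIA) < 20; samples missing either marker are `indeterminate`.
* `tts_metaprofile()` histograms read 5'-offsets from the original
  (pre-extension) TTS, in kilo-RPM per 50 bp bin over [−3000, +1000] by
  default; assignment uses the extended annotation so that tags
  downstream of an under-annotated TTS are captured. The column integral
  equals (reads in window)/(assigned reads) × 10³ — a conservation law
  the tests assert.
* `qpcr_concordance()` orients delta-Ct as housekeeping mean minus gene
  Ct, so higher expression gives larger delta-Ct and the concordance
  slope is positive; the published figure does not state the sign.
* `expression_percentiles()` uses linear interpolation between order
  statistics; the box-plot whisker is median + 2·sd of the cell's
  expressed-gene values. The published legend ("2 s.d. from the median")
  is ambiguous about the spread estimator; the sample standard deviation
  is used and the choice is flagged here.

## Marker classification

Thresholds on log2(RPM+1) define the states used in marker logic:
"(+)" above `theta_on` (default 4, aligned with the expressed-gene
cutoff), "(−)" below `theta_off` (default 2), "low" in between. The
published marker combinations carry no numeric thresholds; these
defaults are the package's choice and are configurable everywhere.

`default_rules()` encodes nine lineages. Rules are applied
first-match-wins in priority order, with the more gene-specific rules
first — necessary because the combinations are not mutually exclusive
(every post-implantation EPI cell also satisfies the pre-implantation
EPI pattern; early and late PGCs share TFAP2C(+)/SOX2(−) and are
separated only by PRDM1/SOX17 versus POU5F1/NANOG). The evaluation
trace of every rule is recorded per cell.

## What the simulators emulate — and what they do not

`make_annotation()` plants each extension scenario (isolated gene,
shared TTS, tandem TSS stop, convergent midpoint, spanning-body
intrusion, pseudogene neighbour) in its own 60 kb slot, far enough
apart that scenarios cannot interact, and records each gene's expected
extended TTS. `simulate_reads()` draws read 5' positions a truncated
exponential (scale 100 bp, truncated at 300 bp) upstream of the TTS —
the positional signature of the protocol's ~300 bp 3' enrichment — with
a binomial share of uniform ERCC-like spike-in reads.

`simulate_expression()` plants each cell into a lineage and draws its
marker values from truncated normals inside the state's threshold
interval: "on" from N(6, 1) truncated above `theta_on`, "low" from
N(3, 0.5) truncated into (`theta_off`, `theta_on`], "off" at 0,
background genes from N(1, `noise_sd`) clipped at 0. The truncation
expresses that a *planted* state genuinely is that state — the spread
models within-state biological variability, not measurement error that
could silently flip the planted truth. Dropout is expression-dependent,
$p = p_0 \cdot 2^{-v}$ with $p_0$ = `dropout_p`: at these sequencing
depths strongly expressed genes essentially never drop out, weakly
expressed ones do at roughly $p_0/8$. (A flat 10% dropout on required
markers would make a four-marker rule fail 34% of the time, which is
not a world in which any boolean classifier recovers 95% of labels —
so the flat reading is internally inconsistent with the recovery
property this generator is specified to satisfy.)

A lineage with an "any of" marker set (gastrulating cells: some of T,
GATA4, GATA6 on) is planted as several distinct expression profiles,
one per chosen gene — mirroring the real cohort, where gastrulating
cells form multiple clusters. The truth table therefore reports both
`label` (9 lineages) and `profile`; the **planted cluster count is the
number of distinct profiles** (typically 11), and cluster-recovery is
measured against `profile` at that k. At k = 9 against bare labels the
dendrogram may legitimately keep two gastrulating sub-profiles apart
while merging the two closely related EPI states.

What a green test does *not* establish: the generators draw
conditionally independent values per gene — no gene–gene correlation
beyond the lineage structure, no batch effects, no ambient RNA, no
doublets, no read-level sequence content (bases and qualities are out
of scope). Recovery rates on this synthetic cohort say the classifier
and clustering logic are correct, not that real cells of these
lineages are this separable.

## Numerical notes

* Ward clustering is `stats::hclust(method = "ward.D2")`, the exact
  routine used on the real cohort; the test suite checks it against a
  naive Lance–Williams re-implementation for n ≤ 7 and exact blob
  recovery for planted cohorts.
* Pearson distance refuses zero-variance cells by name rather than
  returning NaN rows.
* t-SNE (`Rtsne`) is treated as a seeded contract — determinism and
  neighbourhood preservation are tested, exact layout is not.
* `floor((t+u)/2)` midpoints assign the extra base of an odd gap to the
  higher-coordinate gene; the two extensions can touch but never
  overlap.
* All generators run under a scoped RNG seed and restore the caller's
  RNG state.

## Reproducing the real-cohort expressed-gene count (optional, networked)

The count of 19,225 expressed genes (log2(RPM+1) > 4 in ≥ 1 of 474
cells) is a property of the deposited cohort matrices (GEO series
GSE67259, GSE76267, GSE74767), not of any desk-scale fixture. With the
downloaded per-sample expression tables assembled into a genes × 474
matrix `logm` (on the log2(RPM+1) scale), the check is one line:

```r
length(expressed_genes(logm))  # 19225 expected
```

This workflow requires a network download of several hundred MB and is
deliberately not part of the test suite.

## Known limitations

* The GFF3 reader collapses all transcripts of a gene into one exon
  union; isoform-level 3' ends are not modelled (the rewrite operates
  per gene, as the protocol's quantification does).
* `biotype` is a five-level simplification; ncRNA sub-ontologies are
  not distinguished beyond the removal flag.
* Name mapping is consumed as a precomputed two-column table; running
  LiftOver is out of scope.
* The CLI is an `Rscript` executable shipped under
  `system.file("cli", "sc3kit", package = "sc3kit")`; R provides no
  automatic PATH installation for package scripts.
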