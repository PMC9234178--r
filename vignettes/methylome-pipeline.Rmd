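---
title: "Methods: windowed WGBS differential methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed WGBS differential methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical methods, modelling choices and
parameter defaults of `dmrscan`, in pipeline order. It is written as a
methods section: each subsection states what is computed, how, and why
that form was chosen.

## 1. Coordinates and file formats

All internal coordinates are **1-based inclusive**. The package's host
ecosystem — CX count tables, GFF3/GTF, `Biostrings`,
`data.table::foverlaps` — is 1-based inclusive throughout, so adopting
it avoids conversion at every interface; the single 0-based half-open
boundary is the BED writer (`write_dmr_bed()`), which decrements
`start` on output.

Cytosine counts use the six-column "CX report" dialect: chromosome,
position, strand, methylated reads, unmethylated reads, context
(`CG`/`CHG`/`CHH`). Zero-coverage rows are retained on read because
coverage accounting (e.g. the `non` methylation class, covered-site
counts per element) needs to distinguish "no data" from "no signal".
Genomes are FASTA restricted to `{A, C, G, T, N}`; IUPAC ambiguity
codes are rejected because context classification is undefined over
them.

## 2. Context classification

A cytosine's context is read from the strand-local trinucleotide
starting at the C: next base G → `CG`; else base-after-next G → `CHG`;
else `CHH`. On the minus strand the local sequence is the reverse
complement of the reference, so minus-strand cytosines appear as `G`
in the reference and their context is read leftward through
complements. Sites whose two-base window contains `N` or runs off the
chromosome end are dropped (and counted in an `n_dropped` attribute)
rather than guessed.

## 3. Non-conversion estimation and site calling

Incomplete bisulfite conversion makes unmethylated cytosines read as
methylated at some rate $r$. With an unmethylated spike-in contig, $r$
is the pooled methylated fraction over the contig
(`sum(n_meth) / sum(n_total)`), and the bisulfite conversion
efficiency is $1 - r$. Without a spike-in the global CHH level is used
as a proxy — an upper bound wherever genuine CHH methylation exists —
and the function says so in a message.

A covered site is called methylated from the one-sided binomial tail
$P(X \ge n_{meth} \mid n_{total}, r)$ under the null that all apparent
methylation is non-conversion, followed by Benjamini–Hochberg
correction across all tested sites and a q ≤ 0.05 call. Global and
per-context levels are read-count weighted
(`sum(n_meth) / sum(n_total)`), which down-weights noisy low-coverage
sites, and corrected for the false signal as
$\max(0, (m - r)/(1 - r))$.

## 4. Feature profiles

Genes are expanded into eight element classes: `gene_body`, `exon`,
`intron` (gaps between sorted exons), `CDS`, `utr5`, `utr3` (derived
as exon − CDS split 5′/3′ by strand when absent from the annotation),
and strand-oriented `upstream_2k` / `downstream_2k` flanks clipped at
chromosome ends. A site contributes to *every* element containing it
(a CDS site is also exon and gene body), which makes per-gene
read-count pooling an invariant: exon + intron reads reconstruct the
gene-body cell exactly, a property the test suite checks.

The metagene profile bins the 2 kb flanks in fixed 100 bp steps and
the gene body in 40 length-normalised fractional bins; minus-strand
genes are reflected so bin 1 is always 5′-most. Per-bin levels are
read-count weighted over all genes.

## 5. DMR detection

The genome is partitioned into consecutive, non-overlapping 200 bp
tiles. Within a tile and context, replicate counts are pooled per
group by summation; only sites covered in **both** groups contribute,
so both group levels describe the same site set. Each window is tested
with a two-sided Fisher exact test on the pooled 2×2 table
(methylated/unmethylated × group); degenerate tables (a zero margin)
get p = 1. q-values are BH across all tested windows of the context,
genome-wide, one family per comparison. A window is a DMR when it
passes its context's preset:

| context | min sites | min \|Δlevel\| | max q |
|---------|-----------|---------------|-------|
| CG      | 5         | 0.25          | 0.05  |
| CHG     | 5         | 0.25          | 0.05  |
| CHH     | 15        | 0.15          | 0.05  |
| ALL_C   | 20        | 0.20          | 0.05  |

Direction is `up` when group A (the left side of the `A_vs_B`
comparison label) is hypermethylated. A per-replicate Welch t
alternative on window levels is available (`test = "ttest"`) for
sensitivity analysis; pooled Fisher is the default because per-window
replicate-level variance is poorly estimated at 3 + 3 replicates.

## 6. DMGs and enrichment

A DMR is assigned to a gene if it overlaps (≥ 1 bp) the gene body or
either 2 kb flank; `element_hit` records every element class touched,
one record per (gene, DMR) pair. Unassigned DMRs are kept in an
intergenic ledger so `total = mapped + intergenic` always holds.
Term enrichment of a DMG set is the upper-tail hypergeometric
$P(X \ge k)$ against an opaque term → gene map, BH-corrected across
terms; no ontology structure is assumed.

## 7. Expression and integration

Expression is quantified as FPKM
(`count / (length/10^3) / (library/10^6)`), with library sizes
defaulting to column sums. For ≥ 2 replicates per group, the DEG test
is a **pooled-variance** two-sample t-test on `log2(FPKM + 1)`. A
Welch test was considered and rejected: with three replicates the
Satterthwaite degrees of freedom collapse toward 2 whenever one
group's variance shrinks, flooring attainable p-values near 5×10⁻³ —
above any BH threshold at around a hundred genes — so genuine 8-fold
changes become uncallable. The pooled form keeps df = 4 and is exact
under equal variances, the regime the generator produces. The DEG rule
is q < 0.05 and |log2FC| > 1, with the fold change computed on
pseudocounted mean FPKM; 1 vs 1 designs fall back to an exact binomial
split test on pooled counts.

Integration has three views: (i) tercile methylation classes
(`non`/`low`/`middle`/`high`) per region × context, with `non` for
uncovered or exactly-zero genes; (ii) Spearman correlation of regional
methylation with mean FPKM across genes (exact permutation p for
n ≤ 10 without ties); (iii) the DMG × DEG concordance table, where a
record is (gene, DMR, region) and `correlation_sign` is `positive`
when DMR and DEG directions agree. Negative gene-body coupling shows
up as dominance of `negative` cells.

## 8. The synthetic-study generator

The generator exists so the pipeline can be validated with known
truth. All randomness flows from one seed (`seed`, `seed + 1`,
`seed + 2` for genome, methylome, expression), making every output
byte-reproducible. Defaults describe the study conditions the package
is validated under; they were fixed while designing the generator:

- **Genome**: 1 Mb i.i.d. sequence at GC 0.35; 120 non-overlapping
  genes (gamma-distributed lengths, mean 1.5 kb, min 600 bp; 2–5
  exons; UTRs ≈ 10%/15% of the mRNA) spaced ≥ 2 × 2 kb so flanks never
  overlap a neighbouring body; a 5 kb unmethylated spike-in contig.
- **Methylome**: each cytosine draws a true level from a Beta around
  its context mean (CG 0.1276, CHG 0.0077, CHH 0.0078 — the mosaic,
  CG-dominated pattern typical of invertebrate methylomes) with
  concentration 20; the draw is shared across groups and replicates
  (it is the site's biology). 50 planted 200 bp grid-aligned CG
  windows shift the case group's true level by +0.4, clipped to
  [0, 1]; windows must contain ≥ 5 CG sites. Per replicate, coverage
  is Poisson(25) and observed methylated counts are binomial with
  success $p + (1-p)\,\varepsilon$ at non-conversion
  $\varepsilon = 0.01$.
- **Expression**: expected counts are
  $200 \cdot \exp(-0.5\, z_g)$ with $z_g$ the standardised true
  gene-body methylation (negative coupling); genes overlapping a
  planted window get an additional case-group log2 shift of magnitude
  3 whose sign is `sign(coupling) × sign(delta)` — hypermethylated
  genes are silenced. Counts are negative binomial with dispersion
  0.05.

Planted windows are aligned to the tiling grid (`grid_offset = 0`) so
recall and FDR accounting against the scan is exact rather than
fractional; `grid_offset` can be set to study off-grid behaviour.

## 9. Orchestration and determinism

`run_pipeline()` executes load → calling → profiles → DMR scan (four
contexts) → DMG/enrichment → DEG → integration, writes every table
under fixed names, and finishes with a manifest recording the
configuration hash and per-stage row counts — no timestamps, so
identical inputs give byte-identical output directories. Stage
failures are reported as `pipeline stage '<name>' failed: <reason>`,
e.g. a CX table naming a chromosome absent from the genome aborts the
load stage.

## 10. Scope and limitations

- The Fisher window test treats pooled reads as independent Bernoulli
  trials; biological replicate overdispersion within a window is not
  modelled (the t-test route is the escape hatch).
- One transcript per gene is assumed; alternative isoforms are
  collapsed to the first.
- The DEG caller is deliberately simple (t on log2 FPKM); it is not a
  replacement for count-model packages on real data, but is exact
  under the generator's log-normal-like regime and keeps the package
  dependency-light.
- Problem sizes (1 Mb genome, 120 genes, 3 + 3 replicates, depth 25)
  are the package's own validation conditions, chosen to exercise
  every code path in minutes on one CPU.
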