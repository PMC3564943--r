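---
title: "Finding unannotated 3' gene ends with pasScout: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding unannotated 3' gene ends with pasScout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The 3' end of a mature transcript — its cleavage and polyadenylation site
(PAS) — is hard to annotate. Unlike exon junctions it leaves no spliced
read signature, and unlike coding sequence it has no reading frame. Long
3'UTRs can extend kilobases past the last annotated exon, covered only by
short EST fragments that never tie the distal end to the upstream gene.

pasScout scores candidate 3' ends with two independent signals and
calibrates both against independent annotation databases.

**Conservation Drop Index.** Selection acts on transcribed 3'UTR sequence
(AU-rich elements, miRNA seeds) but largely stops at the cleavage site.
For an extreme whose last transcribed base is $b$, let $T$ be the
50-nt window of the mature transcript ending at $b$ (the base $b$ itself
is transcribed and belongs to $T$) and $NT$ the 50-nt window beginning
50 nt outside the transcript. Then

$$\mathrm{CDI} = \overline{s}_{T} - \overline{s}_{NT},$$

the difference of mean per-base conservation. The 50-nt gap between the
anchor and $NT$ matters: the downstream sequence element (a G/GU-rich
region ~25 nt past the cleavage site) is itself under selection, and
without the gap it would contaminate the "non-transcribed" window. We
take the windows literally and do not trim $T$ around the polyA signal
hexamer; the hexamer is conserved, transcribed, and belongs in $T$.
A positive CDI is a 3'-end signature specifically: promoters keep their
flanking sequence conserved, so 5' ends show no comparable drop.

**Coverage Difference.** An orthologous transcript model projected onto
the same genome proposes a concrete extension when it shares the
reference transcript's last intron — exact coordinate identity of donor
and acceptor on the same chromosome and strand, no fuzz, because
"same gene structure" is a categorical claim — and ends strictly more
distally. With RNA-seq coverage binarised per base (covered means depth
$\ge 1$; read orientation is ignored, as total RNA libraries here are
unstranded),

$$\mathrm{CD} = 100\cdot\frac{|\{\text{covered bases in Up}\}|}{|Up|}
             - 100\cdot\frac{|\{\text{covered bases in Down}\}|}{|Down|},$$

where $Up$ runs from just past the annotated PAS to the putative PAS and
$Down$ is the equal-length interval immediately beyond. Binarisation
makes CD invariant to sequencing depth above 1 and robust to coverage
spikes; what it measures is the *fraction of the extension that is
transcribed at all* versus the silence beyond it.

**Empirical FDR.** A putative PAS is *supported* when some validating
transcript (another database, or projected orthologs) ends within a
tolerance of the same position *and* its last intron coincides with an
intron of the examined database — the second condition ties the
validating evidence to a known gene structure rather than to a stray
model. The FDR at cutoff $c$ is the unsupported fraction among sites
scoring $\ge c$; one curve point per distinct observed score, sorted by
descending cutoff, with a rank column for the equal-spacing presentation.
These FDRs are deliberately conservative: a genuine site missing from
every validating database counts as a false discovery.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `linkage_distance` | 1 | nt | EST termini at the same base or 1 nt apart describe one end; chaining is transitive (single linkage) |
| `merge_distance` | 25 | nt | cleavage is heterogeneous over a few nt; nearby clusters are one site, resolved to the transcription-distal cluster |
| `min_support` | 4 | ESTs | clusters with fewer extremes are indistinguishable from alignment noise |
| `splice_site_exclusion` | 25 | nt | an extreme that close to a spliced-EST junction is most likely an unannotated exon boundary, not a transcript end; the radius is inclusive (exactly 25 nt away is removed) |
| `max_gene_distance` | 1 Mb | nt | beyond this no gene can plausibly claim the extreme |
| `window` | 50 | nt | long enough to average over conservation noise, short enough to stay inside the terminal exon |
| `gap` | 50 | nt | skips the conserved DSE (see above) |
| `min_value_fraction` | 0.5 | — | conservation tracks have gaps; a window mean from fewer than half its bases is flagged undefined rather than imputed |
| `pas_tolerance` | 25 | nt | support matching uses the same few-nt cleavage heterogeneity as merging; set 0 for a literal same-position reading |

## Numerical and procedural choices

* **Coordinates.** All intervals live in `GRanges` (1-based, closed), the
  native Bioconductor convention; BED and bedGraph (0-based half-open)
  and GTF/wiggle (1-based) are converted at the parser boundary and
  nowhere else. With 50-nt windows and 25-nt radii the method is
  acutely sensitive to off-by-one drift, so one internal convention is
  enforced by the readers and covered by round-trip tests.
* **Cluster representative.** The modal member position, ties resolved to
  the larger coordinate. The representative only needs to be stable and
  inside the member span.
* **Merge frame of reference.** "Most distal" needs a direction before
  classification exists, so it is resolved against the transcription
  direction of the nearest reference transcript; when no transcript lies
  within 1 Mb the highest-support cluster survives (ties to the larger
  coordinate). One pass suffices: surviving clusters are provably
  $\ge$ `merge_distance` apart, making the operation idempotent.
* **Filter order.** Support filter, then exon filter, then splice-site
  filter, then merging, then classification — merging therefore operates
  only on plausible ends, and classification only on survivors.
* **Intron containment.** A PTE inside a reference intron is classified by
  the orientation of the containing transcripts (the gene body is
  transcribed towards it, so it is treated as a putative PAS of an
  alternative last exon); containment in opposite-strand transcripts, a
  tie between equidistant genes with conflicting labels, or no gene in
  range give `undetermined`. Undetermined PTEs still get CDIs — both
  window orientations, reported as a pair — because orientation, not
  identity, is what the geometry needs.
* **EST orientation** is parsed and carried but never consulted: EST
  library protocols make the recorded strand unreliable, and both termini
  of every alignment are candidate extremes. Any multi-block alignment
  counts as spliced, whatever the gap size.
* **Degenerate input.** Windows truncated at the chromosome start are
  flagged, not fatal; truncation also counts against the value fraction.
  Candidates whose Down interval would be empty are dropped; truncated
  Down percentages are computed over the truncated length and flagged.
  Empty EST input produces empty tables and a success exit.
* **Multiple orthologs** extending the same reference transcript yield one
  candidate per pair; `collapse = "most-distal"` keeps the farthest per
  reference transcript for per-gene reporting. Any strictly positive
  extension is accepted (`min_extension` raises the bar if wanted).
* **Tissue pooling.** Coverage tracks are pooled by per-base depth
  summation, so a base is covered in the union iff covered anywhere —
  the natural companion of the binary covered/not-covered definition.
  Per-tissue CDs remain available through the CLI flag.

## What the generator emulates — and what it does not

`generateScenario()` plants multi-exon genes on a synthetic chromosome
and emits every input the pipeline consumes. Its defaults are the
strong-signal regime the acceptance tests run: 30 three-exon genes on
400 kb, 20 with a true distal PAS 0.5–1.5 kb beyond the annotated one;
per-base conservation Normal with $\mu_{in} = 1.5$ inside mature
transcripts (plus a 200-nt conserved promoter flank upstream of each TSS,
so the conservation drop is specific to 3' ends), $\mu_{out} = -0.5$
outside, $\sigma = 0.5$; Poisson(8) EST ends per true PAS jittered
$\le 1$ nt; uniform decoy extreme clusters at 0.5/kb with support
$4 + \mathrm{Pois}(2)$; per-base coverage probability 0.9 up to the true
PAS and 0.02 beyond; every true extension echoed by an ortholog model and
30% of unextended genes given a decoy ortholog extension. Spliced ESTs
across every annotated intron exercise the splice-site filter, and decoys
land in exons, introns and intergenic space, exercising every filter and
classification branch. All randomness flows from one seed; identical
configurations give byte-identical files.

The generator deliberately omits much of what makes real data hard:
conservation is a two-level Normal step (no phylogeny, no Alu deserts
inside real 3'UTRs), coverage is i.i.d. per base (no expression gradients
or mappability holes), EST ends have no internal priming artefacts, and
there are no overlapping or nested genes beyond what decoy placement
produces. Passing tests therefore demonstrate that the statistics and
filters implement their definitions and recover planted structure under
the stated noise model — not that the method's operating characteristics
on a real genome match these numbers.

## Test problem sizes

The suite checks the definitional examples by hand, equates each core
statistic with an independent brute-force reimplementation on 100 seeded
random instances (1e-12 tolerance on floating means), verifies the
invariants (CDI shift-invariance and scale-equivariance, CD depth
binarisation and bounds, genome-mirror invariance of CDI/CD/labels, merge
idempotence and separation, FDR endpoint identity), and runs the full
pipeline on one 400-kb strong-signal scenario plus smaller 60–90 kb
scenarios for determinism and CLI checks — sizes chosen so the whole
suite stays interactive while every code path is exercised at realistic
densities.

## Known limitations

* Support for a putative PAS requires a multi-exon validating transcript
  (the shared-last-intron condition); single-exon validating models can
  never support a site, which further inflates the estimated FDR.
* The CDI needs a resolved orientation; in gene deserts (no transcript
  within 1 Mb) PTEs stay undetermined and are excluded from PAS-ranked
  FDR curves.
* BAM and bigWig are out of scope by design: depth is consumed as
  bedGraph (`samtools depth` / `bedtools genomecov -bga` upstream), and
  conservation as wiggle or bedGraph text.
* The pipeline consumes projected ortholog models; the cross-species
  projection itself (TransMap or equivalent) is upstream of this package,
  as is read alignment.
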