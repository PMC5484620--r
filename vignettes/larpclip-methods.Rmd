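---
title: "PAR-CLIP binding-site inference and UTR sequence analysis: methods"
author: "larpclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAR-CLIP binding-site inference and UTR sequence analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larpclip)
```

# The problem

PAR-CLIP maps where an RNA-binding protein touches the transcriptome:
4-thiouridine is incorporated into nascent RNA, UV crosslinking covalently
traps protein–RNA contacts, and reverse transcription through a crosslinked
uridine misreads it as cytidine. A bound position therefore announces itself
twice — by a pile-up of reads and by T-to-C mismatches inside them. This
package implements, end to end, the computational side of a PAR-CLIP study
of LARP1, an RNA-binding protein whose contacts with ribosomal-protein (RP)
mRNAs move between transcript regions with mTORC1 activity: under growth
conditions binding sits on 3'UTRs; when mTOR is inhibited, binding
additionally appears on pyrimidine-enriched sequences (PES) at the 3'-most
end of RP 5'UTRs.

Everything runs in transcript space: each gene is represented by a single
transcript model with known 5'UTR/CDS/3'UTR boundaries, and all coordinates
are 0-based half-open internally (SAM is written 1-based, BED 0-based, per
those standards).

# The site-calling model

Reads are placed on the transcriptome (ungapped; the package carries a
desk-scale exhaustive best-stratum placer mirroring a `-v 3 -k 100 --best
--strata` mismatch-bounded policy, for small inputs and for tests — real
libraries arrive as SAM). Mismatches are recovered by comparing each read's
sequence to the reference window it spans, never from alignment tags, so
minimal SAMs suffice. A read mapping to $k$ positions contributes weight
$1/k$ to each (even distribution), and "total mapped reads" of a library is
the sum of placement weights.

The caller then:

1. discards reads with more than 2 T-to-C conversions (abundant conversions
   at this stage indicate sequencing artefacts rather than crosslinks);
2. clusters the surviving reads per transcript into maximal sets connected
   by overlap of at least one nucleotide (half-open intervals: spans
   `(10,20)` and `(20,30)` do *not* overlap);
3. smooths each cluster's weighted per-base coverage with a unit-mass
   Gaussian kernel (sigma 5 nt, truncated at 4 sigma, zero-padded so mass is
   conserved exactly before trimming) and trims the cluster to the maximal
   contiguous run of smoothed coverage at or above a floor (0.5) containing
   the smoothed maximum — clusters entirely below the floor are dropped;
4. keeps a cluster as a binding site iff at least one member read carries a
   conversion and the site's RPM passes a threshold;
5. scores sites by RPM (weighted member reads per million mapped) and by the
   expression-normalized score RPM / gene RPKM × 1000.

Expression comes from replicate mRNA-seq libraries: per-library RPKM
(count / (total/10^6) / (kb)), averaged across replicates, with a gene
counted as expressed if it has reads in at least one replicate — that
expressed set is also the background universe for enrichment tests.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_t_to_c_per_read` | 2 | conversions | read filter before clustering |
| `min_conversion_reads` | 1 | reads | a site must show the crosslink signature |
| `rpm_threshold` | 1.0 | RPM | the original study used an empirically derived, unpublished value; here it is explicit and configurable |
| `smoothing_sigma` | 5 | nt | boundary smoothing scale |
| `smoothing_floor` | 0.5 | coverage | trim level after smoothing |

The RPM threshold deserves emphasis: because the published analysis never
printed its value, reproducibility demands an explicit number. With the
default synthetic library depths (~25k placements) even a single read
clears 1 RPM, so the conversion-read requirement does the heavy lifting;
raising the threshold only ever shrinks the site set (a tested
monotonicity invariant).

# The synthetic study

The generator is the package's ground truth and defines the study
conditions; it is not a tuning knob. Defaults: 300 transcripts, 20% RP,
20% other translation-related (TR_other), 60% non-translation-related
(non_TR); UTR5/CDS/UTR3 lengths uniform on 80–220 / 300–900 / 150–450 nt;
uniform base composition outside planted features.

Planted features per category:

* **RP**: a 5'TOP at the cap (C then ≥5 pyrimidines), a 25-nt PES abutting
  the 5'UTR/CDS junction, and one GA-rich 3'UTR footprint.
* **TR_other**: PES and GA-rich 3'UTR footprint, but no TOP.
* **non_TR**: CDS and 3'UTR footprints only.

The occupancy table (expected reads per footprint) encodes the biology the
pipeline must recover: RP/TR 5'UTR footprints emit reads only under
`mTOR_off` (60 and 40 reads respectively), 3'UTR and CDS footprints emit
under both conditions (40–60 reads). Footprint reads span their footprint;
every covered reference T inside the footprint reads as C independently
with probability 0.3 (the crosslink conversion rate). Background reads are
uniform at 0.5 reads/kb with a 10^-3 per-base sequencing error, and a 60-nt
cassette duplicated into 5% of transcripts (non_TR CDSs, so ambiguity never
collides with planted footprints) creates controlled k-way multimapping.
mRNA-seq counts are one multinomial draw per 5×10^5-read replicate with
probability proportional to log-normal abundance × effective length;
replicates are independent draws from identical abundances, and reads are
emitted as perfect-match placements (only perfectly-mapping mRNA-seq reads
enter quantification, so sequence errors would be discarded upstream
anyway).

Two compositional choices are deliberate:

* PES bases are pyrimidine with probability 0.9, and a planted pyrimidine
  is C with probability 0.85. The C bias keeps the per-read T count of a
  PES footprint near 3, so the 0–2-conversion read filter removes a
  similar, small fraction of reads from every footprint class — otherwise
  T-rich footprints would be selectively depleted and region-share
  estimates biased. Pyrimidine-richness is preserved either way.
* Crosslink positions are *all* Ts inside a footprint. Real crosslink
  geometry within a binding site is not characterized in the source
  analyses; treating every footprint U as crosslinkable maximizes the
  testability of conversion counting. A corollary: a footprint whose
  25 nt happen to contain no T (about 7% of GA-rich footprints at their
  10% T composition) can never produce a conversion read and is invisible
  to the caller *by construction of PAR-CLIP itself*; this bounds
  attainable sensitivity at roughly 93% under the defaults, which is why
  the recovery tests ask for ≥90% rather than ~100%.

What the generator does **not** emulate: fragment-length distributions,
PCR duplicates, quality scores, isoforms, paired conditions sharing one
crosslink landscape, or genuinely unbound transcripts — every transcript
carries some footprint, so "gene is bound" is uninformative in the
synthetic universe. Consequently the enrichment and TE analyses in the
drivers condition on the *selective* signal, genes with 5'UTR sites (RP
and TR_other by construction), and passing tests show the machinery
computes the right quantities on known truth, not that real libraries
would behave this way.

# Statistics

Composition comparisons use Welch's two-tailed t-test (closed-form t,
Welch–Satterthwaite df), implemented in the package and checked against the
reference implementation to 10^-10 in tests. Bound-vs-unbound comparisons
are unpaired and per transcript: within the scoped region the union of site
spans gives one bound composition value and the remainder one unbound value
(pyrimidine fraction for 5'UTRs, G fraction for 3'UTRs); transcripts whose
region is entirely bound contribute no unbound value. Under a null with no
planted composition difference the test's rejection rate at alpha = 0.05 is
verified to sit inside the binomial 95% CI around 0.05 over 1,000 simulated
datasets.

GO enrichment is the classic per-term one-sided Fisher exact test
(hypergeometric upper tail) over a background of expressed genes, Bonferroni
correction across terms tested, significance at adjusted p < 0.001. Graph
decorrelation (elim-style) is out of scope; annotation propagation up
parent links is applied when a parent table is supplied. A packaged mapping
groups terms into super-categories; a gene is translation-related iff
annotated to at least one translation-super-category term. TE fold changes
are classed down/unchanged/up at 1.5-fold in either direction.

Motif discovery is deliberately replaced by two transparent summaries on
±15 nt-extended site sequences: the longest pyrimidine run (with the
fraction of sites reaching ≥6, mirroring the six-consecutive-pyrimidine
consensus) and a hexamer count against base-shuffled backgrounds. The 5'TOP
operational definition — first base C, then ≥4 pyrimidines — is this
package's own (none is standardized), configurable via `min_run`.

# Numerical and degenerate-input choices

* Region assignment: a site belongs to the region holding the largest share
  of its span; exact ties break UTR5 > CDS > UTR3.
* Metagene: the whole transcript is rescaled to [0,1] (regions are not
  rescaled separately); junction marks are category means of fractional
  boundaries; site mass spreads over bins proportionally to overlap, so bin
  mass equals assigned coverage exactly.
* Sites on transcripts with zero or missing RPKM keep `norm_score = NA`
  (logged) rather than being dropped; coverage tables fall back to RPM when
  any norm_score is undefined.
* Zero variance in both Welch groups with equal means returns p = 1 by
  convention (logged); with unequal means it is an error.
* Empty inputs (no reads, empty truth, zero-site categories) produce empty
  outputs with valid headers, not errors.
* All simulators are deterministic given the spec seed; the pipeline
  manifest records md5 checksums, and a re-run with the same config is
  byte-identical.

# Problem sizes

The shipped analyses and tests run at 300 transcripts, ~25k PAR-CLIP
placements and 5×10^5-read mRNA-seq replicates per condition — sizes chosen
so the whole suite exercises every stage, including two full pipeline runs,
in minutes on one CPU. The statistical calibration uses 1,000 null datasets
of 30 transcripts. Oracle-equivalence tests enumerate all hypergeometric
tables with background ≤ 50 exactly and sample 2,000 larger ones.

# Worked example

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 7)
tx <- generate_transcriptome(spec)
reads <- distribute_multimappers(
  annotate_mismatches(simulate_parclip(tx, "mTOR_off"), tx$sequences))
expr <- expression_table(simulate_mrnaseq(tx), tx$regions)
sites <- call_sites(reads, tx, expression = expr, condition = "mTOR_off")
region_coverage_table(sites, tx$regions)
```

The numbered scripts under `analysis/` run the same stages as a narrative:
simulation, expression, site calling (with truth benchmarking), region and
metagene profiling, sequence statistics, and enrichment.

# Known limitations

* The placer is an exhaustive scanner for desk-scale inputs, not an indexed
  aligner; real libraries should arrive pre-aligned as SAM.
* Single isoform per gene; genome-space (exon-aware) analyses are out of
  scope.
* Site boundaries are smoothing-derived, not crosslink-nucleotide-resolution
  (no kernel-density classification of conversion positions).
* The synthetic universe plants binding on every transcript (see above);
  absolute percentages such as a "0% to 17%" RP 5'UTR shift depend on the
  real data's site set and are not reproduced here — only the directional
  pattern is a property of the artifact.
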