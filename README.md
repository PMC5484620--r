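# larpclip

An R package for inferring RNA-binding-protein binding sites from PAR-CLIP
sequencing in transcript space, and for the downstream analyses that
characterize where and what the protein binds. It was built around the
biology of LARP1 — a protein that contacts the 3'UTRs of ribosomal-protein
(RP) mRNAs under growth conditions and relocates to pyrimidine-enriched
sequences (PES) at the 3'-end of their 5'UTRs when mTORC1 is inhibited —
and ships a fully seeded synthetic-data generator so every stage runs and
is tested with no external downloads. It is aimed at computational
biologists who want an auditable, parameter-explicit reimplementation of
this class of CLIP analysis.

## The method

PAR-CLIP reads carry T-to-C conversions at crosslinked uridines. Given
transcriptome-space alignments (SAM), the caller:

1. recovers mismatches by comparing read sequence to the reference and
   discards reads with more than 2 T-to-C conversions;
2. distributes each multimapping read evenly across its k placements
   (weight 1/k);
3. clusters reads per transcript by ≥1-nt overlap (half-open intervals),
   smooths each cluster's weighted coverage with a truncated Gaussian
   (σ = 5 nt) and trims to the contiguous region above a floor;
4. keeps clusters with ≥1 conversion-bearing read and RPM ≥ threshold as
   binding sites, scored by

   RPM = Σ member weights / (mapped reads / 10⁶),
   norm_score = RPM / gene RPKM × 1000,

   with RPKM from replicate mRNA-seq (replicate-averaged).

Downstream: sites are assigned to 5'UTR/CDS/3'UTR by largest overlap
share; binding is summed per gene category (RP / other
translation-related / non-TR) and profiled along normalized transcript
length; bound-vs-unbound sequence composition is compared with Welch's
two-tailed t-test (pyrimidine content on 5'UTRs, G content on 3'UTRs);
pyrimidine-run and hexamer summaries stand in for motif discovery; 5'TOP
starts are classified and intersected with sites; and bound genes are
tested for GO-term enrichment (one-sided Fisher exact, Bonferroni,
p_adj < 0.001) with translation super-category grouping, plus a
cross-tabulation against translation-efficiency fold-change classes
(1.5-fold cut-offs).

## Worked example

```r
library(larpclip)

spec  <- simulation_spec(seed = 7)            # 300 transcripts, 20% RP
tx    <- generate_transcriptome(spec)
reads <- distribute_multimappers(
  annotate_mismatches(simulate_parclip(tx, "mTOR_off"), tx$sequences))
expr  <- expression_table(simulate_mrnaseq(tx), tx$regions)
sites <- call_sites(reads, tx, expression = expr, condition = "mTOR_off")
table(sites$region)
#>  CDS UTR3 UTR5
#>  162  282  116
```

The 5'UTR sites appear only under mTOR inhibition and sit on pyrimidine
tracts: running the numbered drivers (`Rscript analysis/01_simulate.R`
through `analysis/06_enrichment.R`, tables land in `results/`) prints,
among others:

```
mTOR_off: 560 sites (CDS=162, UTR3=282, UTR5=116); sensitivity 93.3%,
          precision 100.0% vs 600 active footprints
RP       mTOR_on   5'UTR share:   0.0%
RP       mTOR_off  5'UTR share:  54.0%
non_TR   mTOR_off  5'UTR share:   0.0%
mTOR_off replicate RPKM r = 0.99955 (R^2 = 0.99910)
mTOR_off.utr5_pyrimidine_welch_p   4.48e-80
mTOR_off.utr5_run6_fraction        1
mTOR_off.utr5_top_overlap_fraction 0
top term: translation (translation), p_adj = 7.31e-78
```

Read: ribosomal-protein 5'UTR binding goes from absent (mTOR on) to ~54%
of RP binding (mTOR off, matching the planted occupancy share of 54.5%);
the called 5'UTR sites are strongly pyrimidine-enriched relative to the
rest of the same 5'UTRs, all contain a ≥6-pyrimidine run, and none overlap
the 5'TOP at the cap — binding sits at the 3'-end PES instead; genes with
5'UTR sites are overwhelmingly translation-related.

The sensitivity ceiling is structural, not a bug: a planted footprint that
happens to contain no uridine cannot produce a T-to-C conversion and is
invisible to PAR-CLIP by construction (~7% of GA-rich footprints at
default compositions).

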