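# anchormap

Linkage mapping and draft-genome anchoring for outbred F1
(pseudo-testcross) crosses, built around the design used to anchor the
rubber tree (*Hevea brasiliensis*) draft genome: two heterozygous parents,
~149 offspring genotyped by targeted capture sequencing, a fragmented
contig/scaffold assembly, and a legacy microsatellite map.

The package provides, end to end:

* **Genotype QC** — the capture-genotyping filter cascade: calls with depth
  < 20 or failing an exact binomial allele-balance test are replaced with
  no-calls; markers with < 80% of samples called, parental no-calls,
  Mendelian-impossible offspring, or distorted segregation
  (χ² p < 1e-5 against the type's 1:1, 1:2:1 or 1:1:1:1 ratio) are dropped,
  with per-stage accounting.
* **Two-point linkage** — for each marker pair, the recombination fraction
  r̂ ∈ [0, 0.5] and LOD = log₁₀ L(r̂)/L(0.5), maximised by EM over
  unobserved transmissions jointly with the ≤ 4 parental phase
  configurations. All pairs are fitted simultaneously via sufficient-
  statistic cross-tabulations whose category probabilities are degree-≤2
  polynomials in r.
* **Map construction** — single-linkage grouping at LOD thresholds 8–18,
  threshold selection by chromosome number (n = 18) with reference-map
  agreement as tie-break, collapse of co-segregating SNPs into
  non-redundant positions (bins), and bin ordering/positioning with Haldane
  distances d = −50·ln(1 − 2r) cM.
* **Anchoring** — majority-rule contig placement with repeat flags
  (within-contig SNP span > 10 cM, multi-group contigs), scaffold
  concordance (gaps ≥ 20 cM, scaffolds split across groups), group
  renumbering against a reference map, and integration of scaffolds
  anchored only by microsatellites.
* **Primer placement** — the blast-hit rules that anchor legacy
  microsatellite markers: 3'-end inclusion + 80% coverage per primer,
  unique convergent product ≤ 500 bp on one contig, or 100% identity over
  ≥ 70% within 300 bp of contig ends across two contigs.
* **A synthetic cross generator** — mixed segregation types, depth-sampled
  allele counts, genotyping error, missingness, distorted loci and
  repeat-duplicated contigs, with a full truth registry, so every stage is
  testable without external data.

## Worked example

```r
library(anchormap)

cfg <- sim_config(seed = 1)                 # 18 chromosomes, 149 offspring
truth <- simulate_cross(cfg)
obs <- sample_observed_calls(truth, cfg)

qc <- run_qc_cascade(obs$calls)
print(qc)
#> Genotype QC cascade
#>               stage n_in n_out calls_replaced
#>    call_replacement  900   900           4621
#>           call_rate  900   900              0
#>  parental_mendelian  900   707              0
#>         segregation  707   692              0

map <- build_linkage_map(qc$markers, lod_thresholds = 8:18,
                         reference = truth$reference_map, target_n = 18)
print(map)
#> Linkage map: 692 SNPs in 18 groups (LOD threshold 8), 0 unplaced
#>   total length 2115.4 cM, 648 non-redundant positions

anch <- anchor_map(map, truth$scaffolds, truth$reference_map)
summary(map)          # per-group SNPs, bins, lengths, totals row
plot(map)             # simple per-group ideogram
```

The QC report reads as: 4,621 calls replaced with no-calls (4,567 for low
depth at the default negative-binomial depth regime, 54 for allele
imbalance), no marker below the 80% call rate, 193 markers lost to the
parental/Mendelian checks (parental no-calls dominate) and 15 to the
segregation test — the generator plants distorted loci on purpose. The
fitted map recovers
the 18 simulated chromosomes; `anch$report` lists the discordant contigs
and scaffolds, which on synthetic data flag the planted repeat-duplicated
contigs. (Numbers shown are for `seed = 1`; other seeds differ slightly.)

Real data enters the same way through the readers:
`read_vcf()`, `read_scaffold_map()`, `read_reference_map()`,
`read_blast_tab()`, `read_gene_models()`. RNA-seq variant work uses
`filter_rnaseq_sites()` (quality ≥ 40, combined depth ≥ 60),
`classify_variant()`/`summarize_variants()` (SNP / insertion / deletion /
complex, transitions vs transversions), `merge_gene_sets()`
(intersect/union of two annotation pipelines) and `variants_in_genes()`
(1 kb-flank overlap).

`run_pipeline(cfg, out_dir)` drives simulate → QC → map → anchor → primer
placement and writes the per-stage tables plus a run manifest echoing every
threshold and the seed; identical configurations give identical outputs.

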