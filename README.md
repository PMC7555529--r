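# molekaryo

Molecular karyotyping and parent-of-origin analysis of androgenetic
complete hydatidiform moles (CHMs) from duo SNP-array data.

## The problem

Almost all CHMs are androgenetic and diploid — monospermic (one
endoduplicated sperm, fully homozygous) or dispermic (two sperm,
segmentally heterozygous). Dispermic moles carry extra chromosomes
surprisingly often, and the extra homolog may be paternal *or* maternal;
some disomic chromosomes even turn out to be biparental (one maternal +
one paternal homolog) inside an otherwise androgenetic genome. Retained
maternal material is a candidate stratifier of gestational trophoblastic
neoplasia (GTN) risk, so a mole work-up wants, per chromosome: the copy
number, and the parental origin of every homolog — from nothing more than
the mole's villous DNA and the patient's blood.

`molekaryo` is aimed at researchers analysing mole/maternal duos typed on
SNP arrays (GenomeStudio-final-report-like exports) and at methodologists
who need a fully seeded simulator of molar genomes to validate such
pipelines.

## The method

At a locus covered by *n* homologs with *k* B alleles, the ideal B-allele
frequency (BAF) is *k/n* and the ideal log R ratio (LRR) is
*a* log2(*n*/2). Copy number is called per chromosome from the BAF band
pattern ({0,½,1} disomy; {0,⅓,⅔,1} trisomy) arbitrated by the median LRR
shift. Parental origin uses the **selected BAF**: restrict the mole's BAF
to loci where the mother is AA. A maternal homolog then contributes an A
allele at every selected locus, capping BAF at (*n*−1)/*n* — the BAF ≈ 1
band vanishes structurally. The retention statistic

    R = observed fraction of selected loci with BAF ≥ 0.85
        ───────────────────────────────────────────────────
        expected fraction under the all-paternal hypothesis

collapses to 0 when a maternal homolog is present and stays near or above
1 otherwise; *R* < 0.25 calls maternal contribution (maternal extra on a
trisomy, biparental disomy on a disomy). STR profiles are classified with
forensic allele-sharing rules, mitochondrial identity guards against
sample swaps, and cohort-level counts are tested with an exact Fisher
test.

## Worked example

Simulate a dispermic mole with a maternal trisomy 13 and analyse the duo:

```r
library(molekaryo)

panel <- default_locus_panel()           # 21,108 loci incl. 208 MT
spec <- constitution_spec("dispermic_CHM", sex = "XY",
                          extra_chromosomes = c(`13` = "maternal"),
                          id = "DEMO", outcome = "SR")
duo <- simulate_cohort(list(spec), panel = panel, seed = 42)[[1]]

classify_conceptus(duo$mole_str, duo$mother_str)
#> Conceptus class: androgenetic_dispermic
#>   loci: 15 | unshared with mother: 10 | two-allelic: 6

kary <- estimate_karyotype(duo$mole)
kary
#> Estimated karyotype: 47,XY,+13

call_origin(duo$mole, duo$mother, kary$calls[["13"]], panel)
#> chr 13 (copy 3): maternal contribution [retention 0.000 = 0.0000 / 0.0597, n=241]
```

The STR profile has ten loci sharing nothing with the mother (hence
androgenetic) and six two-allele loci (hence dispermic). Chromosome 13
shows the four-line BAF pattern and a right-shifted LRR (copy 3), and
among its 241 maternal-AA selected loci the observed BAF ≥ 0.85 fraction
is 0.0000 against an all-paternal expectation of 0.0597 — the top band is
lost, so the extra chromosome 13 is maternal.

`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) chains
simulate → STR classify → karyotype → origin → report for a whole cohort
and writes final-report TSVs, STR CSVs, per-case JSON calls and a cohort
report. The shipped `chm31_cohort()` table encodes the 31-case reference
cohort of dispermic CHMs (22 euploid; 8 autosomal trisomies including one
double; one 47,XYY; 3 biparental disomies; 7 GTN outcomes).

And the cohort-level exact test:

```r
fisher_exact(matrix(c(29, 6, 175, 22), 2, 2))
#> [1] 0.3950791
```

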