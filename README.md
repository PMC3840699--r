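# trflptools

Community-fingerprint analysis of deep-ocean prokaryotic communities by
T-RFLP (terminal restriction fragment length polymorphism), built as a
tested, reusable R pipeline. It targets the question asked of deep
water-mass microbiology: do the bacterial and archaeal communities carried
by a deep water mass change *along its flow path* — i.e. is there
succession inside the water mass — and are communities structured by the
water masses' physical and chemical envelopes?

The package provides:

- **in-silico T-RFLP**: primer matching on 16S templates, prediction of the
  labelled terminal fragment from the first restriction cut (HhaI `GCGC`,
  cut `GCG^C`) on each strand, peak-profile construction and
  binning/standardization into a samples × T-RF fingerprint matrix;
- **OTU and alpha diversity**: p-distance OTU clustering at a 2% cutoff
  (average linkage, inclusive), Shannon H′ = −Σ pᵢ ln pᵢ, Margalef
  SR = (S−1)/ln N, bias-corrected Chao1 = S + n₁(n₁−1)/(2(n₂+1)), and
  analytic (hypergeometric) rarefaction;
- **community structure**: Bray–Curtis percent similarity
  S = 100(1 − Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)), UPGMA clustering with deterministic
  tie-breaks, normalized Euclidean environmental distances, and a
  RELATE-style Mantel test (Spearman rank correlation of resemblance
  matrices with a label-permutation null);
- **succession**: similarity of every station to a reference station within
  one water mass, regressed on along-path distance (distance decay), with a
  station-bootstrap test of H₀: slope = 0 (stations are resampled as whole
  units because all points share the reference sample) and an ANCOVA
  homogeneity-of-slopes comparison against a permutation null;
- **a synthetic transect generator** supplying ground truth for everything
  above: 18 transect + 9 off-path stations, seven to eight depth layers
  drawn inside water-mass environmental envelopes, an OTU pool of 116
  (bacteria) with 18% ubiquitous and 22% group-unique members, and a
  controlled along-path turnover confined to the NADW layers.

## Worked example

```r
library(trflptools)

sc  <- generate_scenario(scenario_config(seed = 1))
fp  <- scenario_fingerprint(sc)   # digest -> peaks -> binned fingerprint
inc <- incidence_summary(fp, setNames(sc$metadata$group,
                                      sc$metadata$sample_id))
inc
#> 116 OTUs detected; 21 (18%) in all groups; 26 (22%) in one group;
#> 40 (34%) high-prevalence

res <- run_succession_analysis(bray_curtis_matrix(fp), sc$metadata,
                               water_masses = c("AAIW", "NADW", "AABW"),
                               n_boot = 10000, n_null = 1000, seed = 1)
res[res$region == "transect", ]
#>   water_mass   region  n     slope       r2    ci_low  ci_high p_bootstrap
#> 1       AAIW transect 17  1.52e-03 0.360880  0.000291  0.00297      0.0084
#> 3       NADW transect 17 -2.61e-02 0.992380 -0.027615 -0.02465      0.0002
#> 5       AABW transect 17 -6.42e-05 0.000828 -0.001436  0.00127      0.9693
```

Reading the table: the NADW community decays in similarity by about
0.026 percentage points per km along the 2000-km path (the generator's
turnover was 3×10⁻⁴ per km, i.e. an expected slope of −0.03%/km before
noise), with R² ≈ 0.99 and a bootstrap p of 2×10⁻⁴ — succession detected
exactly where the generator put it. The AABW analogue is flat. The small
positive AAIW slope is a single-scenario noise fluctuation (any null layer
rejects at roughly the nominal 5% rate; the acceptance suite verifies this
level over 500 replicate scenarios).

Clone-library diversity from one sample (165 clones, as for a typical
library):

```r
counts <- sample_clone_library(as_sample_matrix(sc)["St09_mNADW", ],
                               165, seed = 1)
diversity_summary(counts)
#> S_obs = 56, N = 165, H' = 3.6578, SR = 10.7718, Chao1 = 72.8667
```

## Command line

```sh
Rscript -e 'trflptools::trflp_cli()' -- run --config config.json --out run1
Rscript -e 'trflptools::trflp_cli()' -- digest --fasta otus.fasta \
    --enzyme-site GCGC --cut-offset 3 --out trf.csv
Rscript -e 'trflptools::trflp_cli()' -- succession --fingerprints fp.csv \
    --metadata meta.csv --water-mass NADW --reference St01 \
    --n-boot 10000 --seed 7 --out succession.csv
```

Subcommands: `simulate, digest, fingerprint, otu, diversity, rarefy,
incidence, resemble, cluster, relate, succession, run`.

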