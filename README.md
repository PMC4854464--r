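# enzgrad

Site-specific evolutionary rates in enzymes do not just drop *at* the
catalytic residues — they rise approximately linearly with the
three-dimensional distance to the nearest catalytic residue, over and
above what packing density and solvent exposure explain. `enzgrad` is an
R package for structural bioinformaticians and molecular evolutionists
who want to quantify, decompose, and invert these conservation
gradients in their own structures.

Given a PDB structure (biological assembly or single chain), a
catalytic-residue annotation, and per-site evolutionary rates (Rate4Site
output or a plain two-column table), the package computes per residue:

- **WCN**, the side-chain weighted contact number
  `WCN_i = Σ_{j≠i} 1/r_ij²` (packing density);
- **RSA**, Shrake–Rupley accessible surface area normalized by
  Gly-X-Gly maxima (solvent exposure), with subunit-interface and
  cross-chain-linkage handling;
- **d**, the distance to the nearest catalytic residue, and its 5 Å
  **shell** (shell 0 holds the catalytic residues; 27.5 Å is the outer
  edge of shell 5);

then fits the per-protein linear models `K ~ d`, `K ~ RSA`, `K ~ WCN`,
`K ~ RSA + d`, `K ~ WCN + d`, `K ~ WCN + RSA`, `K ~ WCN + RSA + d`,
summarizes rates by shell, and runs the **optimized-distance scan**:
each residue is tried as a reference, rate is regressed on
distance-to-reference, and the maximal-R² reference is proposed as the
putative active site, with the max-WCN residue as the structural
control and Fisher exact / ROC-AUC comparison between the two.

A synthetic-enzyme generator (packed residue clouds, a planted
catalytic site, rates with known linear composition) makes the entire
pipeline testable with ground truth and no downloads.

## Worked example

```r
library(enzgrad)

cfg <- synthetic_config(n_sites = 200, seed = 42)
sim <- simulate_enzyme(cfg)          # structure + planted site + rates

shell_summary(sim$table)[, c("shell", "count", "mean_K")]
#>   shell count mean_K
#> 1     0     3  0.419
#> 2     1    26  0.540
#> 3     2    47  0.727
#> 4     3    50  0.903
#> 5     4    45  1.294
#> 6     5    25  1.572
#> 7     6     4  1.951
```

Mean relative rate climbs monotonically from 0.42 in shell 0 (the
catalytic residues and their immediate overlaps are the most conserved
sites) to ~2 six shells (~30 Å) out: the planted conservation gradient,
recovered by the shell stratification.

```r
fit_rate_model(sim$table, "K ~ wcn + rsa")$r_squared      # 0.154
fit_rate_model(sim$table, "K ~ wcn + rsa + d")$r_squared  # 0.533
```

Structure alone explains 15% of rate variation here; adding distance to
the catalytic site raises that to 53% — the functional gradient is not
reducible to packing or exposure.

```r
scan <- optimized_distance_scan(residue_centers(sim$structure), sim$table$K)
scan$best            # residue 98 proposed as the active site
scan$best_r_squared  # 0.444
distance_to_catalytic(residue_centers(sim$structure),
                      sim$annotation$index)[scan$best]
#> 7.75  (one shell away from a true planted catalytic residue)
```

For real data, replace the simulation with:

```r
s   <- parse_structure(file = "1dhf.pdb1")              # biological assembly
ann <- load_catalytic_annotation(read.csv("cat.csv"), s) # chain,residue_number
raw <- parse_rates(readLines("1dhf.r4s"), "rate4site")
tab <- build_site_table(s, ann, raw)
```

Dataset-level aggregates (pooled fraction within 27.5 Å, mean R² per
model, mean catalytic/interface rates, active-site-location counts) are
recomputed from a deposited per-residue table with
`reproduce_from_table(path)`; a small synthetic table in that schema
ships in `inst/extdata/` for demonstration.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/enzgrad.R simulate --n 5 --seed 1 --out results/
Rscript inst/cli/enzgrad.R reproduce --table sites.tsv --out results/
```

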