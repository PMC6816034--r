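# netentropy

Per-patient Shannon entropy of up-regulated protein–protein interaction
subnetworks, and the number of hub targets whose inactivation would bring a
tumor's network complexity down to the level associated with full five-year
survival.

## The scientific problem

Tumors from different patients rarely share one molecular profile, so
therapies aimed at a common target are imprecise. One personalized
alternative reads each patient's tumor through the lens of network
complexity:

1. **Call up-regulated genes per patient.** With paired tumor and control
   RNA-seq samples from the same patient, compute the differential
   expression `d_g = tumor_g − control_g` for every gene, bin the values
   into a frequency histogram, transform the relative frequencies with
   `y' = log10(y + 1)`, and fit a Gaussian `A·exp(−(x−μ)²/2σ²)` to the
   transformed bulk. Genes above the one-tail cut `μ + σ·z(1−α)` (α = 0.05)
   are called up-regulated — they carry bulk tail mass ≤ α.
2. **Induce the PPI subnetwork.** Map called genes to protein accessions
   and keep every interactome edge with both endpoints in the set; proteins
   with no partner inside the set are excluded.
3. **Measure complexity.** With `p(k)` the fraction of subnetwork nodes of
   degree `k`, the Shannon entropy is

   ```
   H = − Σ_k p(k) · log2 p(k)        (bits)
   ```

   H depends only on proportions, never on subnetwork size, so differently
   sized patient subnetworks are comparable.
4. **Hubs matter.** Removing the top-degree hubs from a patient subnetwork
   lowers H more than removing the same number of nodes at random; the
   package quantifies this with a 1,000-replicate random-removal empirical
   null and a one-sided add-one p-value.
5. **Entropy tracks prognosis.** Cohort mean entropy regressed on the
   Kaplan–Meier five-year survival rate (from OS/OS.time clinical records)
   gives a negative slope: more complex subnetworks, worse survival.
   Evaluating the fitted line at 100% survival yields a per-study entropy
   goal, and each patient's prescription is the smallest number n ≤ 20 of
   top-ranked hubs whose cumulative removal drives H to or below that goal.

Everything is reproducible offline: a seeded generator emits a scale-free
interactome, paired expression cohorts with planted up-regulation, and
censored survival records whose five-year rates genuinely decrease with
measured subnetwork entropy — written in the same file formats the readers
parse.

## Worked example

```r
library(netentropy)

spec  <- synthetic_spec(seed = 42, n_proteins = 800, n_genes = 800,
                        n_patients_per_cohort = 10, n_cohorts = 4)
paths <- write_synthetic_dataset(spec, file.path(tempdir(), "demo"))

expr <- read_expression_table(paths[["expression"]])
map  <- read_id_mapping(paths[["mapping"]])
ppi  <- read_interactome_mitab(paths[["interactome"]])
clin <- read_clinical_table(paths[["clinical"]])

cfg <- run_config(seed = 42, null_reps = 1000)
rep <- run_cohort(cfg, expr, paths[["sheet"]], map, ppi, clin)
rep
#> <cohort_report> 40 patients in 4 cohort(s)
#> <group_comparison> Kruskal-Wallis chi-squared = 31.796, df = 3, p = 5.78e-07; pairwise holm-corrected
#> <entropy_regression> Y = -0.01429 X + 2.446  (r = -0.538, p = 0.462, n = 4)
#>   entropy goal (100% survival): 1.0176 bits
#>   note: cohort(s) below 30 paired patients: C01, C02, C03, C04

rep$cohorts
#> # A tibble: 4 x 6
#>   cohort n_patients mean_entropy sd_entropy five_year_survival below_min
#>   <chr>       <int>        <dbl>      <dbl>              <dbl> <lgl>
#> 1 C01            10        0.953      0.397               90   TRUE
#> 2 C02            10        1.19       0.181               70   TRUE
#> 3 C03            10        1.65       0.194               44.4 TRUE
#> 4 C04            10        2.07       0.117               70   TRUE

head(rep$patients[c("patient_id", "n_upregulated", "n_nodes",
                    "entropy", "empirical_p", "n_targets")], 5)
#> # A tibble: 5 x 6
#>   patient_id n_upregulated n_nodes entropy empirical_p n_targets
#>   <chr>              <int>   <dbl>   <dbl>       <dbl>     <int>
#> 1 C01-P001              77      25   1.38      0.00200         1
#> 2 C01-P002              91      38   1.30      0.00599         3
#> 3 C01-P003              64      12   0.414     0.444           0
#> 4 C01-P004              75      19   0.297     0.598           0
#> 5 C01-P005              65      22   0.845     0.0200          0

rep$plans[["C03-P002"]]
#> <target_plan> C03-P002: baseline H = 1.7059, goal = 1.0176, targets required = 7
```

Reading the output: each row of `rep$patients` is one patient — how many
genes cleared the one-tail threshold, the induced subnetwork size, its
entropy in bits, the empirical p of hub removal against the random-removal
null (small p = hubs dominate that patient's complexity), and the number of
top hubs to remove to reach the cohort-level entropy goal (`0` = the tumor
is already below the 100%-survival entropy). The Kruskal–Wallis test asks
whether cancer types share one entropy level; the regression line links
cohort entropy to five-year survival and sets the goal. At this demo scale
(4 cohorts of 10) the regression has only 4 points, hence the wide p; every
cohort is flagged below the 30-patient mark that a serious run would
require.

Result objects ship `tidy()`, `glance()` and `autoplot()` methods:
`autoplot(rep$reports[["C01-P001"]]$null)` draws the null histogram with
the hub-removal arrow, `autoplot(rep$regression)` the entropy–survival
scatter with the fitted line, and `autoplot(rep$plans[["C03-P002"]])` the
cumulative removal trajectory against the goal.

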