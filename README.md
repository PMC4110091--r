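# linrob — robustness of determinative cell lineages to cell death

In determinative (mosaic) development, cell fates are fixed: when a cell
dies, its entire subtree of descendants is lost and nothing regrows. The
developmental cell lineage — a rooted binary tree from the zygote to the
typed terminal cells — can therefore be organized well or badly against
such accidents. `linrob` is an R package for quantifying that
organization. It is written for developmental and evolutionary biologists
working with complete cell lineages (nematodes, ascidians and other
invertebrates with determinative development) and for anyone studying
tree-shape null models.

## The model

Terminal cells are classified into functional types. With `T` included
types (apoptotic cells excluded), `N_i` cells of type `i`, `n_i`
survivors of a perturbation and importance exponents `a_i >= 1`, the
robustness index is

    f = prod_i (n_i / N_i)^(a_i)   in [0, 1].

Two perturbation models are evaluated on f:

* **f_n** — robustness to necrosis: the mean f over the single removal of
  every non-root cell (one accidental death per lineage, deterministic).
* **f_p** — robustness to division-program failure: the division program
  of an internal cell is the unordered pair of its daughters' fates,
  defined recursively; all internal cells sharing a failed program arrest
  together. `b ~ Binomial(N_program, p)` programs fail per Monte Carlo
  replicate, with `p = 1/N_internal` so the expected number of arrested
  internal cells is exactly one.

Observed values are compared against eight constrained randomizations of
the same terminal cells (random coalescence; fixed maximum depth;
bootstrap or exact depth multisets; relabeling — free, within depths, or
twin-preserving; and a clonality gradient), giving empirical P-values and
Z-scores. Feature statistics (clonality `C`, the rare-early depth–type-size
correlation, twin counts, physical-vs-lineal distance correlation), a
transcriptome-based reclassification pipeline, and a macroevolution
simulator with truncation selection on robustness and/or simplicity
complete the framework. Real lineage trees are not bundled; the package
ships the published per-type censuses plus generators that synthesize
census-exact lineages, expression matrices and 3D coordinates with
plantable structure.

## Worked example

```r
library(linrob)

toys <- toy_lineages()
tl1 <- toys$TL1$lineage   # ((A1,A2),(B1,B2)); — types clustered
tl2 <- toys$TL2$lineage   # ((A1,B1),(A2,B2)); — types interleaved

necrosis_robustness(tl1)
#> [1] 0.3333333
necrosis_robustness(tl2)
#> [1] 0.4166667
```

Same tree shape, same census — but the interleaved lineage is more
robust: an internal-cell death there halves two types instead of
extinguishing one (any included type at zero drives f to 0). Program
failure agrees, exactly and by Monte Carlo:

```r
exact_program_failure_expectation(tl1, robustness_spec(p = 1/3))
#> [1] 0.2962963
fp <- program_failure_robustness(tl1, robustness_spec(p = 1/3),
                                 replicates = 50000, seed = 1)
round(c(fp, attr(fp, "se")), 4)
#> [1] 0.2959 0.0020
```

A full analysis on a synthetic lineage drawn under the 671-cell
embryonic *C. elegans* census:

```r
cen <- builtin_census("celegans_embryonic")
sum(cen$counts); cen$T_included
#> [1] 671
#> [1] 8
lin <- synth_lineage(cen, rare_early = 0.6, twin_enrichment = 2, seed = 1)
res <- run_analysis(lineage = lin,
                    spec = robustness_spec(excluded = cen$excluded),
                    nulls = list(list(statistic = "f_n",
                                      mode = "coalescent", n = 200)),
                    seed = 1)
res$report[c("f_n", "f_p", "max_depth", "clonality", "rho_rare_early")]
#>         f_n       f_p max_depth clonality rho_rare_early
#> 1 0.9532506 0.9201515        19  1.552772      0.5256168
res$null_tests[c("statistic", "P", "Z")]
#>   statistic P       Z
#> 1       f_n 0 4.10679
```

The synthetic lineage is far more robust than its random coalescent
rewirings (Z ≈ 4.1, empirical P = 0 over 200 nulls) because rare types
were planted shallow and twins enriched — the same features that make the
real lineages robust. `vignettes/lineage-robustness.Rmd` walks through
the model, the null constraints and every design decision.

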