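# icountr

Counting cell divisions from fluorescent tag-dilution reporters.

## The problem

Recombination-induced tag exchange (RITE) division counters — the
iCOUNT/miCOUNT family — tag a stable, replication-replenished protein
(histone H3.1, nucleoporin NUP155) with an old "red" fluorophore that an
induced recombination swaps for a new "green" one.  Every subsequent
division halves the cell's red pool and refills it with green, so a single
cell's green-to-total fluorescence fraction records how many times it has
divided since induction — in culture, organoids, or intact tissue.  A
second, Flp-dependent switch (green to blue) extends counting over two
epochs.

This package is for people analysing such data (or building analysis
methods on it): it provides the dilution mathematics, the per-cell
normalization pipelines used for fixed tissue and live imaging, division
inference with accuracy evaluation, and a branching-lineage simulator that
generates ground-truth datasets with configurable noise.

## The model

With `C` the baseline old-to-new reporter intensity ratio (`C = 1` for
equally bright reporters), the green fraction after `n` completed divisions
and its inverse are

    R(n) = (2^n - 1) / (C + 2^n - 1)
    n(R) = log2(1 + C * R / (1 - R))      # = -ln(1 - R)/ln 2 at C = 1

giving class boundaries at R = 50%, 75%, 87.5%, 93.75% for the five
division classes 0-1, 1-2, 2-3, 3-4, 4+.  The methods vignette
(`vignettes/division-counting.Rmd`) derives the model, states every
assumption and numerical convention, and documents what the simulator does
and does not emulate.

## Worked example

Simulate a recombined tissue, measure it with noise, normalize, infer
division classes, and score against ground truth:

```r
library(icountr)

round(100 * green_fraction_after_divisions(0:4), 2)
#> [1]  0.00 50.00 75.00 87.50 93.75

cfg <- simulation_config(n_founders = 40, horizon = 75, exit_prob = 0.2,
                         recombined_fraction = 0.9, seed = 7)
tree <- simulate_lineages(cfg)
m    <- apply_measurement_noise(tree,
          measurement_noise(multiplicative_cv = 0.05,
                            background_mean = 40, background_sd = 8),
          seed = 8)
norm <- normalize_fixed(m)                      # fixed-tissue pipeline
cls  <- classify_dataset(norm[!norm$red_only, ])
cls$histograms$all
#> Division-class histogram [all] (n = 721)
#>                0-1     1-2      2-3      3-4      4+
#> count      61.0000 52.0000 101.0000 171.0000 336.000
#> proportion  0.0846  0.0721   0.1401   0.2372   0.466

evaluate_accuracy(cls$cells, ground_truth(tree))
#> Accuracy: 678 / 721 events correct (94.0%)
```

The histogram is the per-class division-count distribution of the 721
recombined cells (non-recombined red-only cells serve as normalization
references and are excluded).  With 5% multiplicative noise the class
assignment is correct for 94% of cells; errors concentrate in the deeper
classes, whose bins narrow geometrically in R.  In the noiseless setting
the chain recovers every class exactly — see
`tests/testthat/test-acceptance.R`.

There is also a CLI:

```sh
Rscript -e 'icountr::icount_main()' run \
  --config inst/extdata/demo-config.json --out demo_out
```

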