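# Optional replication on the curated TChard binding data

Everything in this package's test suite runs on synthetic data generated in
code. Reproducing the real-data results additionally requires the TChard
dataset — positive TCR:epitope binding observations curated for human MHC
class I from IEDB, VDJdb and McPAS-TCR, and experimentally validated
non-binders from IEDB and 10X Genomics assays (about 107k positive and 147k
negative records). That download is deliberately **not** part of the build
or of any test: it is large, external, and subject to upstream revisions.
The workflow below is provided for users who want to run it themselves; on
a single CPU the SVM fit on ~200k records takes hours.

## 1. Obtain the data

Download the TChard dataset (see the TChard repository / Zenodo deposit)
and export a single table with one row per observation and columns for the
CDR3beta sequence, the epitope sequence and the binary label
(1 = binds, 0 = validated non-binder), e.g. `tchard.tsv` with header
`cdr3b  epitope  label`. Other column names work too; pass them to
`--cdr3-col` / `--epitope-col` / `--label-col`.

## 2. Curate and split

```sh
TCRH=$(Rscript -e 'cat(system.file("scripts", "tcrh.R", package = "tcrh"))')
Rscript "$TCRH" split --input tchard.tsv --kind epitope_hard \
    --seed 7 --test-fraction 0.2 --out-prefix he
Rscript "$TCRH" split --input tchard.tsv --kind tcr_hard \
    --seed 7 --test-fraction 0.2 --out-prefix hb
Rscript "$TCRH" split --input tchard.tsv --kind strict \
    --seed 7 --test-fraction 0.45 --out-prefix hbe
```

Curation (CDR3beta length 9-23, epitope length <= 15, duplicate and
label-conflict removal) is applied automatically on read. The strict split
keeps only records whose epitope *and* CDR3beta are unseen, so its realized
test fraction is roughly the square of the per-key fraction — hence the
larger `--test-fraction` above. Each run writes `*.train.tsv`,
`*.test.tsv` and a `*.split.json` report (counts, discards, unseen-group
counts). Realized sizes depend on the seed; only the disjointness
invariants are guaranteed.

## 3. Train, evaluate, explain

```sh
Rscript "$TCRH" train --train he.train.tsv --model svm_rbf --seed 7 \
    --threshold 0.8 --out he_model.rds
Rscript "$TCRH" eval --model he_model.rds --test he.test.tsv \
    --report he_eval.json
Rscript "$TCRH" explain --model he_model.rds --train he.train.tsv \
    --test he.test.tsv --n-samples 100 --top-k 50 --seed 7 \
    --report he_shap.json
```

`he_eval.json` carries the confusion counts, accuracy, precision, recall,
specificity, F1, AUC and ROC points; `he_shap.json` / `he_shap.csv` carry
the top-50 mean |SHAP| feature ranking. Repeat with the `hb` and `hbe`
prefixes for the TCR-hard and strict models.

Note that the bundled scale tables mix published values with derived
analogue scales (see the `provenance` column of
`inst/extdata/aa_scales.csv` and the package vignette); real-data metrics
obtained with them are expected to be close to, but not bit-identical
with, results computed from the originally published scale values.
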