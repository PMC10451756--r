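---
title: "Determining the core rhizomicrobiome: membership, composition and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the core rhizomicrobiome: membership, composition and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizocore)
```

## The problem

The rhizosphere — the narrow band of soil shaped by living roots — hosts the
densest microbial communities in soil. A recurring question in rhizosphere
ecology is which taxa form the *core* microbiome: the organisms consistently
associated with a host or habitat across samples. "Consistently associated"
is not one definition but several, and the choice of definition changes the
answer. This package implements three definitions commonly applied to
OTU/ASV relative-abundance tables from amplicon surveys, plus the set
algebra for comparing their results:

- **Membership**: an OTU belongs to the core candidate set when it is
  detected in *every* sample of a group (prevalence 1, the shared-taxa or
  Venn criterion). Candidates are ranked by mean relative abundance and the
  top N (default 10) are retained.
- **Composition**: among the same shared candidates, an OTU belongs to the
  core when its standard deviation of relative abundance across the group's
  samples (SDRA) is *strictly below* a threshold (default 0.01 on the
  percent scale) — shared taxa held at similar proportions everywhere.
- **Function**: OTUs are mapped to ecological functions (nitrification,
  nitrogen fixation, chemoheterotrophy, ...) by matching their taxonomic
  lineage against a rule database in the FAPROTAX flat-file dialect; per
  group, each function is summarized as the percentage of detected OTUs
  assigned to it, and the percentages of two groups are compared with
  Fisher's exact test.

The expected grouping factor is a two-level contrast such as forecrop
(wheat `W` vs legume `L`) with 4 rhizosphere samples per group, but any
number of groups and samples works.

## Scale conventions

Microbiome tables arrive as read counts, proportions or percentages.
Internally everything is a proportion: `to_relative()` divides each sample
column by its sum. All *reported* relative abundances (`mean_ra`, `sd_ra`,
core totals) are on the **percent** scale, because that is how
core-microbiome tables are conventionally printed; the conversion happens
once, inside `summarize_group()`. Consequently the default SDRA threshold
`0.01` is a percent-scale value: it removes taxa whose abundance swings by
more than about one hundredth of a percentage point across samples.
`threshold_scale = "proportion"` restates it on the proportion scale
instead.

Two further conventions are explicit parameters because, with only four
samples per group, they are material:

- `sd_ddof`: the SDRA uses the sample standard deviation (n − 1 denominator)
  by default, the convention of mainstream statistics software; `sd_ddof = 0`
  switches to the population form.
- `presence_epsilon`: detection means proportion strictly greater than 0
  (i.e. at least one read). Noisy pipelines can raise the floor.

Ties in any ranking are broken by OTU id with numeric-aware comparison
(`OTU2` before `OTU10`), so every result is deterministic. OTU identity is
always the id, never the taxonomy label — reference tables legitimately
contain two distinct *Pseudarthrobacter* OTUs.

## The bundled reference tables

Four published core-microbiome summary tables ship with the package as
plain data (`core_table_fixtures()`): membership cores for a wheat and a
legume forecrop group (10 OTUs each, percent means) and composition cores
for the same groups (10 OTUs with mean ± SD). The underlying per-sample
table was never published, so `fixture_community()` reconstructs a minimal
4-sample community whose group summaries reproduce a table *exactly*: each
listed OTU gets per-sample proportions `mean ± d` with
`d = sd * sqrt(3)/2` (which has sample SD exactly `sd` over the pattern
`+d, -d, +d, -d`), and a per-sample filler OTU — present in that sample
only, hence never a core candidate — absorbs the rest of the column mass.

```{r fixtures}
core <- membership_core(fixture_community("table1"), "W", top_n = 10,
                        taxonomy = fixture_taxonomy())
core$total_core_abundance      # 0.1976 (percent)
head(core$members, 3)
```

The reference tables are internally inconsistent in places, and the package
reproduces the tables rather than the surrounding summaries:

- The legume membership table's per-OTU values sum to 0.2009, while the
  prose accompanying it quotes 0.2006. The computation necessarily returns
  the sum of the rows it is given; 0.2009 is asserted, the 0.2006 figure is
  recorded here as a known discrepancy.
- Applying the stated composition rule (SDRA < 0.01, strict) to the wheat
  composition table keeps exactly 8 of its 10 printed rows (the two
  high-variance rows, ±0.1780 and ±0.2790, fail), although the accompanying
  text speaks of five core ASVs; for the legume table *no* printed row
  passes the stated threshold. The implementation follows the stated rule
  and makes no attempt to reverse-engineer the unstated selection that
  produced "five".
- Dominant composition-core abundances quoted in prose (1.638%, 1.240%) do
  not appear in any printed row and are not reproducible from the tables.

## The synthetic community generator

Real per-sample data for the reference tables is not available, so
`synth_community()` generates communities with the structure the methods
assume, with known ground truth for validation:

- **Planted core** (`n_core = 10`): ubiquitous, low-variance taxa. Each
  gets a community base weight from a lognormal with mean
  `core_mean_ra = 0.005` and CV `core_cv = 0.05`, jittered per sample by an
  independent lognormal with the same CV. The low CV mirrors the reference
  composition tables, whose retained core taxa show relative SDs of order
  0.001–0.01 of their means.
- **Decoy taxa** (`n_decoy = 2`): abundant (0.8× the core weight) but
  high-variance (`decoy_cv = 1.0`). These are the taxa the SDRA filter
  exists to reject — SDRA is an *absolute*-scale statistic, so only taxa
  that are both abundant and variable can exceed a threshold set relative
  to the core's SD. Rare-but-variable taxa are already excluded by the
  prevalence step.
- **Peripheral taxa** (`n_peripheral = 40`): weights one order of magnitude
  below the core, each present in a given sample with probability
  `peripheral_prevalence = 0.5` — the patchy tail of the community.

Per sample, expected proportions are renormalized and counts drawn from a
multinomial at `depth = 5000` reads, the order of magnitude of per-sample
totals in small rhizosphere surveys. Two groups (`W`, `L`) of 4 samples are
generated from the same base community; an optional `group_effect`
multiplies a chosen taxon subset in the second group (off by default, so
the groups are exchangeable draws). Everything is reproducible from `seed`
(Mersenne-Twister, recorded in the truth record), and the caller's RNG
state is left untouched.

The truth record reports each core taxon's **planted SDRA** — its design
coefficient of variation times its expected share, on the percent scale.
This is the reference point for threshold tuning on known ground truth: at
3× the median planted SDRA, the composition filter excludes decoys while
keeping the planted core. The *realized* sample SDRA is deliberately not
used as the reference: at 5,000 reads it is dominated by multinomial
counting noise (relative SD ≈ `1/sqrt(depth * p)`) plus renormalization
coupling, and thresholds tuned to it drift upward with the very noise the
filter should reject. The same counting-noise floor means the tiny SDs of
the reference composition tables (CV ~0.01 at sub-percent abundances)
cannot arise at this depth — a useful reminder that passing synthetic tests
demonstrates method correctness, not that real communities look like the
generator. The generator also does not simulate taxonomic
misclassification, chimeras, or read-level error.

Measured at the defaults over hundreds of simulations during development,
membership recovery of the planted core (top-N at N = 10) averages ≈ 0.95
and decoy exclusion ≈ 0.92–0.95; both are re-measured by the test suite
(100 and 60 seeds respectively — sizes chosen to keep the default test run
fast while leaving sampling error well below the margins).

```{r synthetic}
g <- synth_community(synth_spec(seed = 7))
rel <- to_relative(g$table)
got <- core_members(membership_core(rel, "W", 10))
mean(g$truth$core_ids %in% got)    # recall in one community; ~0.95 on average
```

## Functional rules

`read_function_rules()` parses the FAPROTAX flat-file dialect: a function
header at column 0, indented taxon patterns, `#` comments, and
`add_group:NAME` include directives that import the clauses of a previously
defined function (includes are therefore acyclic by construction; forward
or undefined references are errors). A clause matches an OTU when its
wildcard pattern (`*` = any substring, case-sensitive) matches the full
semicolon lineage path or any single rank name. OTUs with wholly
unclassified lineages are never assigned: function prediction rests on
taxonomic identity at genus/species level, so unidentified organisms are
excluded from the functional analysis, and assignment percentages use
*detected OTU counts* — never read counts — as denominator.

The bundled miniature rule set (`faprotax_mini_rules()`) covers 13
functions over taxa recurrent in rhizosphere surveys, enough to exercise
every code path offline; the full FAPROTAX database file, where licensing
permits downloading it, parses through the same reader.

The between-group comparison uses Fisher's exact test by default. The
choice is deliberate: at desk-scale OTU counts the normal approximation is
unreliable, and the exact test is valid at any count. A two-proportion
z-test (`method = "prop_z"`) is provided for comparability with
spreadsheet-era analyses whose exact test is unrecoverable.

## Numerical choices and degenerate inputs

- Proportion columns must sum to 1 within 1e-9 (percent: 100 within 1e-6);
  all-zero sample columns are an error naming the sample.
- Mode inference (counts/proportion/percent) is best-effort from the file
  body; an explicit `mode` always wins, and `check_sums = FALSE` admits
  deliberately partial tables such as the bundled summary fixtures.
- A one-sample group has SDRA 0 by convention in summaries, but
  `composition_core()` refuses it outright — an SD from one observation is
  undefined and silently returning the whole candidate set would be
  misleading.
- `membership_core(top_n = k)` returns fewer than `k` members without
  complaint when fewer OTUs are shared; an empty candidate set gives an
  empty core with total 0.
- Core reports print abundances with 4 decimals (the convention of the
  reference tables); re-reading a report recovers members, order and totals
  to that precision.

## Limitations

Compositionality is acknowledged but not transformed away: the methods
operate on relative abundances directly, as their published definitions do,
without CLR or other log-ratio transforms. Rarefaction, denoising and
classification are upstream of this package. The pipeline
(`run_core_pipeline()`) is a plain function driven by a YAML or list
config; it aborts on the first failing stage with the stage named in the
error.
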