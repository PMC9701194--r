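---
title: "Profiling Cas9 PAM specificity from excision-reporter libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling Cas9 PAM specificity from excision-reporter libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamdose)
library(dplyr)
```

## The assay and the model

Cas9 nucleases only cleave targets flanked by a protospacer adjacent motif
(PAM), and compact type II-C enzymes such as the *Neisseria cinerea* Cas9
(NcCas9) read an 8-nt PAM. Excision-based positive-selection reporters
characterize this requirement in cells: a plasmid library carries a fully
randomized 8 N cassette, cleavage at a functional PAM excises a tdTomato
cassette (switching the reporter to EGFP), and the excised junctions are
PCR-amplified and deep-sequenced. PAM k-mers that support cleavage are
enriched in the sequenced (cleaved) pool relative to the input library.

`pamdose` implements that analysis path end to end, together with a
simulator that generates libraries under a *known* per-PAM cleavage model
so every downstream stage can be validated against ground truth:

1. **sim** — synthetic cleaved/input FASTQ pools, reporter flow-cytometry
   events, and base-editing pileups;
2. **extract** — read anchoring, the indel-near-PAM filter, and cassette
   counting;
3. **pamstats** — enrichment, position probability matrices (PPM),
   information content (IC), IUPAC consensus, positional dependence;
4. **editquant** — reporter efficiency, editing-window maxima, embryo
   summaries;
5. **guidescan** — degenerate-PAM target-site scanning and density.

### The generative model

A cleaved-pool read is produced by sampling a cassette $\pi$ from the
library bias $b(\pi)$ (uniform $0.25$ per base by default), accepting it
with the cleavage probability $a(\pi)$, and emitting
`upstream_anchor + cassette + downstream_anchor` with sequencing errors.
The accepted-cassette distribution is therefore

$$ f(\pi) = \frac{b(\pi)\,a(\pi)}{\sum_{\pi'} b(\pi')\,a(\pi')}, $$

and `simulate_pamdose()` samples cassettes *directly* from $f$, which is
distributionally identical to per-read rejection sampling but does not
spend $\sim 10^7$ rejected draws when mean activity is low (under the
default planted model only $\approx 0.9\%$ of random cassettes are
cleavable). The input pool skips the acceptance step. The returned
`truth` tibble carries $a(\pi)$ and $f(\pi)$ for every k-mer, and a
chi-square goodness-of-fit against $f$ is part of the test suite.

The error model is deliberately minimal: i.i.d. substitutions (default
$2\times10^{-3}$ per base) and at most one 1-bp insertion or deletion per
read (default $10^{-3}$ per read, uniform position) — enough to exercise
the extraction filters. It does not model PCR jackpotting, UMIs, paired
ends, or learned quality profiles, so passing tests say nothing about
those artifacts in real libraries. The default planted activity model
(`GTAT` 1.0, `GCAT` 0.8, `ATAT`/`GTTT` 0.3 at cassette positions 5–8)
mirrors the relative preferences seen for NcCas9 in reporter assays;
default anchors are arbitrary 14-mers chosen so that no repeated base
spans an indel-filter zone edge, which keeps alignment gap placement
unambiguous exactly where the filter decision flips.

## Extraction and the indel filter

Reads are anchored by exact/mismatch-only search first
(`Biostrings::vmatchPattern`, tolerance `max_mismatch = 1` per anchor) and
only the residue — reads carrying an indel inside an anchor — falls back
to semi-global gapped alignment (match $+1$, mismatch $-1$, gap $-2$; at
most 3 gap bases per anchor). Both orientations are tried; ties go to the
higher-scoring frame, then forward.

Reads with an insertion or deletion inside the cassette or within
`window = 3` bases of either cassette boundary are rejected
(`filter_indel_near_pam()`), because such gaps corrupt the 8-mer register.
The window is applied symmetrically to both boundaries. The exact
convention, pinned position-by-position by the test suite, is: a deletion
is rejected when the removed base lies within 3 bases of a boundary (or
inside); an inserted base that has $k$ original bases between itself and
the boundary counts as distance $k+1$, so an insert adjacent to the
cassette is distance 1. Substitutions never trigger this filter.

Every read lands in exactly one ledger category, assigned in the fixed
order *no-anchor → indel-near-PAM → ambiguous-base → passed*, so
`glance()` on a count table always partitions the total:

```{r extract-demo}
design <- library_design()
model <- activity_model("table", table = c(
  NNNNGTAT = 1, NNNNGCAT = 0.8, NNNNATAT = 0.3, NNNNGTTT = 0.3))
sim <- simulate_pamdose(design, model, error_model(0.002, 0.001),
  n_reads = 20000, seed = 1)
counts <- count_pams(sim$cleaved, sim$input, design)
glance(counts)
```

## From counts to a consensus PAM

`pam_enrichment()` computes
$e(\pi) = \hat f_{\mathrm{cleaved}}(\pi) / \hat f_{\mathrm{background}}(\pi)$
with a shared pseudocount ($\alpha = 1$ by default) over the complete
$4^8$ k-mer space; the background is the input pool when present,
otherwise the design bias. The PPM uses raw cleaved-pool counts by
default — PAMs are counted, matching how such logos are usually built from
a positive screen — with enrichment weighting available as an option;
neither is claimed to be the one used for any particular published
figure. The PPM pseudocount defaults to 1% of the total weight split
across the four bases, which stabilizes empty cells without visibly
moving well-sampled columns.

Information content per position is
$\mathrm{IC}_j = \sum_b p_{jb} \log_2 (p_{jb}/q_b)$ with uniform
background $q$, i.e. $0$ bits for a uniform column and $2$ bits for a
fixed base. `call_consensus()` includes every base with
$p_{jb} \ge t - \epsilon$ (default $t = 0.25$, always keeping the argmax
base so the set is never empty) and writes the set as an IUPAC code. The
boundary tolerance $\epsilon = 0.005$ is a deliberate numerical choice:
probabilities estimated from counts fluctuate around the true value by
$\approx \sqrt{0.25 \cdot 0.75 / n}$, so a genuinely uniform column
(true $p = 0.25$) would straddle a hard $t = 0.25$ cut at random — half
its bases dropping out — while 0.005 is far below the gaps that separate
preferred from disfavoured bases in any informative column. Exact ties at
the threshold are included. With fewer than a few thousand passed reads
the tolerance no longer covers the sampling noise and unconstrained
positions may be reported as partial codes rather than N; the remedy is
depth, not a larger $\epsilon$.

```{r consensus-demo}
prof <- pam_profile(counts, threshold = 0.25)
glance(prof)
suffix_enrichment(prof$scores, k = 4) |> head(4)
```

At $10^5$ reads the planted model is recovered as `NNNNGYAT` with the
planted enrichment ordering; at the 20,000 reads used here the consensus
is already correct while the enrichment estimates are noisier.
`positional_dependence()` reports pairwise mutual information between
cassette positions as a diagnostic for whether a position-independent
logo is adequate (for the factorized planted model the off-diagonal terms
are near zero; the estimator's small-sample bias is positive, roughly
$9/(2 n \ln 2)$ bits).

## Editing quantifications

* `reporter_efficiency()` — the EGFP+/tdTomato+ cell ratio under
  rectangular gates, with a Wilson 95% CI. Simple thresholds match the
  relative-frequency semantics of the assay; no density-based gating is
  attempted.
* `base_edit_site_frequency()` — the maximum conversion frequency within
  the editing window, ties to the smallest (most PAM-distal) position.
  Spacer positions are numbered from the 5′ PAM-distal end of the 24-nt
  spacer; because no numeric window is universally defined for this
  enzyme class, the window is a user-supplied argument defaulting to the
  whole spacer.
* `embryo_summary()` — edited-blastocyst counts and percent with the
  min–max frequency range over edited embryos. The edited call uses a 1%
  frequency floor by default (a Sanger-quantification noise floor),
  configurable; raising it can only lower the count.

## Guide scanning

`scan_targets()` reports every spacer+PAM match of a degenerate pattern
(default `NNNNGYAT`, 24-nt spacer) on both strands, 0-based half-open
coordinates on the forward reference, BED6 export included. Reference
windows containing N are skipped rather than wildcard-matched —
conservative for design use. The 5′-G rule is ambiguous between
substituting the first spacer base and prepending a 25th base; the
default substitutes (keeping a G+23 = 24-nt guide) and
`g_rule = "prepend"` gives the extended form, with the modification
flagged either way. `pam_density()` compares observed site density with
the i.i.d. closed form $\prod_j \sum_{b \in \mathrm{allowed}_j} c_b$
(1/128 per strand-position for `NNNNGYAT` under uniform composition).

```{r scan-demo}
sites <- scan_targets(
  c(demo = paste0("GACGTACGTACGTACGTACGTACG", "AAAAGTAT")), "NNNNGYAT")
sites[, c("spacer_start", "strand", "pam_seq", "sgrna_spacer")]
```

## Problem sizes, determinism and limitations

The package's validation runs use $10^5$-read libraries for consensus
recovery and the uniform-activity null (where the maximum positional IC
stays below 0.05 bits), $2\times10^4$ reads for the indel-ledger
comparison against the simulator's ground truth, $10^3$ error-free reads
for exact brute-force count equivalence, and 100-kb random sequence for
density checks — sizes at which the multinomial and binomial error bars
used in the assertions are small relative to the planted effects. All
simulators are seed-deterministic down to byte-identical FASTQ output.

One statistical caveat worth stating: a battery that demands an
estimate-inside-95%-CI event in at least 95% of a small number of
replicates is itself a near-coin-flip — with 20 replicates and true
per-replicate coverage of 0.95, the chance of seeing at least 19
successes is only about 0.74 — so replicate-coverage checks of that shape
should be read as consistency checks, not sharp gates.

Known limitations: the simulator emits single-amplicon, single-end reads
only; anchors are assumed unique within a read; enrichment is undefined
for k-mers with positive cleaved mass but zero background mass (reported
as NA); the consensus is a per-position summary and will mask coupled
preferences, which is why the mutual-information diagnostic is provided;
and scanning uses exact IUPAC matching with no mismatch tolerance, as
appropriate for guide design rather than off-target enumeration.
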