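---
title: "Detecting internal m7G in tRNA from chemical-cleavage sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal m7G in tRNA from chemical-cleavage sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boseq)
```

## The assay and its signal

Internal N7-methylguanosine (m7G) sits at position 46 of the variable loop in
a subset of tRNAs, deposited in humans by METTL1/WDR4.  Treating RNA with
sodium borohydride reduces the m7G base and leaves an abasic site; aniline
then cleaves the chain by beta-elimination immediately 3' of the modified
position.  The 3' cleavage fragment carries a ligatable 5' phosphate and
enters a small-RNA sequencing library, whereas the 5' fragment ends in a
blocked 3' aldehyde and is mostly lost at adapter ligation.  In a treated
library, fragment start sites therefore pile up at the modified position N
and a few bases downstream (reverse transcription stops spread over roughly
N..N+3), while an untreated library of the same RNA shows only background
fragmentation.  The same chemistry also produces abasic sites at
3-methylcytidine (m3C), wybutosine and dihydrouridine (D); because those
arise from non-G parent bases, restricting calls to guanosines removes them.

`boseq` implements the computational side of this assay: reference
construction, start-site counting with the assay's filters, the
cleavage-score statistic and candidate calling, projection onto isoacceptor
coordinates, and a ground-truthed simulator of the chemistry so every stage
is testable without sequencing data.

## The statistic

For a contig with $N$ aligned reads in a condition and $n_i$ reads whose
fragment start site is position $i$, the *cleavage ratio* at $i$ is

$$ r_i = \frac{n_i + \alpha}{N} $$

and the *cleavage score* compares the two conditions:

$$ s_i = \log_2 \frac{r_i^{\mathrm{treated}}}{r_i^{\mathrm{untreated}}} . $$

Positions with $s_i$ above a threshold $\tau$ are candidate cleavage sites;
the modified guanosine is then located upstream of the score peak within the
RT-stop window (below).

Numerical choices:

* **Pseudocount** $\alpha = 0.5$ is added to the start counts of *both*
  conditions before forming ratios.  The literal ratio is undefined when the
  untreated library has no read at a position — the common case at a real
  cleavage site — and a symmetric pseudocount keeps every score finite while
  preserving exact antisymmetry under swapping the conditions (the score is
  computed as `log2(r_t) - log2(r_u)`, so the swap negates it to the last
  bit).  `alpha = 0` reproduces the literal formula and errors on zero
  counts.
* **Two thresholds** are exposed rather than reconciled: the conservative
  default $\tau = 6.5$, and $\tau = 5$ as the documented operating point for
  broader candidate lists.  Both are presets of the same `threshold`
  argument.
* **Support threshold**: a start-site cell must hold at least 10 reads
  (`minSupport`); weaker cells are zeroed.  We read the support rule as
  applying per (contig, start-site) cell — the alternative per-distinct-
  sequence reading is operationally very close for 51-nt reads, and the
  per-cell form makes the zeroing interact transparently with the ratio.
  Zeroed cells still count in $N$: the denominator is defined as total
  aligned reads, not the sum of retained starts, so thresholding is monotone
  (raising it can only lower counts, never raise a score).
* Scores are computed at *every* position of every contig covered in both
  conditions (with $\alpha$ making them finite); a contig without reads in
  either condition is skipped with a logged reason rather than scored.

## Candidate calling and the guanosine restriction

Qualifying positions ($s > \tau$ and a strictly positive treated count — the
latter guards against pseudocount-only artifacts on near-empty contigs) are
grouped per contig into windows whose consecutive members are at most
`maxGap = 3` apart, matching the ~4-base RT-stop region.  Within a window
the peak is the maximum-score position, ties breaking toward the smaller
coordinate (closer to the putative modified base, and deterministic).  The
candidate guanosine is the largest position $g \le \mathrm{peak}$ with
reference base G and $\mathrm{peak} - g \le 3$; a window with no such G is
discarded.  This is an explicit formalisation of a verbal rule: the source
analyses state the window width and the G restriction but no algorithm, so
the grouping, peak and tie-break rules here are this package's own, chosen
to be deterministic and order-independent.

A caveat the formalisation makes visible: if a non-G modification (e.g. m3C)
cleaves within three bases downstream of an *incidental* guanosine, the
restriction cannot reject the window and a false candidate at that G is
possible.  This is inherent to the assay's G-restriction logic, not to this
implementation; the simulator's off-target sites make the behaviour easy to
demonstrate.

## Reference construction

* Mature tRNA gene bodies (intron-less, no tail) get an unconditional 3'
  `CCA` since mature tRNAs carry a non-genomic CCA; a `ccaIfAbsent` flag
  covers inputs that already include tails.
* Genes identical at 100% after tailing collapse to one contig (exact string
  equality, no near-identity clustering), named after the lexicographically
  smallest member id so collapsing is permutation-invariant.  A contig is
  excluded from analysis only when *all* members are pseudogenes or
  mitochondrial: reads on a mixed contig are attributable to the functional
  copy, so discarding them would waste true signal.
* The genome copy of each gene is masked to `N` so mature reads map to the
  contigs, and 50-bp flank intervals — shifted 3 bp away from the gene on
  the 5' side and 6 bp on the 3' side — mark pre-tRNA territory.  The shifts
  are strand-mirrored on minus-strand genes (the natural reading of
  "upstream/downstream" in transcript sense; the source text does not state
  strand handling).  Reads whose genome alignment overlaps any flank by one
  base or more are removed before counting.
* Coordinates are 0-based half-open in on-disk gene tables and BED, 1-based
  in every user-facing report, so "G46" means the 46th base.

## What the simulator emulates — and what it does not

`simulateLibrary()` draws reads from a generative model of the chemistry,
per molecule:

1. a molecule on a contig carrying a modification cleaves with the site's
   `efficiency` (treated condition only; the 5'-most cleavage wins if
   several sites fire);
2. a cleaved molecule's 3' fragment is recovered with probability 0.9 and
   its observed start is $N + \mathrm{offset}$, offset drawn from
   `{0: 0.15, 1: 0.55, 2: 0.20, 3: 0.10}` — peaked at N+1, the nominal
   beta-elimination point, with the spread representing stutter of the
   reverse-transcription stop.  No offset distribution is published, so the
   default is a modelling choice, fully configurable and recoverable from
   the truth log;
3. the 5' fragment is recovered with probability 0.05, representing
   ligation failure of the blocked 3' end (again a qualitative, not
   measured, rate chosen to reproduce the strong 3'-fragment coverage bias);
4. intact molecules yield full-length reads (trimmed to the 51-nt read
   length) or, with a per-base background break rate of 0.001, a fragment
   from a uniform position;
5. a configurable fraction of reads is pre-tRNA contamination: genomic
   sequence spanning a locus/flank junction, so it maps into a flank on the
   unmasked genome;
6. fragments shorter than 15 nt are not sequenced (size selection).

Base quality is constant and the default error rate is zero: the assay's
signal is positional, and error-free reads keep the alignment oracle exact
(an `errorRate` option adds uniform substitutions).  m3C/D off-target sites
cleave exactly like m7G — deliberately, so that only the downstream
G-restriction removes them.

The companion gene generator fixes a realistic modification context in every
simulated gene: T at 20 (the D site), C at 32 (the m3C site), G at 46 with
non-G bases at 47–49, mirroring the canonical variable-loop context.  The
non-G constraint just downstream of 46 reflects real tRNA sequence (47 is
the D/U-rich position); without it, an incidental G at 47–49 would make the
upstream-G assignment ambiguous in a way real position-46 contexts are not.

Features of real data the simulator does **not** model, and which passing
tests therefore say nothing about: misincorporation and premature stops at
the many *other* tRNA modifications, PCR duplication (the `dedup` filter
exists but defaults off), adapter read-through, partial 3'-CCA loss, ragged
transcription starts, and alignment ambiguity among near-identical
isodecoders beyond exact duplicates.  Real libraries should be aligned with
a production aligner and ingested as SAM/BAM; `naiveAlign()` is an
exact-substring test aligner, not a mapping tool.

## Position projection

Candidate positions are projected onto isoacceptor canonical coordinates via
multiple alignments consumed as Stockholm files (one per isoacceptor);
covariance-model scanning is deliberately not reimplemented, since its role
here is positional bookkeeping.  Projection maps position $p$ of a gene to
the alignment column holding its $p$-th non-gap character — a bijection on
non-gap columns, tested exhaustively.  Rows are matched to contigs by exact
ungapped-sequence equality (CCA excluded, as alignments cover the tRNA
body); a mismatch rejects the row rather than fuzzily matching, and
positions inside the appended CCA map to synthetic labels `CCA1..CCA3`.
When a `#=GC RF` line is present its non-gap columns are numbered to give
canonical labels; otherwise raw column indices are reported.  Candidates
from isodecoders landing on the same column merge into one isoacceptor-level
site (maximum score, members retained).  The source pipeline's step of
discarding hits to intron-containing profiles has no analogue under
column projection and is intentionally absent.

## Reporting

Heatmap matrices sum member-gene coverage within an isoacceptor *before*
normalising (summing, not averaging, weights isodecoders by their actual
read mass).  Default normalisation is per-row maximum, which reproduces the
per-isoacceptor pile-up view; counts-per-million is offered for cross-sample
comparison.  Plots are a thin optional layer over the exported matrices —
every number in a report is reproducible from the stage TSVs.  The pipeline
writes a YAML manifest of resolved parameters and output checksums;
everything downstream of a seed is byte-deterministic, which the test suite
checks by re-execution.

## Validation scale

The test suite validates the statistic against an independent closed-form
evaluation on 1,000 randomised count cells, and runs the pipeline end to end
on simulated studies of 20 contigs (76 nt + CCA) with m7G planted at the
position-46 analogue on 10 of them at efficiency 0.8 and 50,000 reads per
condition — the regime in which the method recovers planted sites with
sensitivity and precision at or above 0.9 at the $\tau = 5$ operating point,
calls nothing in an untreated-vs-untreated null, and calls nothing at
planted m3C/D positions.  Smaller configurations (6–10 contigs, 4,000–15,000
reads) cover offset-invariance, pre-tRNA subtraction and byte-level
determinism.  These sizes are the package's chosen validation scale;
sensitivity at much lower coverage or cleavage efficiency degrades smoothly
and can be explored with the simulator.

## Known limitations

* The G-restriction false-call mode near non-G modifications, noted above.
* Exact-duplicate collapsing only: near-identical isodecoders remain
  separate contigs and compete for reads in real alignments.
* The cleavage score is a fixed-threshold statistic, not a significance
  test; no multiple-testing machinery is attached, by design.
* Quantitative methylation stoichiometry is out of scope: the score ranks
  evidence of cleavage, it does not estimate the methylated fraction.
```{r session}
sessionInfo()
```
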