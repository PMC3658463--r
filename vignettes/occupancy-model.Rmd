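---
title: "A sequence-context model of H3K4me3 and H3 nucleosome occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequence-context model of H3K4me3 and H3 nucleosome occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsig)
```

## The problem

Active promoters and other regulatory elements in human cells are marked
by nucleosomes carrying trimethylation of histone H3 lysine 4 (H3K4me3),
while the bulk of the genome is covered by unmodified H3 nucleosomes or is
nucleosome-free.  H3K4me3 nucleosomes sit preferentially on CpG-rich,
distinctive DNA, which raises a concrete computational question: how much
of the H3K4me3 landscape is predictable from the genome sequence alone?
`nucsig` answers it in three steps:

1. estimate state-specific **6-mer sequence specificities** from ChIP-seq
   read positions (module: `count_kmers()`, `kmer_specificity()`),
2. convert them into **fifth-order conditional emission models** and decode
   a hidden Markov model over competing nucleosome arrangements to get, for
   every base pair, the posterior probability of being covered by an
   H3K4me3 nucleosome, an H3 nucleosome, or neither (`hmm_params()`,
   `run_genome()`),
3. score the predictions against experimental coverage with correlation,
   Poisson enrichment calling, precision–recall, false-negative rates and
   meta-profiles (`evaluation` functions), and inspect dinucleotide
   periodicity (`positional_dinuc_profile()`).

A synthetic-data generator (`simulate_genome()`, `simulate_reads()`,
`end_to_end_fixture()`) is the generative dual of the HMM and makes every
step testable without any external download.

## The occupancy model

### State space and transitions

The hidden chain walks over states $\{F, M_1,\dots,M_L, N_1,\dots,N_L\}$:
$F$ is a nucleosome-free base, $M_i$ ($N_i$) is the $i$-th base pair of an
H3K4me3 (H3) nucleosome of fixed length $L$ (default 147 bp).
Within-nucleosome transitions are deterministic, $M_i \to M_{i+1}$; all
stochastic choices happen at *decision points* — after a free base or a
completed nucleosome:

$$P(F \mid \text{decision}) = d,\qquad
  P(M_1 \mid \text{decision}) = (1-d)\,\rho,\qquad
  P(N_1 \mid \text{decision}) = (1-d)(1-\rho).$$

$d$ is the nucleosome-depletion probability and $\rho$ the probability
that a newly started nucleosome carries H3K4me3.  Linker lengths are
therefore geometric; that is a deliberate modelling floor, not an
oversight (see Limitations).

Rather than exposing $d$ and $\rho$ directly, the user states target
genome proportions.  Under the renewal structure, a decision point emits
one base with probability $d$ or $L$ bases with probability $1-d$, so the
stationary bound fraction is $L(1-d)/(L(1-d)+d)$.  Setting this equal to
the target $\pi_{nuc}$ gives the closed form used by
`calibrate_transitions()`:

$$d = \frac{L(1-\pi_{nuc})}{L(1-\pi_{nuc}) + \pi_{nuc}},\qquad
  \rho = \frac{\pi_{me3}}{\pi_{nuc}}.$$

Defaults are $\pi_{nuc} = 0.80$ and $\pi_{me3} = 0.05$: roughly 5% of the
human genome in CD4+ T cells is H3K4me3-occupied, and 75–85% is a
conventional estimate of total nucleosome coverage.  Both are ordinary
arguments — they are priors, and analyses of other cell states should set
them deliberately.

### Emissions

Each state class emits bases conditional on the preceding five bases
(a "modified fifth-order" HMM): one $4^5 \times 4$ table per class
(H3K4me3, H3, background), estimated by `emission_from_counts()` as
pseudocounted conditional frequencies of 6-mers in 151-bp extended read
intervals (or the whole genome, for background).  Emission tables are
position-independent within the nucleosome: read extension pools all
positions of the bound fragment into one frequency table, so the data do
not constrain a per-position table.  Within the first five bases of a run
no full context exists; the model uses order-$k$ tables ($k = 0..5$)
obtained by uniformly averaging the order-5 rows over all contexts sharing
the same length-$k$ suffix (`emission_marginals()`).  This keeps the first
bases of every run in the likelihood instead of discarding them.

### Decoding

For posterior decoding the deterministic within-nucleosome structure is
exploited: forward and backward quantities are computed over decision
points only,

$$f(u) = P(S_1..S_u,\ \text{decision point after } u),\qquad
  b(u) = P(S_{u+1}..S_T \mid \text{decision point after } u),$$

with $f(0) = 1$, $b(T) = 1$ and three-term recursions (free step, or an
$L$-step of either nucleosome class).  The posterior that an H3K4me3
nucleosome *starts* at $u$ is
$f(u-1)(1-d)\rho\, E_{me3}(u, u+L-1)\, b(u+L-1) / P(S)$, and the per-base
occupancy track is the sliding $L$-window sum of start posteriors —
mathematically identical to summing state posteriors over $M_1..M_L$, but
$O(T)$ instead of $O(TL)$ in both time and working memory.
`nuc_forward()`/`nuc_backward()` also reconstruct the full per-state
scaled matrices on request, which the tests compare against an exhaustive
enumeration oracle (`brute_force_oracle()`).

**Boundary rule.** Runs (maximal N-free, unmasked stretches) start and end
at decision points: no partial nucleosomes overhang a run boundary, and a
run shorter than $L$ is decoded as entirely free.  One visible consequence
is that the total log-likelihood with identical emission tables is *not*
exactly the background log-probability of the sequence: arrangements whose
last nucleosome would overrun the run end carry no mass, which costs an
$O(1)$ deficit independent of $T$.  The tests assert precisely this
behaviour.  A second consequence is edge depletion: occupancy relaxes from
0 at a run boundary to the stationary value over many nucleosome lengths.

### Numerics

All recursions run in log space with extended (`long double`)
accumulation; cumulative log-emission sums are kept in extended precision
so that differences over an $L$-window retain full double accuracy.  The
free-state posterior is computed directly from $f$ and $b$ rather than as
$1 - P_{me3} - P_{h3}$, so the conservation check
$P_{me3}+P_{h3}+P_{free}=1$ (asserted to $10^{-9}$ per base) is a genuine
numerical validation.  The enumeration oracle recomputes per-position
emissions in plain R, independently of the compiled kernel, and agrees
with the decoder to better than $10^{-12}$ on toy instances.

## Sequence specificity estimation

Reads are extended from their 5$'$ end toward the 3$'$ end to a total of
151 bp (the assumed immunoprecipitated fragment length); on the minus
strand extension runs leftward.  Every 6-mer window fully inside an
extended interval and containing no N contributes one count; overlapping
intervals are counted per read — depth is signal — and both strands are
counted by default so all derived quantities are strand-symmetric.
Enrichment is the pseudocounted state frequency over the pseudocounted
genome frequency, rescaled so the genome-frequency-weighted mean is
exactly 1.  The default pseudocount of 0.5 (a Jeffreys-style choice)
guarantees the positivity the HMM's log-space arithmetic requires.
`positional_kmer_specificity()` restricts (or excludes) the read intervals
to a region set before counting, e.g. to compare promoter versus
non-promoter specificity.

## Dinucleotide periodicity

`positional_dinuc_profile()` computes, for offsets within ±73 bp of site
centers, the frequency of each dinucleotide within a 3-bp smoothing
window, pooling reverse-complement pairs into the ten canonical panels
(AA/TT, CC/GG, AG/CT, AC/GT, CA/TG, GA/TC, and the self-complementary AT,
TA, CG, GC).  Minus-strand sites are reverse-complemented so the offset
axis is 5$'\to$3$'$ of the site.  `periodicity_power()` reports the
fraction of detrended profile variance explained by a sinusoid at exactly
the stated period.  The projection is evaluated at frequency $1/\text{period}$
directly rather than at the nearest DFT grid bin: profile lengths are
generally not multiples of the period, and grid quantization would leak a
pure period-10 signal into neighbouring bins, understating its power.
`compare_profiles_paired()` is a paired t-test over offsets with the
degenerate cases pinned down: identical profiles give $t=0, p=1$; a
constant non-zero shift gives $t=\pm\infty, p=0$.

## Evaluation machinery

* `coverage_track()` — number of 151-bp extended reads covering each base.
* `track_correlation()` — Pearson $r$ over jointly unmasked bases
  (standardization by the standard deviations makes tracks of different
  sequencing depth comparable).
* `call_enriched_sites()` — genome-wide rate $\lambda$ = mean coverage
  over unmasked bases; a base is enriched when
  $P(X \ge \text{obs};\lambda) < 10^{-5}$ (Poisson upper tail).  The
  cutoff is exposed; there is no hidden normalization, so uniformly
  scaling the coverage acts only through $\lambda$.
* `precision_recall()` — base-pair-resolution confusion counts at cutoffs
  0.1–0.9 (precision is reported as `NA`, not 0, when nothing is
  predicted); a region-level mode matches predicted runs and truth
  regions by overlap instead.
* `false_negative_rate()` — elements tiled into 200-bp windows; the rate
  is the fraction of windows with mean predicted probability below
  $10^{-5}$ whose mean coverage nonetheless reaches the genome-wide top
  0.1% quantile.  Ties at the quantile count as high, but a window with
  zero coverage is never "top" — otherwise an all-zero track would make
  every window high by tie-inclusion.  Window statistics use means, not
  maxima.
* `meta_profile()` — strand-flipped mean of a track around anchor 5'
  ends, with the genome-wide mean for reference.

## The synthetic generator

`simulate_genome()` samples the decision-point chain exactly as the model
defines it (a nucleosome that would overrun the genome end is rejected in
favour of a free base, mirroring the decoder's boundary rule) and emits
bases from the active state's conditional tables.  The planted tables are
deliberately simple and interpretable: background uniform; the H3K4me3
table multiplies C/G continuation probabilities by 3 (CpG-richness); the
H3 table multiplies A-after-A and T-after-T by 2 (the AA/TT stacking
preference of bent nucleosomal DNA, applied position-free).
`simulate_reads()` places 36-bp reads (inside the 30–50 bp range of the
modelled ChIP-seq protocols) at nucleosome boundaries with Gaussian 5'-end
jitter (SD 10 bp), modelling fragment-end variability.  Default problem
sizes — a 2-Mb genome, 2×10⁵ reads per state — were chosen as the
smallest instance at which k-mer estimation operates in the
large-count regime (about 500 reads per 6-mer on average) while a
laptop-scale run finishes in seconds.

What the generator does *not* emulate: PCR duplicates, GC bias,
sequencing error, paired ends, position-specific (rotational) dinucleotide
structure within nucleosomes, and non-geometric linker lengths.  Passing
the recovery tests therefore demonstrates the correctness and internal
consistency of the estimators and the decoder — not that real chromatin
attains the same accuracy.  On real data the attainable track correlation
is bounded by ChIP noise and by genuinely sequence-independent regulation,
and is substantially lower than on this idealized fixture.

## Design decisions taken where the design was open

* **Extension semantics**: "extended to 151 bp" is read as *total* length
  151 from the 5' end (not 151 added to the read); `ext` is exposed for
  the other reading.
* **Strand handling**: both strands are counted for reads and background
  alike, making enrichments strand-symmetric; the minus-strand extension
  runs leftward so that 3' direction is respected.
* **Initialization**: a run begins at a decision point (states $F$, $M_1$,
  $N_1$ only), with the same $\{d, (1-d)\rho, (1-d)(1-\rho)\}$ weights as
  any decision; the termination sums mass over $F$, $M_L$, $N_L$.
* **Reverse-complement symmetry of the decoder is not asserted**: the
  fifth-order emission is directional, so decoding a sequence and its
  reverse complement can legitimately differ even with strand-symmetric
  training counts.
* **No Viterbi**: all outputs are posteriors; no argmax segmentation, so
  no tie-breaking rules are needed.
* **Segment classification** (`segment_probability()`) treats a 6–147 bp
  segment as exactly one of the three classes with prior
  $(\pi_{me3}, \pi_{nuc}-\pi_{me3}, \pi_{free})$; it is a likelihood-ratio
  summary, not a replacement for decoding in genomic context.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script regenerate everything from code:
toy instances ($L \le 4$, $T \le 15$) are verified against exhaustive
enumeration; conservation and forward/backward agreement are checked on
random instances up to $T = 10^4$; the stationary-limit and calibration
checks run at $T = 10^5$ and $T = 10^6$; and the full recovery chain runs
at the generator's defaults ($T = 2\times10^6$, $2\times10^5$ reads per
state).  These sizes are the package's own choice of a convincing yet
quick demonstration; all of them scale linearly if enlarged.

## Known limitations

* Geometric linker lengths and a single fixed nucleosome length; no
  fuzzy/overlapping occupancy beyond what the posterior mixture expresses.
* Two nucleosome classes only; other modifications would need their own
  emission tables and states.
* Emission tables are position-independent within the nucleosome, so
  rotational positioning signals are averaged out.
* Mappability is taken as given (an optional mask), not computed.
* The model predicts sequence *propensity*; H3K4me3 placement driven by
  sequence-independent epigenetic factors is invisible to it — that gap is
  exactly what `false_negative_rate()` quantifies.
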