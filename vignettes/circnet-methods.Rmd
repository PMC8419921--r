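---
title: "circnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`circnet` implements, as one tested pipeline, the computational chain used
to nominate interferon-responsive competing-endogenous-RNA (ceRNA)
networks from bulk RNA-seq of paired patient samples: circRNA discovery
from chimeric split alignments, circular-junction quantification,
differential-expression (DE) screening per RNA class, correlation-gated
circRNA/lncRNA–miRNA–mRNA network assembly, and over-representation of the
resulting gene sets. Because studies of this design rarely deposit raw
patient data, the package ships a synthetic-data generator with planted
ground truth, and every stage is validated by recovery of that truth.

# The back-splice caller

A circRNA's hallmark is its head-to-tail (back-splice) junction: a
downstream splice donor joined to an upstream acceptor, visible as a read
whose partial alignments appear in reverse genomic order. A read supports
a candidate junction when two of its segments map

1. to the same chromosome, no more than 1 Mb apart,
2. on the same strand, and
3. in reverse order relative to their order in the read.

"Reverse order" is strand-aware: on the minus strand the transcript runs
right-to-left, so a back-splice read's segments ascend in genomic
coordinates. Reads whose implied breakpoints agree within 5 nt are pooled
into one candidate (aligners dither breakpoints by a few bases around
repeated context; the merge tolerance is configurable and irrelevant for
exact alignments). Rejected reads are tallied by the first violated rule,
so a run log can be audited decoy by decoy.

## Splice-strength scoring

The exact junction is chosen by maximizing splice-site strength near the
implied breakpoints. We score donor sites over the canonical 9 nt window
(3 exonic + 6 intronic) and acceptors over 23 nt (20 intronic + 3 exonic)
with a position-weight-matrix log-odds model,

$$S(w) = s \sum_{i} \log_2 \frac{p_i(w_i)}{q(w_i)},$$

with background $q$ uniform and scale factor $s$. The PWM content
(`inst/extdata/splice_pwm.tsv`) encodes standard human donor/acceptor base
composition and is a package-defined synthetic model; any other
per-position model — for instance a maximum-entropy table collapsed to
positional weights — can be dropped in through the same file interface.

The scale factor calibrates the score to the call threshold of 10, which
the pipeline treats as its published operating point: under the default
$s = 0.5$ the consensus donor+acceptor pair scores about 17.1, while the
*maximum* score over the ±10 nt search radius in random sequence has mean
≈ −0.7 and SD ≈ 2.5, so the threshold sits roughly four null standard
deviations above chance. (At $s = 1$ random windows crossed 10 in about
0.25% of trials — a calibration, not a property of the data.) Ties in
total score resolve by proximity to the implied breakpoints, then by the
smaller genomic coordinate; both rules are exercised by an enumeration
test.

A candidate becomes a call iff it has **at least 2** supporting reads and
a splicing score **greater than or equal to 10** — both boundaries
inclusive, and both checked at the boundary by tests.

# Junction quantification

For each call we build a pseudo-reference by concatenating the donor-side
flank with the acceptor-side flank so the circular junction sits exactly
at the center (`genome[end-flank, end) ++ genome[start, start+flank)`,
reverse-complemented for minus-strand calls; flanks truncate symmetrically
at chromosome edges or for circles shorter than the flank). A read counts
for a circRNA iff it matches the pseudo-reference exactly, in either
orientation, crossing the center with **at least 6 nt** on both sides.
Synthetic-mode counting is exact-match; a mismatch allowance belongs to
the external realigner in real-data mode and is out of scope. Each read
counts at most once per circRNA.

Normalization is reads-per-million (RPM) for miRNA and circRNA junctions
(no meaningful transcript length) and RPKM for mRNA/lncRNA. Library sizes
are supplied per sample; the generator's libraries are the counted
features plus a large constant mapped background (see below).

# Differential-expression screen

Per feature we report group means on the normalized scale, the fold
change $\log_2\!\big((\bar x_B + \varepsilon)/(\bar x_A +
\varepsilon)\big)$ with $\varepsilon = 1$, and a p value. Status is `up`
iff log2FC > 2 **and** p < 0.01, `down` iff log2FC < −2 and p < 0.01 —
strict inequalities, so a fold change of exactly 2 is not significant.
No multiple-testing correction gates the status (the screen is on raw p);
BH q values are reported alongside for transparency.

Three tests are available: Welch's t on log2-transformed values (module
default), a paired t on per-patient log differences, and two pooled-count
tests (an MA-plot z test under a Poisson random-sampling model, and
Fisher's exact test). The *pipeline's* default is the paired t, because
the design it emulates is paired — the same nine patients sampled before
(group A) and after (group B) therapy — and the generator couples the two
samples of a patient through shared latent factors. The unpaired default
remains on `de_screen()` itself for generic use.

# ceRNA network assembly

Targets are predicted by canonical seed matching: with the seed defined as
miRNA positions 2–7, a site on the target (read 5′→3′) is classified
`8mer` (complement of positions 2–8 followed by A), `7mer-m8`, `7mer-A1`
or `6mer`. The table of predicted edges is interchangeable with an
externally supplied interaction table in the same schema, so exports from
target databases can be dropped in.

Candidate ceRNA–mRNA pairs are those sharing at least one miRNA. Each is
gated by the Pearson correlation of log2(normalized + 2⁻¹⁰) across **all
18 samples pooled**, with the two-sided p from the t transform and BH
adjustment over exactly the tested pair set; an edge is retained iff
r > 0.9 and adjusted p < 0.1 (both strict). Two deliberate choices here:

* *Log scale.* On strongly log-normal abundances the linear-scale Pearson
  of a perfectly coupled pair is systematically below 1 (a pair with
  log-scale correlation 0.96 can fall below the 0.9 gate with no noise at
  all); the log scale makes the gate measure coupling rather than
  skewness. The offset 2⁻¹⁰ only guards zero counts, so noiseless planted
  pairs remain exactly collinear.
* *Pooling.* Pooling both groups maximizes n (18); a within-group option
  exists. Pooled correlation does mix the group effect into r — that is
  precisely the signal a ceRNA pair regulated in the same direction
  should share.

A triplet (ceRNA, miRNA, mRNA) enters the network iff the miRNA has seed
edges to both partners, all three are DE, ceRNA and mRNA share a
direction, the miRNA is DE in the *opposite* direction, and the pair
passed the correlation gate. The miRNA-direction rule is the ceRNA logic
(a sponge de-represses its target); because the direction convention is
the one genuinely ambiguous reading of such analyses, triplets excluded
*solely* by it are logged, and `mirna_rule = "any"` switches the
convention. Four sub-networks are emitted — {circRNA, lncRNA} × {up,
down} — with per-sub-network composition counts, and export to SIF and
GraphML (round-trip safe, node attributes carry class and DE status).

# Enrichment

Network gene sets are tested by hypergeometric over-representation
against user-supplied GMT annotation over an explicit universe, flagged
at raw p < 0.05 (q values reported, not gating). This is the coherent
reading of "GSEA applied to a DE gene list": the input is a set, not a
ranked list, so the permutation walk statistic has nothing to rank and is
out of scope.

# The synthetic-data generator

The generator *defines* the study conditions the pipeline is validated
under; it is first-class, tested code.

**Genome.** Two 100 kb chromosomes carry 60 mRNA, 30 lncRNA and 30 miRNA
genes on random strands (4 exons of 90–130 nt with 40–70 nt introns for
mRNA/lncRNA; single-exon 22 nt miRNAs). Every internal exon boundary is
written with the full consensus donor/acceptor window, so annotated splice
sites are GT..AG sites that score maximally under the packaged PWM.

**Planted circRNAs.** 50 callable back-splice junctions sit on internal
exon-boundary pairs (consensus motifs, depth 10 junction reads); 20 decoys
cycle through six single-rule violations: different chromosome, >1 Mb
separation, opposite strand, forward (linear-splice) order, a single
supporting read, and a weak (motif-free) junction. A >1 Mb decoy cannot
fit on a 100 kb chromosome, so the generator appends a gene-free random
scaffold chromosome for it — the synthetic analogue of the unplaced
scaffolds of real assemblies. Junction reads are 150 nt, emitted as a
primary plus supplementary SAM record sharing the QNAME; the candidate
rules never consult mate information, so reads are written single-end
(insert-size realism is explicitly out of scope). A configurable fraction
of junction reads carries a 5 nt overhang, emitted as a single clipped
record — an aligner would not split on 5 nt — to exercise the overhang
rule. No sequencing-error model; qualities are constant Q30.

**Expression.** Nine patients, paired samples (A = pre, B = post). On the
log2 scale, feature $f$ in patient $p$, group $g \in \{0, 1\}$:

$$\log_2 x_{fpg} = \mu_f + \beta_f\, g + \alpha_f\, z_{f(p)} +
\epsilon_{fpg},$$

with baseline $\mu_f \sim N(10, 1.2)$, planted fold change $\beta_f$
(±4 for triplet members, ±3 for standalone DE features, 0 otherwise),
per-patient latent factors $z \sim N(0,1)$ shared between a patient's two
samples, and noise $\epsilon \sim N(0, \sigma)$ with $\sigma = 0.5$ by
default. Counts are $2^x$ rounded (negative-binomial sampling is
config-selectable); in the noiseless limit rounding is skipped so planted
fold changes and correlations are exact. Within a triplet, the ceRNA and
mRNA share the factor with coefficient $+\alpha$ ($\alpha = 2.2$) and the
miRNA with $-\alpha$: the ceRNA–mRNA pair is exactly collinear in log
space before noise (model correlation 1), while members of different
triplets share only the group shift, giving cross-pair correlation
$\beta^2/4 \,/\, (\beta^2/4 + \alpha^2) \approx 0.45$ — below the 0.5
line that separates "tolerated" from "forbidden" decoy triplets in the
recovery analysis.

Three calibrations make the planted truth a well-defined target, and were
validated over 25 generator seeds (25/25 exact noiseless network
equality; mean noisy recovery 99.3%, zero decoy triplets):

* *Library background.* Per-sample library sizes are the class's counted
  features plus a constant 10⁷ mapped background. Without it the toy
  feature panel *is* the library, and planted 16-fold features inflate
  group-B totals enough that RPM normalization pushes null features past
  the −2 log2FC gate — a compositional artifact real libraries avoid
  because counted features are a sliver of total mapped reads.
* *Dynamic range.* $\mu \sim N(10, 1.2)$ and $\alpha = 2.2$ keep
  normalized values well above the screen's $\varepsilon = 1$ at the low
  tail (where $\varepsilon$ would compress a true fold change of 4 below
  the gate) and keep single heavy-tailed draws from dominating library
  sums at the high tail.
* *Seed hygiene.* Each triplet's miRNA gets an 8mer site written into its
  ceRNA and mRNA sequences (through the genome text, inside exon
  interiors, clear of splice windows). Chance seed matches of DE miRNAs
  in DE transcripts are then scrubbed by single-base mutations —
  transcript positions are exonic, so GT..AG signals are never touched —
  and DE miRNAs are chosen seed-compatible, so no miRNA's 6mer core hides
  inside another triplet's protected site. Non-DE features keep their
  chance matches: realistic target-table noise the DE and correlation
  gates must reject. Triplet circRNAs take distinct host genes, and host
  genes carry no planted DE of their own, because a host transcript
  contains its circRNA's injected site.

**What passing does and does not show.** The generator realizes the
decision structure of the method — thresholds, boundary semantics,
direction conventions, truth recovery under noise — with exact alignments,
no sequencing error, lognormal counts and clean seed biology. Passing
therefore demonstrates correctness of the pipeline's logic, not
performance on real reads: alignment artifacts, overdispersion beyond the
NB option, isoform ambiguity and database-grade target prediction are
deliberately outside the model.

# Numerical and procedural choices

* Coordinates are 0-based half-open internally; BED output follows the
  BED convention.
* Candidate aggregation tolerance 5 nt; junction search radius 10 nt
  (both configurable).
* Degenerate inputs: zero-variance expression vectors are skipped by the
  correlation gate with a logged reason; constant paired differences give
  p = 0 when the shift is nonzero and NA (ns) when zero; windows touching
  a chromosome edge score −∞ and truncate flanks symmetrically with a
  warning; malformed alignment segments (end ≤ start) skip the read with
  a logged reason.
* Determinism: every stochastic step takes a seed, and a fixed
  configuration + seed reproduces byte-identical FASTA/SAM/TSV outputs.
* Problem sizes used in the validation suite: the full study-scale
  configuration above for end-to-end properties; 20 replicate draws for
  Monte-Carlo checks (null calibration at 20 × 1000 features, triplet
  recovery at 20 draws of the 12 planted triplets); brute-force oracle
  comparisons on 20 random alignment sets of 250 two-segment reads, with
  closed-form checks for correlation/BH and exhaustive enumeration for
  hypergeometric tails at N ≤ 30.

# Known limitations

* The splice model is positional (PWM); it reproduces MaxEntScan's window
  geometry and decision role, not its higher-order dependencies.
* Real-data mode consumes aligner output; no realignment, no CIRI-style
  paired chiastic clipping re-derivation, no isoform-level quantification.
* Seed matching ignores thermodynamics and conservation; database-grade
  prediction should be supplied as an external interaction table.
* The 9-patient paired design is small; the correlation gate at n = 18 is
  validated for the planted effect sizes, not for marginal ones.
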