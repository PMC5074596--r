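---
title: "Virtual-primer contig elongation: model, parameters and design"
author: "vpseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-primer contig elongation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpseq)
```

## The problem

De Bruijn graph assemblers (Trinity and kin) fragment transcripts wherever
read depth dips, so a de novo transcriptome typically contains many contigs
whose open reading frames are cut off at one or both ends. Full-length ORFs
are what downstream annotation, phylogenetics and heterologous expression
need. `vpseq` elongates such contigs after assembly by a local
overlap-consensus procedure — effectively an in silico RACE: the terminal
20 bp of a contig is used as a "virtual primer" to fish reads out of a hash
table, the recruited reads are piled on the contig end, and new bases are
called one position at a time from posterior nucleotide probabilities. The
procedure iterates, redesigning the primers from the newly extended ends,
until neither end grows.

Because only the two contig ends are ever searched, the cost is linear in
reads times contigs, not quadratic in reads as for a full
overlap-layout-consensus assembly.

## The consensus model

At a candidate extension position $i$ (counting outward from the contig
terminus), let $N(nt \mid i)$ be the number of recruited reads showing
nucleotide $nt \in \{A,C,G,T\}$ there and $N(i) = \sum_{nt} N(nt \mid i)$
the pile-up depth. With a pseudo-count $n$ (default 20) the posterior is

$$\Pr(nt, i) \;=\; \frac{N(nt \mid i) + n/4}{N(i) + n}.$$

The four posteriors sum to one by construction. For a two-base IUPAC code
(R, Y, K, M, S, W) the posterior is the sum of its two component-base
posteriors. The calling rule at threshold $p$ (default 0.8) is, in order:

1. if $\max_{nt}\Pr(nt,i) \ge p$, call that base (ties A<C<G<T);
2. else if the best two-base code reaches $p$, **both** of its component
   bases are actually observed in the column, and the previously called
   character is an unambiguous base, call the code (ties R<Y<K<M<S<W);
3. else stop elongating at this end for this round.

Three consequences worth knowing:

* **A minimum calling depth.** A unanimous column calls its base only when
  $(N + n/4)/(N + n) \ge p$, i.e. $N \ge (pn - n/4)/(1-p)$ — 55 reads at
  the defaults. Low-coverage contig ends simply do not extend, which is the
  method's built-in error guard.
* **Both-alleles requirement.** Without the "both components observed"
  condition in branch 2, a unanimous column just below the calling depth
  would be promoted into a spurious ambiguity call purely by the
  pseudo-count share of a base that no read supports (at $N(A)=54$,
  $\Pr(R) = 64/74 \approx 0.865$). A code is a claim of two observed
  alleles, so we require evidence for both.
* **No successive ambiguity codes.** Branch 2 is gated on the previous call
  being a plain base, which keeps low-complexity or contaminating pile-ups
  from painting runs of ambiguity codes. At most every second emitted
  character can be a code.

## Read recruitment

Reads are held in a hash table keyed by every exact 10-mer of every read,
both strands, with pairing information deliberately discarded. A 20-bp
primer is located by looking up its two 10-mer halves and verifying the
full 20 positions under IUPAC set matching; by the pigeonhole principle any
occurrence with at most one mismatch has at least one exact half, so the
one-mismatch search is complete. An `N` in a read matches nothing, so
undetermined bases never feed the consensus.

Round 1 primers come straight from the assembler's contigs and are searched
with a one-mismatch budget — that is what lets reads carrying a sequencing
error or the other allele of a heterozygous site join the first pile-up.
Later rounds instead inherit any ambiguity codes the consensus has emitted
into the terminal 20-mer (ambiguous positions are expanded during key
lookup, at most 16 keys per half; a half with more than two ambiguous
positions contributes no keys and the other half carries the search), and
are searched exactly. Whether later rounds should also enjoy a mismatch
budget is not knowable from the method description; the default is no, and
`vp_params(later_mismatch = 1)` overrides it.

The 5' end is extended as the 3' end of the reverse-complemented contig,
which guarantees the two ends behave symmetrically. Minus-strand hits
contribute the read's reverse complement. A read containing the primer more
than once is anchored once per occurrence. Extension is fully
deterministic: there is no randomness anywhere in the engine, and contigs
are processed independently, so permuting the input permutes the output.

Each round recruits once from the fixed primer and then calls outward until
the rule refuses; bases called within a round do not re-recruit until the
next round redesigns the primer. With 101-bp reads a round can add at most
81 bp, and in practice adds ~50 bp before depth falls below the calling
floor, so a 150-bp truncation takes about three rounds per end. A safety
cap (`max_rounds`, default 100) bounds pathological cases; termination
otherwise happens naturally when a full round adds nothing to either end.
The input contig is preserved verbatim as a contiguous substring of the
output (`core_span` records it): the mismatch allowance affects recruitment
only and never rewrites the template.

## Read cleaning

Two bespoke rules accompany the method. PCR duplicates: two reads are
duplicates when their first 10 bases are identical **and** positional
identity over the shorter read strictly exceeds 90%; reads are bucketed by
prefix and the first occurrence is kept. No alignment is attempted —
fixed-length Illumina reads are compared position by position. Quality
trimming: base calling starts at the first run of five Phred scores
strictly above 30 and stops just before the position at which the
cumulative fraction of bases at Q30 or better (counted from the start
position) drops to 0.5 or below. The description of the stop rule does not
say whether the fraction is windowed or cumulative; the cumulative reading
is implemented and tested against a literal reference implementation.
Surviving reads shorter than 10 bp (the duplicate-prefix key) are dropped.
Adapter removal is assumed done upstream.

Note that perfectly error-free simulated reads sharing a start position are
*bona fide* PCR duplicates under the rule; pipelines on synthetic data
therefore run extension on uncleaned reads (`run_pipeline(clean = FALSE)`).

## ORF completeness

`classify_orf()` reimplements an alignment-guided completeness classifier.
With a protein hit (best blastx hit per contig, e-value then bitscore), in
the hit's frame: the 3' end is complete iff an in-frame stop occurs at or
after the aligned query end, and the 5' end is complete iff an in-frame ATG
lies at or before the aligned query start and either an in-frame stop sits
upstream of it or the alignment starts within 15 residues of the subject
N-terminus.

Without a hit, all six frames are scanned for maximal stop-free segments
and the candidate with the longest coding stretch wins (featureless
segments — no ATG, no stop — only stand when nothing with coding evidence
exists; ties prefer more evidence). Start evidence then requires an
in-frame stop upstream of the ATG. An alternative rule — accepting any ATG
with at least `min_utr5` nucleotides of open 5' sequence — is exposed but
disabled by default: under that rule a 5'-truncated CDS fragment is
classified full-length through whichever internal ATG comes first, which
inverts the statistic the classifier exists to measure. Both knobs live in
`orf_params()`. These rules are a documented stand-in for the cited
classifier's unpublished internals, not a claim of bit-compatibility.

## Contig redundancy

`pair_distance()` maps a contig pair to $1 - M/\min(|a|,|b|)$, where $M$ is
the *effective overlap*: the score of the best end-gap-free (overlap)
alignment over both relative orientations, at +1 match / -1 mismatch / -2
gap, with intersecting IUPAC sets counting as matches, floored at zero. On
a clean overlap the score equals the number of matched positions, so
identical sequences and contained fragments score distance 0; between
unrelated sequences the best spurious alignment has near-zero score, so
the distance sits near 1. (The raw matched-position count would not do:
under this scoring the best spurious alignment of two unrelated 300-mers
still carries ~30 matched positions.) Candidate pairs are restricted to
contigs sharing an exact 20-mer, which avoids all-vs-all alignment;
`find_redundant()` single-links pairs at distance <= `d_max` (default
0.05, tolerant of ambiguity codes and rare variants) and reports the
longest member of each cluster as representative. Supplying the
post-extension sequences flags *asymmetric fragments*: pairs distant
before extension but redundant after — non-overlapping 5' and 3' pieces of
one transcript that elongation has united.

## Quantification and enrichment

The internal mapper assigns a read to every contig that contains it with at
most one penalized mismatch, mismatches at read positions below Q20 being
free; a read matching $k$ contigs contributes $1/k$ to each, and
$\mathrm{FPKM} = 10^9 c / (L \cdot T)$ with $c$ assigned fragments, $L$ the
contig length and $T$ total assigned fragments. Differential classes use an
FPKM floor of 0.1 (both samples at or below it: not expressed) and a log2
ratio cut of ±2, with a pseudo-FPKM of 0.01 in the ratio to avoid log of
zero. GO-term enrichment between two gene sets is
$\log_2 \frac{(N_A + 0.05)/N_{tot,A}}{(N_B + 0.05)/N_{tot,B}}$, the 0.05
pseudo-count rescuing empty numerators; the direction convention is
abstract (sets A and B), and `enrich_table()` reports both orientations.

## Phylogenetic clustering

`upgma()` takes an externally computed distance matrix (multiple alignment
and distance estimation are jobs for an aligner, not this package; a k-mer
Jaccard distance is bundled for self-contained examples) and builds the
standard UPGMA tree: closest pair merged, node at half the merge distance,
distances to the merged cluster as size-weighted means. Ties break by the
lexicographically smallest label pair, making the tree reproducible.
`cut_tree()` flattens it either at a height or into exactly `k` clusters,
and `species_tally()` categorizes clusters by how many of the four species
contribute members (singleton / one / two / three / all). The independent
cross-check in the tests is `stats::hclust(method = "average")` plus
`stats::cutree`. Bootstrap support is out of scope — it resamples alignment
columns, which this package never holds.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates transcripts with a planted complete ORF
(an in-frame stop just upstream of the ATG, sense codons, a stop codon,
UTRs of 60–140 / 80–250 bp), optional biallelic 50/50 heterozygous sites,
fixed-length reads with substitution errors and realistic Phred strings
(Q40 core decaying to Q25 over the last 15 cycles), and contigs truncated
by fixed amounts at each end. Defaults mirror the study conditions the
engine targets: 101-bp reads, 200x coverage, 0.1% substitution error,
5x10^-4 heterozygosity, 150-bp truncations.

Read starts are uniform, *including* fragments that overhang a transcript
end: such fragments are clipped to the transcript and kept when at least
20 bp remain, the way end fragments survive adapter trimming in a real
library. This detail matters: were read starts confined to the interior,
the depth available for calling a base $p$ bp from the transcript end
would be at most $\text{cov} \cdot p/|read|$ (~$2p$ at 200x), so terminal
bases could never reach the depth-55 calling floor and no coverage would
ever recover a full template. Conversely the simulator has no indels, no
3' coverage bias, no chimeras and no assembler artifacts beyond
end-truncation — passing tests demonstrate the engine's correctness under
its own model, not robustness to every artifact of real libraries.

Everything is reproducible from the config seed. `evaluate_extension()`
scores results against the gold standard: fraction of truncated bases
recovered, per-base identity (an ambiguity code is correct iff its set
contains the true allele(s); at a het site the exact two-allele code is
what the het recall counts), and ORF class before/after.

## Numerical choices and problem sizes

Threshold comparisons are inclusive (`>= 0.8`), matching the calling rule
as printed. The posterior denominator is $N + n$ — the unique reading under
which the posteriors normalize (and the one that fixes the depth-55
boundary). All tie-breaks are lexicographic and documented above. The test
suite exercises the engine at the full study conditions (50 transcripts of
0.9–3 kb at 200x, ~190k reads, ~37M indexed 10-mer positions — the k-mer
store and primer search are C++ for this reason) and completes in about two
minutes; the acceptance script repeats the measurements from scratch in
under a minute.

## Known limitations

* Extension cannot cross regions with zero read support or depth below the
  calling floor; it fills truncated ends, it does not scaffold.
* More than two alleles at a site, or allele ratios far from 50/50, will
  not be represented (three/four-base codes are read but never written).
* The quantification mapper is a seeded heuristic, not a full aligner;
  externally computed count tables can be substituted.
* The ORF classifier's fallback path is heuristic by necessity; supply
  protein hits where available.
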