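---
title: "Predicting pseudoknotted RNA secondary structure by sequence labelling and compatible stem assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pseudoknotted RNA secondary structure by sequence labelling and compatible stem assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An RNA secondary structure is a set of base pairs over a single sequence,
with three admissible pairings: the Watson-Crick pairs A-U and G-C and the
G-U wobble.  Most prediction tools restrict themselves to *nested*
structures, where no two pairs $(i_1, j_1)$, $(i_2, j_2)$ interleave as
$i_1 < i_2 < j_1 < j_2$.  Pseudoknots are exactly such interleavings, they
occur in tmRNA, rRNA and many viral RNAs, and they matter functionally —
but they make energy-minimisation NP-hard, which is why many tools simply
exclude them.

`knotfold` takes a different route, in two stages:

1. **Prediction unit** — a per-base sequence labeller assigns each
   nucleotide one of seven symbols of the *extended dot-bracket* alphabet
   `( ) [ ] { } .`.  Any structure whose pairs can be partitioned into at
   most three internally non-crossing layers is representable this way,
   one bracket class per layer; crossings *between* classes encode the
   pseudoknots.
2. **Correction unit** — the labelling is noisy, and a labelling is not
   yet a structure: brackets need not balance and labelled partners need
   not be complementary.  The correction unit therefore treats maximal
   runs of one bracket symbol as *prediction complementary regions* (PCRs)
   — hypotheses about stem sides — and assembles an optimal set of
   mutually compatible stems supported by those hypotheses, maximising the
   number of paired bases.  This base-pair-maximisation framing uses no
   thermodynamic parameters at all; the sequence-specific signal all comes
   from the labeller.

Both stages are independently testable: the labeller can be replaced by an
*oracle* that emits the true labelling corrupted at a configurable rate,
which is how the correction unit's behaviour under controlled error is
measured.

## Structure representation

A `secondary_structure` is a length plus a set of 1-based pairs $(i, j)$,
$i < j$, each position in at most one pair; crossings are legal.
Conversion to dot-bracket requires assigning each pair to one of three
layers so that no layer contains a crossing.  The assignment algorithm is
greedy first-fit: pairs sorted by $(i$ ascending, $j$ descending$)$, each
placed in the lowest-index layer where it crosses nothing.  This is
deterministic, assigns nested helices to the lowest class, and handles
every structure of page number at most three; structures needing a fourth
layer are rejected with an error naming the offending pair.  Which
crossing stem lands in which class in a tie is a convention of this
package, not a property of the science; all downstream code treats the
three classes symmetrically.

CT (6-column) and BPSEQ (3-column) files are read and written with
reciprocal-pairing validation; since those formats store raw pairs they
round-trip pseudoknots verbatim.

## The labeller

The encoder is a stacked bidirectional LSTM.  Each base is one-hot encoded
as an 8-bit vector (A, U, G, C each map to a fixed row; the padding base N
to all-zeros).  The LSTM cell uses peephole connections — the input and
forget gates see the previous cell state, the output gate the current one:

$$
\begin{aligned}
i_t &= \sigma(x_t W_i + h_{t-1} U_i + c_{t-1} \odot p_i + b_i)\\
f_t &= \sigma(x_t W_f + h_{t-1} U_f + c_{t-1} \odot p_f + b_f)\\
c_t &= f_t \odot c_{t-1} + i_t \odot \tanh(x_t W_c + h_{t-1} U_c + b_c)\\
o_t &= \sigma(x_t W_o + h_{t-1} U_o + c_t \odot p_o + b_o)\\
h_t &= o_t \odot \tanh(c_t)
\end{aligned}
$$

Forward and backward hidden states (300 units each at full scale) are
concatenated into a 600-vector per position, fed to a fully connected
decoder with layer widths 600–1024–512–7 and ReLU activations.  The seven
output scores are hardened by argmax into a symbol.  Training minimises
softmax cross-entropy with Adam, initial learning rate 0.002, weights
initialised from a normal with standard deviation 0.1, dropout with keep
probability 0.9 in encoder and decoder, 50 epochs with a per-epoch
multiplicative learning-rate decay.

Design choices where the design was genuinely open:

* **Dropout of "0.9"** is read as *keep* probability 0.9 (drop rate 0.1).
  A 90% drop rate would cripple training; 0.9 keep-probability is the
  conventional reading of that framework era.  Configurable.
* **Decay schedule**: exponential, ×0.96 per epoch by default,
  configurable; only the monotone non-increase is relied on.
* **Padding labels** are the all-zero 7-vector and are masked out of both
  the loss and the accuracy, so the model cannot inflate its score on
  padding.  Whether full-scale accuracy figures elsewhere count padding is
  unknowable from the outside; excluding it is the conservative choice.
* **Batch size** (unspecified upstream): default 32.

The implementation is plain vectorised R with hand-derived
backpropagation through time; every gradient is verified against central
finite differences in the test suite (worst relative error below
$10^{-3}$ on a two-layer peephole model).  At the scales the package
trains in its tests this is entirely adequate, and it keeps the package
free of heavyweight runtime dependencies.

### Windowing

Sequences are processed in windows of 300 bases.  Shorter sequences are
padded with N; longer ones are cut into windows starting at positions
1, 101, 201, … (consecutive windows overlap by 200), the last window
padded.  When overlapping windows disagree about a position, the symbol
comes from the window whose midpoint is nearest the position (ties to the
earlier window): a bidirectional encoder has the richest context at its
centre.  The merge rule is this package's choice; the splice itself is
required but its tie-breaking is not prescribed anywhere.

## The correction unit

### Definitions

For a sequence of length $n$, the **pair matrix** is the upper-triangular
boolean matrix with a 1 wherever positions $(i, j)$ can pair (complementary
under A-U/G-C/G-U and $j - i \ge \texttt{min\_loop} + 1$).  A **stem**
$(S, E, L)$ is a run of $L$ stacked pairs $(S+k, E-k)$, a diagonal in the
matrix.  Defaults `min_stem_len = 2` and `min_loop = 3` are standard
sterics; both are configurable, and neither is prescribed upstream.

Two stems are **compatible** when they can coexist in one pseudoknot-free
substructure: their occupied bases are disjoint and their pairs do not
cross — equivalently they are fully separated, or one lies entirely inside
the other's loop.  The literal printed inequalities for this predicate in
the source literature admit stem pairs whose 3′ regions share bases (for
example $(1,20,3)$ and $(5,19,2)$ overlap at bases 18–19 yet satisfy the
third clause); since a base cannot take part in two pairs, the package
implements the evident intent as the default and retains the literal form
behind `literal = TRUE` purely for comparison.

A **PCR** is a maximal run of one bracket symbol: runs of an opening
symbol are 5′ hypotheses, runs of a closing symbol 3′ hypotheses, and the
three bracket classes partition the PCRs into three independent sets.

The **usage rate** of a stem combination over a PCR group with $H$ 5′
bases and $G$ 3′ bases is $\tfrac{1}{2}(h/H + g/G)$, where $h$ and $g$
count the combination's 5′- and 3′-side bases falling inside the group's
PCRs.  A rate of 1 means the combination explains every labelled base.

### The combination search (CSCP)

Candidate stems are combined by priority: longer stems first.  The search
grows a tree of combinations layer by layer; at each priority layer, each
node is extended by the *largest* subsets of that layer's stems that are
pairwise compatible and compatible with everything already in the node
(all tying subsets spawn children; a node with no compatible stem passes
down unchanged).  The leaves are the optimal combinations: each is
pairwise compatible, contains the initial set, and is maximal — no unused
candidate can be added.  The per-layer subproblem is a maximum-clique
search on the compatibility graph, solved exactly via igraph.  Because
the tree can branch on ties, its width is capped (default 50 nodes per
layer) with deterministic pruning by score then lexicographic order, and
equal-score leaves are ordered lexicographically by their sorted
$(S, E)$ triples — the upstream description leaves tie-breaking among
equal leaves open, so determinism is imposed here.  An unpruned
brute-force reference implementation (`cscp_brute`, direct recursive
subset enumeration) is part of the package and serves as the oracle in
the tests: with the cap disabled the two agree exactly on hundreds of
random instances.

### The three selection steps

Each bracket class is processed independently through three steps.  In
each step, PCR groups are enumerated; groups whose smallest-position PCR
is 3′ or largest-position PCR is 5′ cannot form stems and are discarded.
For each surviving group, candidate stems are collected from the pair
matrix restricted to the rectangles spanned by each ordered (5′, 3′) PCR
pair ($i \le j < p \le q$), a first CSCP (empty initial set) finds the
group's best combination, and the group's usage rate decides acceptance:

* **Step 1** examines groups of size $n = 2$, then 3, then 4, accepts only
  complete usage (rate $= 1$), and after each group size removes every PCR
  that contributed a base to the running optimal set.  PCRs are removed
  whole: they are atomic hypotheses, and a partially used PCR was already
  explained by the accepted stems.
* **Step 2** examines pairs and accepts when a *single side* is fully used
  (5′-rate $= 1$ or 3′-rate $= 1$) — the other side's surplus is labelling
  noise; fully used sides are removed.
* **Step 3** examines pairs and accepts when the rate strictly exceeds
  0.6 (the threshold is applied as a strict inequality, as printed).

After each step's groups are processed, the accepted stems are pooled and
a second CSCP, seeded with the running optimal set, produces the updated
optimal combinations.  Two readings were left open upstream and resolved
here: the rate is computed on the *best* first-kind combination (not on
all of them), and on unextended stems (extension happens once, at the
end, not before rate computation).

### Extension and cross-class combination

The per-class optimal stems are then extended along their maximal
diagonals in the pair matrix, one pair at a time, alternating the outer
end $(S-1, E+1)$ and the inner end $(S+L, E-L)$, longest stem first (then
by $S$); growth in a direction stops as soon as the next pair is not
pairable or touches a base used by any other stem or extension.  Stepwise
growth with base blocking provably cannot introduce a crossing, so
extension preserves compatibility, never lowers the score, and is
idempotent.

Finally one optimal combination per class (up to `k_keep = 3` are
retained per class) is chosen in every combination of the three classes.
Crossings between classes are kept — they are the pseudoknots.  If two
classes claim the same base (possible under noise), the class whose
combination scores higher wins and the losing stem is trimmed from its
conflicting end, dropped entirely if it falls below `min_stem_len`.  The
assembled structures are ranked by total paired bases with a
lexicographic tie-break; in benchmark mode, when a reference structure is
available, the candidate with the highest F-score against the reference
is selected instead, mirroring the evaluation protocol of the literature
this method descends from.

## Evaluation

Predictions are scored at the base-pair level: $TP$ exact pair matches,
$SEN = TP/(TP+FN)$, $PPV = TP/(TP+FP)$, and their harmonic mean
$F = 2 \cdot SEN \cdot PPV / (SEN + PPV)$.  Pair-level comparison makes
pseudoknotted and pseudoknot-free predictions commensurable.  The printed
form of the F formula in the source text, $2\,(SEN+PPV)/(SEN \cdot PPV)$,
is a misprint — it is not the harmonic mean the text announces and
exceeds 1 — so the harmonic mean is implemented, with the literal form
available behind a debug flag.  When both prediction and reference are
empty all three metrics are defined as 1 (a correctly predicted
unstructured RNA is a perfect prediction); an empty prediction of a
structured reference scores 0.

## The synthetic generator

Because the full-scale training corpus is external and training the
full-width model takes hours, the package ships a generator that plants
stems in random sequences so every stage is testable from first
principles.  An instance draws a length (default 70–150 nt), a stem count
(2–4), stem lengths (3–6 stacked pairs) and, with probability `pk_prob`,
a forced pseudoknot; paired bases are drawn from the admissible pairings
with a 10% G-U wobble fraction, and at least one unpaired base separates
any two stem sides so that a perfect labelling's PCRs coincide exactly
with the planted stem sides.

In **unambiguous mode** the instance is certified by exhaustive
enumeration: within every ordered PCR-area rectangle, every non-planted
candidate stem is strictly shorter than both parent planted stems, and
the planted combination is inextensible.  Under that certificate a
perfect labelling has a unique best interpretation and the correction
unit must recover the planted structure exactly (F = 1); this is asserted
over hundreds of instances, at least a quarter pseudoknotted, in the
test suite.

The noise model corrupts the true labelling either by i.i.d. per-symbol
substitution at rate $\varepsilon$ (the simplest model that exercises the
usage-rate thresholds) or by shifting the boundaries of bracket runs by
1–2 positions, calibrated so the expected changed fraction is about
$\varepsilon$ — run-boundary error is the characteristic failure mode of
a per-base labeller and precisely what the usage-rate machinery is
designed to absorb.

What the generator does *not* emulate: the family structure, length
distribution and sequence composition of real RNA corpora
(5S rRNA/tRNA/tmRNA/RNase P), thermodynamic plausibility of the planted
stems, and correlated labeller errors beyond run-boundary shifts.
Passing the synthetic suite therefore demonstrates algorithmic
correctness of the pipeline under its stated error models, not benchmark
accuracy on real families; reproducing published per-family accuracy
would require the external corpus and full training, which the
command-line interface supports but the tests deliberately do not
attempt.

## Problem sizes and numerical choices

The test and acceptance workloads are sized to run comfortably on a
single CPU: 1,000 structures for conversion round trips; 200 random
instances (≤ 12 candidate stems) for the search-vs-oracle comparison;
200 certified unambiguous instances (≥ 50 pseudoknotted) for zero-noise
recovery; 100 instances per noise level over
$\varepsilon \in \{0, 0.05, 0.1, 0.2\}$; and a reduced labeller (2
bidirectional layers, 24 hidden units per direction) overfitted on 20
windows for the training smoke test — chosen as the smallest network
that cleanly memorises 20 windows in about two minutes of CPU time.
Search width is capped at 50 nodes per layer; all tie-breaks are
lexicographic; all randomness flows from explicit integer seeds, and
every dataset manifest records per-instance seeds for exact replay.

## Known limitations

* Scoring is base-pair count only; no thermodynamics, no partition
  function, no suboptimal ensemble.
* At most three bracket classes: structures of page number ≥ 4 (extremely
  rare in known RNAs) are rejected rather than approximated.
* PCR group enumeration is combinatorial in the number of PCRs per class;
  heavily corrupted labellings of long sequences make step 1 expensive.
  The coverage prefilters keep the common cases fast, but worst-case
  inputs exist.
* The labeller implementation favours transparency over speed; full-scale
  (300-unit, 3-layer) training is supported but slow in R, and is not
  exercised by the tests.
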