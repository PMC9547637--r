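---
title: "Privacy-preserving record linkage and intersection cardinality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving record linkage and intersection cardinality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilinkr)
```

## The problem

Two medical institutions each hold a table of patient identifying data
(IDAT: names, birth date, ZIP, city) and want to know **how many patients
they have in common** — for example to judge whether a joint rare-disease
study is feasible — without either side disclosing a single patient record
to the other, and without a trusted third party seeing identifiers.
Exact-match set intersection is useless on IDAT, which is riddled with
typos, swapped name fields, relocations and missing values.  What is
needed is *fault-tolerant* record linkage, evaluated obliviously.

epilinkr implements this pipeline end to end in R:

1. a plaintext **EpiLink-style probabilistic linkage engine** over
   Bloom-filter field encodings (the reference implementation and oracle),
2. the same scoring and classification logic compiled onto
   **full-threshold secret shares** (Boolean XOR sharing with Beaver-triple
   AND, additive sharing modulo $2^\ell$), revealing only two counts,
3. a **synthetic patient data generator** with controlled overlap
   structure and a corruption model, so all of it is testable without real
   patient data.

## Record similarity

Each configured field is compared either exactly (`binary`, e.g. year of
birth) or fuzzily (`dice`).  Fuzzy string comparison tokenizes the
normalized value into bigrams, hashes each bigram with $k$ hash functions
into an $m$-bit Bloom filter, and scores two filters with the Dice
coefficient

$$ S \;=\; \frac{2\,\mathrm{Hw}(\mathrm{Bl}(x) \wedge \mathrm{Bl}(y))}
               {\mathrm{Hw}(\mathrm{Bl}(x)) + \mathrm{Hw}(\mathrm{Bl}(y))}, $$

where $\mathrm{Hw}$ is the Hamming weight.  A single substituted character
touches at most two bigrams and therefore at most $2 \cdot 2k$ filter
bits, which is what makes the encoding fault-tolerant.  The Bloom filter
is used purely as a similarity data structure, *not* as a privacy
mechanism — privacy comes from the secret sharing layer.  The $k$ hash
functions are realized by double hashing,
$g_j = (h_1 + j\,h_2) \bmod m$, where $h_1, h_2$ are 48-bit slices of
`SHA-256(salt || 0x01 || bigram)`; 48 bits keep every value exactly
representable in an R double, and since indices are reduced modulo $m$ the
slice width is otherwise immaterial.  The construction is a deterministic
function of (value, $m$, $k$, $n$, salt), so both parties encode
bit-identically — a hard cross-party contract that also covers value
normalization (NFKD, strip combining marks, uppercase, strip
non-alphanumerics except internal spaces, collapse whitespace; empty
becomes *absent*).

Field similarities combine into a record score as a normalized weighted
sum over the fields present on both sides,
$s(x,y) = \sum_{i \in D} w_i s_i / \sum_{i \in D} w_i$; a missing field
drops out of numerator and denominator alike.  Weights derive from field
error rates $e_i$ and value frequencies $f_i$ by the classical log-odds
convention $w_i = \log_2((1-e_i)/f_i)$ — rare, reliable fields count more.
The score is compared against two thresholds (ties upward): below the
lower one the pair is a non-match, at or above the upper one a match, in
between a *tentative match* for manual review.

**Exchange groups.** First name, surname and birth name are easily swapped
at data entry, so the three name fields form an exchange group: every
permutation of one side's group values against the other side's slots is
scored, and the permutation maximizing the resulting record score wins.
Weights belong to the slots (they encode the slot's error statistics), and
slots with a missing member drop out per permutation.  A consequence worth
knowing: with *unequal* slot weights the score is not exactly symmetric
under swapping the two records when group fields are missing or permuted —
the weight attaches to the fixed-slot side.  This is inherent to
slot-weighted permutation matching; with equal group weights the score is
symmetric, and the package's tests check the permutation maximum against a
brute-force oracle in all cases.

## Default configuration

The default is the common eight-field patient configuration: first name,
surname, birth name (exchange group, Dice, $m = 500$, $k = 15$), day,
month and year of birth, ZIP (exact), and city (Dice).  The numeric error
rates and frequencies — and everything downstream of them — are this
package's documented placeholder calibration, chosen as plausible for
German registry data (e.g. birth-year frequency $1/70$, ZIP $10^{-3}$);
real deployments should calibrate against their own data.  Thresholds
default to 0.7 (tentative) and 0.9 (match).  All of it is configurable via
`linkage_config()` or a JSON/YAML file.

## Fixed-point arithmetic

Secret-sharing circuits compute over integers, so the secure path (and the
plaintext `mode = "fixedpoint"` engine that serves as its exactness
oracle) uses:

* similarities as $\lfloor 2^p s_i \rfloor$ with $p = 16$ fractional bits
  (per-field quantization error below $2^{-p}$, record-score error below
  `fields` $\cdot\, 2^{-p}$),
* weights as $\tilde w_i = \mathrm{round}(W w_i)$ with $W = 64$,
* the record score as the pair $(N, M) = (\sum \tilde w_i s^{fp}_i,
  \sum \tilde w_i \cdot \mathrm{present}_i)$, never actually divided:
  thresholds $t = t_{num}/t_{den}$ are tested by cross-multiplication
  $N t_{den} \ge t_{num} M 2^p$, and exchange-group candidates are
  compared as $N_a M_b > N_b M_a$,
* a candidate with $M = 0$ (no field present in any slot pairing) is
  canonicalized to $(0, 1)$, i.e. score 0, before the tournament.

The ring width defaults to $\ell = 48$: all ring elements live in doubles,
and a 24-bit limb-split multiplication keeps every product exact; the
configuration loader verifies at load time that the largest possible
circuit intermediate (including the tournament cross-products) stays below
$2^{\ell-1}$, the soundness bound of the sign-based comparison.  Sums of
many ring elements are reduced in 16-element chunks so no partial sum
leaves the exactly-representable range.  With the default configuration
the worst-case intermediate needs about 43 bits, leaving headroom.

## The oblivious circuit

Party 1 holds dataset $A$, party 2 dataset $B$.  After comparing
configuration fingerprints in clear (mismatch aborts before anything is
shared), each party secret-shares its encodings: Bloom filter bits and
presence flags as XOR shares, Hamming weights as additive shares, exact
fields as 32-bit salted token hashes (collision probability $2^{-32}$ per
comparison).  For every record pair, vectorized across all pairs:

* **Dice fields:** bitwise Beaver-AND of the shared filters, per-bit
  conversion to arithmetic shares (one dealer bit-correlation each), local
  summation into the shared intersection weight, then a restoring
  long-division circuit computes $\lfloor 2 \cdot 2^p \mathrm{Hw}_\wedge /
  (\mathrm{Hw}_x + \mathrm{Hw}_y)\rfloor$ on Boolean shares.  Because the
  quotient never exceeds $2^p$, the top numerator iterations shift bits
  into the remainder without a subtraction.  A zero denominator (absent
  field) yields garbage that is multiplied away by the presence bit.
* **Binary fields:** XNOR-AND-tree equality of the hash bits, gated by
  presence.
* **Scoring:** the $(N, M)$ accumulation, per-permutation candidates,
  canonicalization and the mux-based tournament described above, with
  oblivious comparisons implemented as the sign bit of a shared
  subtraction extracted through an $\ell$-bit shared adder.
* **Aggregation:** per-pair match/tentative bits are OR-reduced over $B$
  (NOT-AND trees), converted, and summed into two shared counters.

Only those two counters are ever reconstructed.  The returned statistics
audit this: `reveals == 2`, with all other interaction being openings of
uniformly masked Beaver/conversion values whose distribution is
input-independent (a property the test suite checks empirically on
transcripts — a sanity check, not a security proof).

## Setup/online phases and the dealer

All correlated randomness (Boolean and arithmetic Beaver triples, bit
conversion correlations) is produced before any input-dependent work, in a
setup phase, and the online phase can only consume it — exhaustion is an
error, never silent regeneration.  Because the circuit is data-oblivious,
its consumable requirements depend only on dataset sizes and
configuration; the setup phase measures them with a profiling pass over
the circuit (zeroed shares, no communication) and then generates exactly
that much.  Profiles are cached per circuit shape.

The original system obtains this randomness from oblivious-transfer
extension between the two parties.  Here a **trusted dealer** generates it
instead: correctness, the phase structure and the online protocol are
identical, but the trust model is weaker — the dealer must not collude
with either party.  This is a deliberate, documented simplification;
treat the implementation as a faithful functional model of the protocol,
not as a hardened cryptographic artifact.  (Neither OT extension, garbled
circuits, malicious security, nor any transport hardening are in scope;
both parties run lock-step in one process, with every transmitted payload
passing through a channel object that records transcripts and byte
counts.)

## Synthetic data

`generate_overlapping_datasets()` reproduces the three-institution
evaluation design: three datasets of `n_per_dataset` records each, a
configurable number of persons appearing in exactly one pair of datasets
(`pairwise_overlap`, per pair), `triple_overlap` persons in all three, the
rest unique — with exact machine-readable ground truth.  Identities come
from packaged German name/city pools with uniform birth dates and ZIPs and
are deduplicated by rejection; the birth name equals the surname except
for a 20% married-name deviation.  Duplicate copies (never the canonical
record) pass through a per-field corruption model: character substitution
(3%), deletion (1%), exchange-group field swap (1%) and field drop (2%)
by default — low rates, as is realistic for registry IDAT.

Scale: the package's reference composition uses 2,000 records per dataset
with 200 pairwise-exclusive overlaps and 8 triple-overlap persons; the
composition parameters are free, so the full-scale variant (18,000 per
dataset) is one argument away.  The generator emulates overlap structure
and entry noise; it does **not** emulate realistic name/birthday frequency
distributions (pools are uniform), household correlations, or temporally
drifting identities.  Passing the recovery tests therefore demonstrates
correctness of the linkage machinery under controlled noise, not
field-realistic precision/recall.

## Numerical and design choices

* Ties at either threshold classify upward; tournament ties keep the
  earlier permutation (deterministic, mirrored exactly by both engines).
* `link_pair()` breaks best-match ties toward the lowest index of the
  right-hand dataset.
* Intersection cardinality counts left-side records with at least one
  match (no one-to-one assignment); tentative counts are reported
  separately as records whose best class is tentative.  Three-way overlap
  composes two pairwise linkages.
* Dice of two empty filters is defined as 0 (defensive; cannot occur for
  present values).  All-fields-missing pairs score 0.
* n-grams are unpadded by default (`padded = TRUE` available); strings
  shorter than $n$ yield themselves as a single token.
* Per-dataset problem sizes in the test suite (2,000-record overlap
  recovery, 100×100 secure runs over five seeds, randomized small
  compositions) are the package's desk-scale reference conditions chosen
  so the whole suite runs comfortably on a single core.

## A worked example

```{r example, eval = FALSE}
library(epilinkr)
config <- default_linkage_config()

gen <- generate_overlapping_datasets(n_per_dataset = 100,
                                     pairwise_overlap = 10,
                                     triple_overlap = 5,
                                     noise = noise_model(), seed = 1)
A <- gen$datasets[[1]]
B <- gen$datasets[[2]]

plain <- intersection_cardinality_plain(A, B, config, mode = "fixedpoint")
secure <- secure_intersection_cardinality(A, B, config, seed = 42)
tidy(plain)
glance(secure)
```

The two calls agree exactly (this is the package's central acceptance
property): the secure path is the same integer computation executed on
shares.

## Limitations

* Semi-honest, two-party, dealer-assisted model only (see above).
* The weight/threshold defaults are placeholders, not a validated
  calibration.
* No blocking or indexing: all $|A| \times |B|$ pairs are compared, as the
  underlying method prescribes; runtime is quadratic, and the secure
  path's correlated-randomness pools grow linearly in the number of pairs
  (roughly 10,000 Boolean triple bits and 5,000 bit conversions per pair
  under the default configuration, a few hundred megabytes for a 100×100
  run), so large secure runs are memory-bound.
* Binary-field equality inside the circuit has a $2^{-32}$ hash-collision
  probability per comparison.
* Score asymmetry under unequal slot weights in exchange groups, as
  discussed.

One further quantization detail: integerizing the weights
($\tilde w_i = \mathrm{round}(W w_i)$, $W = 64$) perturbs the normalized
score by up to roughly $0.5/(W \min_i w_i)$ — about $2\times10^{-3}$ with
the default calibration — independent of $p$.  The `fields`$\cdot 2^{-p}$
bound above describes similarity quantization at fixed weights.  $W$
trades this perturbation against ring headroom: the exchange-group
tournament squares the weight mass, so $W$ cannot grow past the
$2^{\ell-1}$ comparison bound.
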