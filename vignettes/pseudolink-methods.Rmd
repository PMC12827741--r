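---
title: "Methods: pseudonymization, record linkage and consent in pseudolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudonymization, record linkage and consent in pseudolink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudolink)
```

pseudolink models the job of a patient-list service in a medical research
network: it holds identifying data (PII) and pseudonyms, links incoming
records to the people it already knows despite typos and name changes,
encodes PII for privacy-preserving comparison, tracks modular informed
consent, and gates every operation behind single-purpose tokens. This
vignette explains the models behind each part, the tunable parameters and
their defaults, and the choices made where the design was genuinely open.

## The patient model

A *patient* is a person; an *identity* is one snapshot of their identifying
fields. Because people marry, move, and get misspelled, a patient
accumulates identities over time: exactly one is the MAIN identity (shown
to users and exported), the rest are ALIAS identities, which are invisible
in ordinary views but fully active in record linkage — once a conflict has
been resolved, the same visit data should never raise it again. Identities
are append-only; merging two records turns the absorbed record's identities
into aliases of the survivor and leaves a `duplicate_of` link so that all
of the absorbed record's pseudonyms keep resolving. A split is recorded as
a permanent exclusion so a rejected pair cannot be re-proposed.

The default field schema is `first_name`, `last_name`, the three
birth-date components, `zip` and `city`. Dates are split so that one wrong
component (a very common entry error) perturbs one comparison out of
seven, not an entire date string. Values are normalized before any
comparison: uppercased, transliterated to ASCII (diacritics stripped), all
non-alphanumeric characters removed; empty results count as missing.

## Check-character PIDs

Internally generated pseudonyms are short, human-readable and
self-checking. A PID is 8 characters over a 32-symbol alphabet (digits
plus the Latin letters without B, I, O, S, which are too easy to confuse
with 8, 1, 0, 5):

* The 6 payload characters carry a creation counter (capacity
  $32^6 = 2^{30}$), scrambled by a 4-round keyed Feistel permutation over
  30 bits whose round function is HMAC-SHA256 under the store's mixing
  key. The permutation is bijective, so PIDs are injective in the counter,
  and key-dependent, so two deployments emit unrelated-looking sequences —
  with no stored mapping table.
* The 2 check characters make the codeword $c_0..c_7$ satisfy
  $\sum_j c_j \alpha^j = 0$ and $\sum_j c_j \alpha^{2j} = 0$ over
  GF($2^5$) (primitive polynomial $x^5 + x^2 + 1$). This is a shortened
  Reed–Solomon-style code with minimum distance 3.

Distance 3 allows *either* correcting any single wrong character *or*
guaranteeing detection of any two — not both at once, since a double error
can land within Hamming distance 1 of another codeword. The operating mode
is therefore configuration (`CORRECT1`, the default, or `DETECT2`), with
exactly two check characters in both modes. Verification computes the two
syndromes; in `CORRECT1` mode a consistent nonzero syndrome pair locates
the error position as $\log_\alpha(S_2/S_1)$ and repairs it. Payload
length is configurable (2–10 symbols); the check structure is fixed.

## Derived pseudonyms and transport

A *CryptoID* is derived from a base pseudonym by deterministic
authenticated encryption in an SIV construction: the IV is a truncated
HMAC-SHA256 of the plaintext, the body is AES-256-CBC under a second
derived key, and the result is re-encoded over a configurable
power-of-two alphabet. Determinism is the point — the ID can be
regenerated on every access and never needs to be stored; the synthetic IV
doubles as an authenticator, so inverting with a wrong key fails loudly
rather than yielding a wrong base pseudonym.

*ElasticIDs* encode a counter into a template of vocabulary and digit
slots (`"{w}-{w}{d}"`), mixed-radix, most significant slot first. They are
injective up to the template capacity and support a maximum-length check
for labels that must fit on a biosample tube.

For sending pseudonyms to a trusted third party, `transport_encrypt()`
uses hybrid encryption (the standard envelope construction): the payload
is encrypted under a fresh symmetric session key, and only the session key
is encrypted with the recipient's RSA public key. Equal payloads produce
distinct envelopes because the session key and IV are fresh per call.

## The linkage score

Two identities are compared field by field. `EXACT`/`DATE_COMPONENT`
fields contribute 1 or 0; name-like fields use Dice similarity of padded
bigram multisets ("ANNA" → {_A, AN, NN, NA, A_}), which degrades gracefully
under substitutions, insertions, deletions and transpositions. Fields
missing on either side are excluded entirely. The record score is

$$s = \frac{\sum_i w_i s_i}{\sum_i w_i}, \qquad
  w_i = \log_2\frac{1 - e_i}{f_i},$$

summing over mutually present fields. The weight rewards fields that are
reliable (low error rate $e_i$) and discriminating (low
agreement-by-chance frequency $f_i$): a matching surname is strong
evidence, a matching birth month is weak. Defaults: $e = 0.01$ for every
field; $f$ = 0.01 (first name), 0.005 (last name), 1/31, 1/12, 1/70
(birth day/month/year), 0.01 (zip), 0.05 (city). These are typical
most-common-value frequencies for central-European cohorts and are fully
overridable per field.

Two thresholds cut the score: at or above `threshold_match` (default
0.95) the pair is a MATCH, below `threshold_nonmatch` (default 0.80) a
NON_MATCH, in between a TENTATIVE match. Boundaries are inclusive upward
(a score exactly at a threshold takes the higher class). The tentative
zone exists because a one-typo duplicate and two siblings sharing a
household can score similarly; a human (trustee) resolves the queue by
merging or splitting. Deployments that prefer automation can set
`auto_reject_tentative`: the pair is then reported as a rejected
non-match and *no record is created* — the submitter is expected to check
the data and retry.

During matching, a probe is scored against every identity (MAIN and
ALIAS) of every candidate patient; a patient's score is the maximum over
its identities (chosen over recency-weighted alternatives because an old
alias that matches exactly is exactly the signal aliases exist to
provide). Ties break to the lowest internal record key, so results are
reproducible. A MATCH returns the existing patient unchanged; new alias
identities enter only through explicit edits or merges, keeping silent
data drift out of the store.

## Privacy-preserving comparison

Where clear-text comparison is not permissible, field values are encoded
as Bloom filters: each bigram sets $k$ positions
$(h_1 + i\,h_2) \bmod m$, $i = 0..k-1$, with $h_1, h_2$ drawn from one
HMAC-SHA256 of the gram under a shared secret (keyed double hashing —
one secret, two hash streams). Dice similarity on the bit vectors,
$2|a \wedge b| / (|a| + |b|)$, then stands in for the clear-text gram
Dice in the same weighted score. Defaults $m = 500$, $k = 10$ follow
common practice for field-level filters; both are exposed because the
privacy/fidelity trade-off is deployment-specific. One filter per field
(not a record-level composite) keeps the scoring engine unchanged.

Encoding fidelity is measured on pairs of a name and a typo variant of
it — the regime candidate pairs are actually in after blocking, and the
regime where fidelity decides match outcomes. On such pairs the mean
absolute gap between Bloom Dice and clear-text Dice stays within 0.05 at
the defaults; at very large $m$ (no collisions) the two are exactly equal.
For widely dissimilar values the encoding systematically overestimates
similarity by a few hundredths (random bit collisions), which does not
move decisions because those pairs sit far below the lower threshold.

Serialization is lowercase hex with filter bit 0 as the most significant
bit of byte 0 — a bit-exact contract for cross-implementation tests. The
encoded CSV emitted by the command-line wrapper carries only hex filters
and pass-through pseudonym columns, never plaintext PII.

## Blocking

Scoring all pairs is quadratic and infeasible beyond toy sizes, so an
index maps cheap keys to patients, and only patients sharing at least one
key with the probe are scored. Three default blocking variables:

* **Soundex of the last name** — the classic American variant (H/W
  transparent, vowels break runs), so MEIER and MAYER share bucket M600;
* **birth year**, verbatim;
* **LSH bands over the first name's Bloom filter** — $Q = 8$ bands of
  $L = 32$ bit positions sampled deterministically from a seed; similar
  filters agree on most bits, so true pairs share a band with high
  probability. Bands whose sampled bits are all zero emit no key
  (otherwise near-empty filters pile into one giant bucket). $L = 32$ was
  chosen over shorter bands because the synthetic name pools share many
  bigrams across distinct names; shorter bands produced buckets of
  hundreds of unrelated records.

Keys combine with union (OR) semantics: a typo must break *all three*
variables simultaneously to hide a record, which is why measured blocking
recall on the benchmark cohort is ≈ 1 while the candidate set stays below
5 % of all pairs. A probe with no keys at all (all blocked fields
missing) falls back to full comparison. Alias identities contribute keys
like any other identity. Blocking only selects pairs — scores are
identical with and without it, which the tests check against exhaustive
comparison.

## Consent

A consent template models the paper form: each module is a checkbox,
mapped to one or more data-use policies. A consent record stores the
patient's PERMIT/DENY choice per module (unstated optional modules
default to DENY — fail-safe), a signature date, an optional Base64-embedded
scan, and a version counter per (patient, template); recording supersedes
the previous ACTIVE record, history is append-only. Withdrawal is either
full (status WITHDRAWN, effective from its date — checks dated earlier
still see the original decision) or partial (a successor version with the
named modules set to DENY); the two are distinct operations because
registries need both.

`check_policy(patient, policy, at_date)` evaluates the highest applicable
version signed on or before the date: expiry of a configured validity
period denies (fail-safe, since an expired consent is no legal basis),
withdrawal denies from its effective date, and the absence of any record
returns UNKNOWN rather than DENY so callers can distinguish "never asked"
from "refused".

Serialization targets structural conformance with the base FHIR
resources: one Consent with a permit/deny provision per module, a
DocumentReference holding the scan (restricted to `application/pdf` and
`image/png`), and a Provenance linking the two — present exactly when a
scan is attached. Validation against national profiles is out of scope.

## Sessions, tokens, tenants

All operations on patient data run through a delegation model: a client
authenticates with an API key and opens a session; within it, tokens are
created, each authorizing exactly one operation class (`ADD_PATIENT`,
`READ_PATIENT`, `EDIT_PATIENT`, `DELETE_PATIENT`); redemption validates
the token, executes the operation, consumes single-use tokens atomically
(validation failures do not consume; execution failures do), writes one
audit record, and fires callbacks. The callback mechanism implements
visibility splitting: the redeemer receives only the pseudonym types the
token names, while other types (e.g. the internal PID) are delivered to an
allow-listed URL — so a web form's user never sees the linking pseudonym
and the back-end system never sees the PII.

Authorization is deny-by-default role-based access control with granular
grants (`create-token:ADD_PATIENT`, `read-idtype:study_a_id`,
`read-field:first_name`, `tenant:study_a`). Tenants partition the store:
a role sees only patients enrolled in its tenants, and enrollment always
mints the tenant's project pseudonym (`<tenant>_id`). Consent integrates
as a grant gate: a grant suffixed `?requires-policy=<id>` applies only to
patients for whom that policy currently evaluates to PERMIT. Session and
token ids are 128-bit random strings; an invalidated or expired session
kills all its issued tokens. The service is an in-process engine —
callback deliveries are recorded in a log rather than posted over HTTP —
so the entire authorization logic is testable without networking; a thin
HTTP facade can be layered on top without moving any logic.

## Synthetic cohorts and the error model

The generator makes every claim testable without real PII. Name pools
(~1,000 first and last names, ~60 cities with linked postal codes) are
built deterministically from syllable enumeration — they are synthetic and
ship no real person's data — with sampling frequencies
$\propto 1/(\text{rank} + 20)$, putting the most common name near 1.2 %,
consistent with the default $f$ values so the linkage weights are
meaningful on generated data. Birth dates are uniform over 1935–2004;
city and zip are linked.

A cohort is $n_\text{base}$ unique persons plus $n_\text{dup}$ duplicates
produced by corrupting sampled base records. The error model applies, per
field and duplicate, independent corruption draws: substitution 0.02,
insertion 0.01, deletion 0.01, adjacent transposition 0.01 on string
fields; dropping an optional field (city, zip) 0.01; a wrong birth-date
component 0.01 each. These rates correspond to the low per-field error
rates of trained data entry — most duplicates are clean or carry one
small error — and were fixed as the study condition before any end-to-end
measurement. Ground truth (base row, duplicate row, applied corruption
tags) is emitted alongside; everything is bit-reproducible given the
seed.

What the generator does *not* emulate: swapped first/last names, household
effects (siblings sharing surname, address and birth year), nicknames and
cultural name variants, scanning/OCR noise, and real name-frequency
skew. Passing benchmarks on this cohort therefore demonstrates the
machinery (weighting, thresholds, blocking, bookkeeping) under controlled
noise, not field performance on any real registry; on real data the
comparator frequencies and thresholds must be re-estimated.

## Benchmark sizes and numerical choices

The standard benchmark is 5,000 base records + 1,000 duplicates ingested
into an empty store at thresholds (0.80, 0.95) — large enough for stable
rates and small enough for an ordinary laptop core; the oracle-equivalence
check runs at 200 records where exhaustive all-pairs comparison is cheap.
The acceptance script and test suite both regenerate these cohorts from
fixed seeds. Degenerate inputs are defined, not accidental: Dice of two
empty gram sets is 1 and of one empty set 0; an identity with no
comparable fields is an error; a probe with no blocking keys triggers full
comparison; malformed PIDs verify as INVALID rather than erroring. Score
ties break to the lowest record key; rows of a batch are processed in
input order and may match earlier rows of the same batch.

## Known limitations

* The linkage engine scores probes incrementally (record-at-a-time); there
  is no global one-shot deduplication of an existing store.
* Bloom-filter hardening (balancing, salting, xor-folding) and
  cryptographic multi-party protocols are out of scope; the Bloom encoding
  here mitigates, but does not eliminate, inference attacks.
* Exchange groups (swapped field pairs) are not modeled.
* The consent serializer targets the base FHIR resource shapes, not any
  national profile's constraints.
* The service engine is single-process; the single-use token check-and-set
  is atomic within one R session, not across processes.
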