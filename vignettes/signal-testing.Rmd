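---
title: "Methods: annotation-based testing of drug-safety signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-based testing of drug-safety signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adesignal)
```

## The problem

Spontaneous reporting systems capture only a fraction of adverse drug
events; most of the evidence sits in free-text clinical notes. `adesignal`
tests a *hypothesized* condition–drug–event signal against a note corpus by
(i) recognizing concept mentions with dictionary matching plus negation
detection, (ii) ordering each patient's mentions in time, (iii) classifying
patients into the cells of a 2×2 exposure-by-event table by the temporal
pattern of their *first* mentions, and (iv) summarizing disproportionality
with an odds ratio, a Woolf interval and Fisher's exact test.

The design premise is deliberate simplicity: term extraction rather than
grammatical parsing trades some per-mention precision for the throughput
needed to scan millions of notes, and the statistics are computed on
population-level counts where independent annotation errors largely wash
out (see the false-positive analysis below).

## Annotation model

**Matching.** Lexicon surfaces and note text are reduced to lowercase
alphanumeric token sequences; a multi-token hash automaton enumerates every
token-aligned occurrence of every surface. Overlaps are resolved
deterministically: longest character span first, ties to the leftmost
start. A surface shared by several concepts yields one annotation per
concept on the same span. Multi-token terms do not match across newlines
unless `across_lines = TRUE` — clinical notes often use line breaks as hard
section boundaries, and the safer default is to respect them.

**Negation.** A mention is negated iff a pre-negation trigger precedes it,
or a post-negation trigger follows it, within `scope_window` tokens
(default 5, the conventional NegEx window). Scope is truncated at sentence
boundaries (`.;:!?` and newline — clinical notes lack reliable sentence
markup, so punctuation plus newlines is the approximation) and at
termination phrases ("but", "however"). Pseudo-negation phrases ("no
increase") never negate and mask the trigger words they contain. The
shipped trigger file (`inst/extdata/negex_triggers.txt`) is a compact
editable subset of the published NegEx rule set; users with domain-specific
phrasing should extend it.

**Per-note collapsing.** The feature matrix stores one state per
(note, concept): `positive`, `negated`, or absent. When a concept occurs
both ways in one note, positive wins — a note that first denies and later
asserts a finding is evidence the finding is present, and downstream logic
needs a single state per cell.

Negated states never satisfy any positive predicate anywhere downstream:
they neither qualify a patient for the cohort nor contribute first-mention
times. They are retained in the matrix because they carry information for
other analyses (and for auditing the negation rules).

## Timelines and classification

Timelines merge note-derived states with coded ICD-9 events (prefix-mapped
to concepts, longest prefix first). Time resolution is the calendar day;
same-day order falls back to provenance (note before coded) and then
`note_id`, purely to make output deterministic.

For a triplet (condition *c*, drug *x*, event *y*) and window, each
cohort patient is classified from the dates of their first positive
mentions `t_c`, `t_x`, `t_y`:

- no condition mention → excluded (not in the indication cohort; restricting
  the background to patients with the drug's usual indication avoids
  comparing against patients with zero propensity for exposure);
- first drug mention strictly before `t_c` → excluded by default (the drug
  was evidently not prescribed for this indication;
  `prior_drug_policy = "unexposed"` pools these patients into the unexposed
  arm instead);
- first event mention strictly before `t_c` → excluded by default (a
  prevalent event cannot be incident to the exposure;
  `prevalent_event_policy = "keep"` retains the patient and dates the event
  from its first occurrence after `t_c`);
- otherwise: **exposed** iff `t_c < t_x`; exposed patients fall in cell
  **a** when `t_x < t_y` and **b** otherwise; unexposed patients fall in
  **c** when `t_c < t_y` and **d** otherwise.

Two conventions deserve a note. First, *strict* inequality is the default
tie rule: day-resolution timestamps cannot order same-day mentions, so a
same-day pair does not establish succession (`ties = "weak"` flips this).
Second, **b** and **d** are defined as within-arm complements of **a** and
**c**. The alternative — defining b by "no event after the drug" — leaves a
gap: a patient with condition < event < drug < second event is neither "first
event after drug" (cell a) nor "no event after drug". The complement
convention closes the gap, guarantees the conservation identity
`a + b + c + d + excluded = patients classified`, and matches the
substantive reading that cell a requires the *first* event to follow
exposure. The test suite certifies the classifier against a brute-force
transcription of these rules over every order type of first-mention triples
(including absences and ties) and over random multi-mention timelines.

The default window is 1999-01-01 to 2004-12-31, the rofecoxib market
period; the stricter reading of "before 2005" was chosen where the window's
right edge was ambiguous, and both edges are plain arguments.

In `icd9_only` mode the condition and event channels are restricted to
coded-provenance events, while drug exposure uses whatever occurrence
channel the run supplies — coded diagnoses carry no drug exposure, so the
caller must designate one.

## Statistics

The odds ratio is `ad/(bc)`, undefined (flagged, not corrected) when `b` or
`c` is zero; the Haldane–Anscombe +0.5 correction is available behind an
explicit flag. The Woolf interval is
`exp(ln OR ± z · sqrt(1/a + 1/b + 1/c + 1/d))`; it reproduces the published
intervals for both reference tables from their printed cells, which is why
it is the package's interval method.

Fisher's exact test defaults to the point-probability two-sided convention
(sum of all margin-consistent tables no more probable than the observed
one, with a `1 + 1e-7` relative guard against floating-point ties —
the same guard the standard implementations use).
`fisher_exact(method = "doubled")` doubles the smaller one-sided tail; the
two conventions differ noticeably for asymmetric tables, and the reference
ICD-9 table's published p-value of 0.19 corresponds to the doubled
convention (the point convention gives 0.14).

**False-positive sensitivity.** Entering a patient into cell a erroneously
requires three simultaneous false-positive annotations; under independence
at rate `fp` this has probability `fp³` (0.8% at `fp = 0.2`). The
`adjust_false_positive()` scheme discounts each cell by the probability its
defining annotations are all true — `a(1-fp)³, b(1-fp)², c(1-fp)², d(1-fp)`
— rounded to whole patients. Because these factors cancel in `ad/(bc)`, the
scheme leaves the odds ratio essentially unchanged and only widens the
interval; no simple per-cell scaling can do otherwise, so the scheme
identifier is recorded in the output and the adjustment is presented as a
sensitivity analysis, not a bias correction. It is deliberately not
idempotent (applying it twice discounts twice).

## The synthetic corpus generator

`generate_corpus()` emulates exactly the features the pipeline is sensitive
to: planted first-mention orderings for each cell and exclusion pattern
(dates drawn uniformly in the window under the ordering constraints, by
sequential sampling without replacement), mentions embedded in a small bank
of clinically flavored templates, decoy negated mentions phrased with real
NegEx triggers, trade-name variation (Vioxx vs rofecoxib) to exercise
normalization, an optional parallel ICD-9 stream mirroring condition/event
mentions, and per-note spurious-insertion / mention-dropout noise. It does
*not* model realistic clinical language (vocabulary breadth, misspellings,
abbreviation ambiguity, section structure), visit patterns, demographics or
censoring. Passing the zero-noise recovery tests therefore certifies the
*logic* of the pipeline — matching, negation scoping, normalization,
temporal classification, counting — on clean text; it does not certify
recall or precision on real notes, which depend on lexicon quality and
local phrasing.

Generation is fully deterministic given the config seed, and all commands
write byte-identical outputs on identical inputs (no timestamps are
embedded), which the determinism tests check end to end.

## Test problem sizes

The suite certifies: exact planted-cell recovery over 50 random
configurations (cells 0–5 plus exclusions, negated decoys at rate 0.25);
classifier equivalence with the brute-force rules over all first-mention
order types and 300 random multi-mention timelines under all eight policy
combinations; matcher equivalence with a regex oracle over randomized
corpora (5 corpora × 20 notes × 50 terms); Fisher agreement with exhaustive
enumeration for 150 random tables with totals up to 200 (plus a cross-check
against `stats::fisher.test`); and 95% Woolf coverage of a planted odds
ratio of 3 in ≥90% of 200 binomial replicates with expected cells ≥ 30,
with pipeline recovery spot-checked on a sample of those replicates (the
zero-noise recovery property makes the pipeline step deterministic, so
coverage is a property of the interval, not of the text processing).

## Known limitations

- Term matching is exact at the token level: no stemming, spelling
  correction or morpheme matching; recall on real notes is bounded by
  lexicon coverage.
- Negation handles direct negation only — no family-history, hypothetical
  or historical context detection.
- Day-resolution timestamps cannot order same-day mentions; the strict tie
  rule is conservative about exposure.
- One drug, one event, first mentions only: no dose, duration, recurrence
  or multi-drug interaction modeling, and no confounding adjustment beyond
  the indication restriction.
- The false-positive adjustment assumes independent, uniform annotation
  error rates across concepts and cells.
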