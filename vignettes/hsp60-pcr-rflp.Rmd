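---
title: "Typing Bifidobacterium species by hsp60 PCR-RFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing Bifidobacterium species by hsp60 PCR-RFLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidotyper)
library(dplyr)
```

## The assay

*Bifidobacterium* species are hard to separate by 16S rDNA: several close
pairs (e.g. *B. catenulatum* / *B. pseudocatenulatum*) and the subspecies of
*B. longum* and *B. animalis* carry identical or near-identical 16S
sequences. The 60 kDa chaperonin gene *hsp60* (*groEL*) varies more between
close taxa, and a short stretch of it can be amplified across the whole genus
with one degenerate primer pair:

* H60F `GGNGAYGGNACNACNACNGCNACNGT` (forward)
* H60R `TCNCCRAANCCNGGNGCYTTNACNGC` (reverse)

The primer-inclusive product is ~590 bp. A single complete digestion with
HaeIII (`GG^CC`) then yields a fragment pattern — read as bands on a 3%
agarose gel — that is species-specific for all but two sets of subspecies.
This package reimplements every step of that workflow in silico: primer-site
search and amplicon extraction, restriction digestion, a gel model that
converts fragment multisets into visible band sets, a packaged database of
the predicted type-strain profiles, enzyme scoring, a dichotomous
identification key, and identification of unknown isolates from observed
band sizes.

## The gel model

A fragment list is not what a gel shows. Three rules translate one into the
other, each a `gel_model()` parameter:

* **Visibility window** `min_visible = 25` bp to `max_reliable = 360` bp.
  Shorter fragments run with the primer front and carry no discriminatory
  signal; longer fragments are excluded because incomplete digestion of long
  stretches cannot be ruled out, so a >360 bp band is not trustworthy
  evidence. Both bounds are part of the assay definition, not tuning knobs.
* **Co-migration**: two sizes merge into one band when they differ by at most
  `max(comigration_abs, comigration_rel * smaller)`, i.e. max(2 bp, 3%) by
  default. The source tables never state a numeric gel resolution; these
  defaults are our inference from which predicted profiles the assay treats
  as distinct — 96 vs 97 bp (the two *B. animalis* subspecies, different
  lanes) must co-migrate while 53 vs 71 bp must resolve. Merged bands are
  represented by the rounded mean of their members and flagged when they
  swallowed two or more fragments (a doubled fragment is one brighter band,
  e.g. the doubled 139 bp fragment of *B. breve*).
* **Set comparison**: band sets are compared as sets of representative sizes
  under the same tolerance, by greedy order-preserving matching; multiplicity
  flags are ignored by default because a gel reader cannot count molecules,
  with a strict mode for in-silico work. `profile_distance()` is the
  unmatched fraction, `1 - matched / max(|a|, |b|)`.

```{r gel}
digest_linear(synthetic_amplicon(1, 584, c(106L, 245L, 384L))$seq, "HaeIII") |>
  apply_visibility_filter() |>
  merge_comigrating()
```

## Numerical and design choices

**Coordinates.** All arithmetic is 0-based half-open internally; every
user-facing table is 1-based inclusive. A cut coordinate equals the length of
the prefix it leaves, so fragment lengths are plain successive differences.

**Degenerate matching.** IUPAC codes are 4-bit masks over {A, C, G, T}; a
pattern position matches a subject base when their expansions intersect
(default) or when the subject's expansion is contained in the pattern's
(strict mode, for inputs with N runs that should not be trusted to match).
`U` is rejected outright rather than converted: the assay is DNA-only and a
silent conversion would hide upstream errors. Mismatch allowances default to
0 — the primers are already highly degenerate and the packaged profiles
presume exact in-silico amplification — and can be raised for noisy genome
assemblies, optionally counting mismatches only at non-degenerate pattern
positions.

**Primer-inclusive amplicons.** The predicted per-taxon fragment sums cluster
at 584–598 bp, matching the ~590 bp product only if the primer tracts are
counted; amplicons are therefore primer-inclusive, and a 400–900 bp
plausibility window rejects spurious primer pairings. Typing workflows
require exactly one product per record and refuse to guess between several
(a gel lane holds one product); batch extraction reports all products with a
warning.

**Digestion is complete and strand-symmetric.** Every recognised site is cut
exactly once; over- and under-digestion are handled by the gel model's
visibility window, not by kinetics. Each double-strand break contributes
both strand nick positions — `start + offset` and its mirror
`start + len - offset` — which coincide for blunt cutters and differ for
staggered ones (Sau3AI, AatII, PvuI). This keeps a digestion identical on a
sequence and its reverse complement, the property a double-stranded molecule
must have; the cost is that a sticky site contributes its ≤4 bp overhang as
a stub fragment, far below gel visibility. Sites spanning an ambiguous base
count as cuts under the default policy, with a warning, so potential
polymorphism is surfaced rather than hidden.

**Enzyme scoring.** An enzyme's score is the fraction of unordered taxon
pairs whose band sets it distinguishes — robust to group sizes and directly
checkable against which taxa the assay leaves merged, unlike a
count-of-distinct-profiles. Taxa in unresolved pairs are grouped by
transitive closure. Double digests are out of scope by design: the assay's
goal is a single-enzyme protocol. Ranking ties break by the variance of
visible band counts (flatter profiles are easier to read) and then by name,
so the ranking is deterministic.

```{r score}
score_enzyme(reference_fragments(), enzyme = "HaeIII")
```

## The dichotomous key

The published key is a figure whose branch structure is not machine-readable;
the tree is therefore reconstructed algorithmically under the contract that
its **leaf partition** — not its branch order — reproduces the assay's
discriminations. Construction is greedy and deterministic: at each node,
candidate band sizes (co-migration cluster representatives of the pooled
bands, plus the exact sizes) are scored by how evenly their presence/absence
question splits the remaining taxa, ties toward the larger size; recursion
stops when the remaining taxa are mutually indistinguishable, so
identical-profile groups (the three *B. longum* subspecies; the two
*B. thermacidophilum* subspecies) end in shared leaves. Greedy construction
is transparent and testable; optimality of the tree is not claimed, and with
29 taxa not needed.

One refinement beyond the balanced-split rule: candidates are preferred when
every remaining taxon answers the question with at least 1 bp of margin
against the co-migration tolerance. Without it, a band sitting exactly at the
tolerance boundary of a question (e.g. a 54 bp band asked about at 52 bp)
flips its answer under ±1 bp of gel-reading noise and derails the walk; with
it, every reference profile survives ±1 bp noise on every band.

Identification walks the key, then **confirms** the leaf by profile distance
against each leaf member — a key alone funnels any input, including an
unknown species, to some leaf, so a confirmation threshold (default 0.25,
i.e. at least three of four bands accounted for) converts bad fits into
`no_match`, with the full-database nearest neighbours reported alongside.
Subspecies inside an identical-profile group are reported as the group,
never guessed. *B. subtile*, which has no in-silico profile, is identifiable
only through the nearest-neighbour route if a user supplies empirical bands
for it.

```{r key}
key <- build_key()
glance(key)
identify_bands(c(53, 198, 338), key = key)
identify_bands(c(42, 113, 138, 139, 158), key = key)
```

## The reference database

`load_reference_db()` ships the predicted HaeIII profiles of the 30 most
widely distributed type strains (25 species), transcribed digit-for-digit
from the published in-silico digestion table and guarded by an md5 checksum
and shape invariants — a modified copy refuses to load. Known anomalies of
the printed table are preserved verbatim and annotated rather than silently
corrected: one collection number (ATCC 27539) is printed for both
*B. catenulatum* and *B. minimum*; accession AY004282 appears in two rows,
as does AY004276; *B. subtile*'s unexplained table flag is encoded only as
"no in-silico data". The 39-strain validation panel (12 taxa) carries the
two documented reassignments — B1955, deposited as *B. catenulatum*, shows
the *B. adolescentis* profile; Su864, deposited as *B. longum* subsp.
*suis*, shows the *B. breve* profile — giving the 37/39 ≈ 95% concordance
the panel is known for:

```{r validation}
v <- run_validation_panel(key = key)
summarise(v, concordance_pct = 100 * mean(concordant))
filter(v, !concordant)
```

## Synthetic fixtures, and what passing tests do not show

`synthetic_amplicon()` builds sequences that start with a concrete
realisation of H60F, end with the reverse complement of a realisation of
H60R, and contain `GGCC` exactly at requested positions: unplanned motifs
are destroyed by point mutation and the result is verified by re-scanning,
with a bounded retry budget and a hard failure rather than silent bias.
`synthetic_genome_context()` embeds such amplicons in primer-free random
flanks so extraction must recover exactly the planted products. Both are
pure functions of their seed and leave the caller's RNG state untouched.

These fixtures emulate the *combinatorics* of the assay — site layouts,
primer geometry, fragment arithmetic — under a uniform background
(default GC 0.5, roughly in the range of bifidobacterial hsp60 sequence).
They are not phylogenetically realistic hsp60 sequences: no codon structure,
no real primer-template mismatch spectrum, no gel measurement error beyond
the co-migration model. Tests passing on them therefore validate the
machinery and the printed reference profiles, not the wet-lab behaviour of
new field isolates; the one claim about real data the package can check
offline is that the packaged profiles reproduce the published
discriminations, concordance and key behaviour. A user with network access
can close the remaining gap by downloading the *B. catenulatum* entry
AY004272 and running `check_reference_sequence()` on it, which should
reproduce the 53-198-338 profile with largest fragment 338 bp.

Problem sizes used by the shipped test-suite and acceptance script — 1,000
random sequences per enzyme for the digestion oracle, 1,000 seeded
generate→amplify→digest round-trips in the tests and 200 in the acceptance
script — were chosen as comfortable desk-scale checks of deterministic code.

## Known limitations

* Complete digestion only; partial digests, star activity and methylation
  sensitivity are out of scope, as is circular topology.
* The gel model has no mobility-curve or intensity component; it cannot
  simulate a gel image, only band sets.
* Subspecies inside identical-profile groups are not resolvable by this
  assay at all; downstream subspecies-specific PCR is the documented remedy.
* The co-migration defaults are inferred, not measured; users with
  calibrated gels should set their own `gel_model()`.
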