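---
title: "protrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrack)
```

protrack is a laboratory information management library for protein
production groups. This vignette explains the models and conventions it
implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where more than one defensible choice existed.

## The data model

Four reagent record types form a directed acyclic lineage:

```
protein batch  ->  supe(s)  ->  cell line  ->  DNA construct(s)
```

Links only point from later record classes to earlier ones, so the
lineage graph cannot contain a cycle by construction. Many-to-many
links (co-transfections, multi-supe batches) live in junction tables
(`cellline_construct`, `supe_construct`, `batch_supe`); the full DDL is
in `inst/sql/schema.sql`. Requests are kept in their own table, apart
from the reagent tables.

Three rules keep the lineage meaningful:

* a **stable** cell line must name at least one integrated construct;
  **parental** and **hybridoma** lines carry none;
* a supe from a **parental** line must name the construct(s)
  transfected (transient expression); a supe from a **stable** line
  names none and inherits the line's;
* a batch needs at least one supe, and each of its supes must trace to
  at least one construct (hybridoma supes therefore cannot feed a
  batch — antibody purification from hybridomas is outside the model).

Deletion is refusal-based, not cascading: a record still referenced
downstream (or by a request) cannot be removed. Identifier serials
(`DNA-00001`, `CL-00001`, ...) are per-prefix counters that are never
reused, so an id that once existed can never silently point at a
different record. Record timestamps come from a persisted logical
clock, not wall time, which makes stores byte-reproducible and report
output deterministic.

## Sequence-derived properties

The mature protein sequence entered on a construct drives every derived
field. The conventions are the de-facto community standards, chosen
because they are what a bench scientist will compare against:

* **Normalization.** Whitespace, digits and `*` are stripped and the
  sequence uppercased. The ambiguity codes B, J, O, U, X, Z are
  rejected outright rather than given zero mass: a silently wrong
  molecular weight would propagate into the A280 and every mass
  calculation downstream.
* **Molecular weight** is the sum of average (not monoisotopic)
  residue masses plus one water, 18.0153 Da. The embedded 20-entry
  table carries 4-decimal residue masses; reporting rounds to 2
  decimals, internal arithmetic is full double precision.
* **Extinction at 280 nm** follows Gill & von Hippel as refined by
  Pace: 5500 M⁻¹cm⁻¹ per tryptophan, 1490 per tyrosine, plus
  125 per cystine when cysteines are assumed fully paired. Whether a
  given protein's cysteines are oxidized is not something the record
  can know, so **both** values are computed and stored; the reduced
  value feeds the default 0.1 % absorbance, `A280 = ε_reduced / MW`.
* **N-glycosylation sequons** are occurrences of `N-X-S/T` with
  `X ≠ P`. Overlapping sequons are each counted, and no exclusion is
  applied for a proline after the S/T position — the simplest
  defensible reading of "number of potential sites"; occupancy is a
  wet-lab question the counter does not try to answer.
* **Mass bookkeeping.** `total = concentration × volume`;
  `remaining = total × current_aliquots / original_aliquots`. The
  proportional convention is forced by the data model: the batch
  tracks aliquot counts, not per-aliquot volumes, so equal portions is
  the only consistent reading. Masses and A280 round half-even to 2
  decimals, extinction coefficients to integers.

Derived fields are recomputed inside `create_record()` and
`update_record()` and are not directly writable; a batch's read-only
sequence properties come from its **first effective construct in id
order** (a single scalar display field must pick one construct of a
co-transfection; reports list all of them).

## Roles

Reads are open; mutation requires a role parameter: `record_admin` for
reagent records, `request_admin` for request administration. Request
*submission* is deliberately open to any role — in a production group
the requesters are exactly the people without admin rights. Roles are
a library-level permission check, not authentication.

## The request workflow

Requests carry one of five kinds (`transfection`, `stable_supe`,
`dna`, `purification`, `aliquot`), each validated against the record
type it must reference. Status is a forward-only chain
`Pending → Started → Fulfilled`; skipping or reverting raises
`protrack_illegal_transition`. No shortcut and no reopen exist because
neither has an evidenced workflow meaning: a fulfilled request that
needs more work is a new request.

Each kind has its own priority queue over its Pending requests; ranks
are maintained as a contiguous `1..n` permutation at all times. New
requests append at rank `n+1`; `prioritize()` swaps a request with its
neighbour (boundary moves are no-ops); leaving Pending — by starting or
deleting — closes the rank gap. Only Pending requests can be
prioritized or deleted ("work has not yet begun").

A transfection request may fan out secondary plasmid-DNA and/or
purification requests, bidirectionally linked to it and queued in
their own kinds. The auto-generated purification secondary carries no
subject record: the supe it will purify does not exist yet, so the
parent transfection defines the work. Secondaries stay independent —
fulfilling the parent does not advance them.

Notifications go to the configured request-management group on every
submission and to the requestor (when an email is on file) on every
status change, each carrying a `proteintracker://<ID>` link. Delivery
is a pluggable sink — a JSON-lines log file by default, an SMTP stub
for integration — because the library must be fully testable offline;
every event is also recorded in the store itself (`notifications()`).

## Search, pagination, reports

Listing and search run in SQL with a deterministic ordering: the sort
key plus id as tie-break, so pagination partitions the record set
exactly for any page size. Filters are conjunctive; `contains` is
case-insensitive substring, `range` is inclusive. The construct
map-file check is a pure existence test under the configured map
directory; a missing file is a warning carried on the record
(`map_file_found`), never a rejection, and filenames that escape the
map directory (absolute paths, `..`) are treated as not found because
a library cannot assume a trusted network share.

Reports are deterministic structured text: every stored field of the
record, and for supes and batches the chain of custody with full
sections for each ancestor. `chain_of_custody()` walks the lineage
graph upstream depth-first, visiting each node once; when two supes
share an ancestor the printed tree truncates the repeated subtree, so
leaf-ness is defined on the underlying graph — `lineage_leaves()`
returns the construct nodes, which for any batch equal its effective
constructs. A batch spanning supes from different cell lines is legal
but flagged in its report.

## The synthetic-store generator

`populate_store()` builds coherent stores at arbitrary scale for tests
and demos: uniform random sequences (length 30–300 by default),
projects/vectors/tags drawn from small realistic pools, a
parental/stable/hybridoma mix of 35/55/10 % with at least one parental
and one stable line, supes split evenly between transient and stable
expression by default, 1–2 supes per batch, and requests submitted
through the real workflow, then advanced so that roughly 50 % remain
Pending, 30 % are Started and 20 % Fulfilled. The `"production"`
preset (2600 constructs, 1300 lines, 2600 supes, 1300 batches, 1200
requests) reproduces the ~9,000-record scale of a multi-year
deployment and is used by the scale tests; the default small spec
keeps unit tests fast.

What the generator does **not** emulate: biological sequence
composition (residues are uniform — fine for combinatorial invariants,
useless for, say, realistic sequon densities), expression-yield
correlations, wall-clock timestamp patterns, or concurrent operators.
Passing tests therefore demonstrate the bookkeeping, calculators and
workflow logic, not statistical properties of real production data.

Determinism is strict: the generator runs under a locally-scoped seed
(the caller's RNG state is untouched) and timestamps come from the
store's logical clock, so one `fixture_spec()` yields field-identical
stores on every run.

## Numerical and edge-case choices

* Rounding is half-even (R's `round`), applied only at the reporting
  boundary; oracle comparisons in the tests run pre-rounding at 1e-6.
* A chromophore-free sequence legitimately has `ε = 0` and `A280 = 0`.
* An odd cysteine contributes nothing to the oxidized extinction
  (`⌊nCys/2⌋` pairs).
* `current_aliquots = 0` is a legal, fully-depleted batch;
  `original_aliquots` must be at least 1.
* Empty search filter lists reproduce plain listing; a page past the
  end is an empty page, not an error.
* SQLite is opened with `synchronous = OFF` and bulk population runs
  in one transaction; durability in the crash-recovery sense is not a
  goal of an embedded single-user store, reopen-consistency is, and is
  what the tests assert.

## Known limitations

* Single-process use; no concurrent writers, no migrations.
* Roles are parameters, not authenticated identities.
* PDF rendering is out of scope; reports are deterministic UTF-8 text
  that a renderer could typeset.
* Construct map files and QC images are stored as names/links plus an
  existence flag only, mirroring the split between database and file
  server that production systems of this kind use.
* Whether a supe's "remaining quantity" is a volume is
  site-dependent; it is modeled as free text.
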