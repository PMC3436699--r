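# protrack

Protein production and purification tracking for reagent groups.

Labs that express and purify recombinant proteins accumulate four kinds
of linked records: expression **DNA constructs**, the **cell lines**
carrying (or transiently receiving) them, harvested conditioned-media
**supes**, and purified **protein batches**. protrack keeps these in an
embedded single-file SQLite store with strict referential integrity, so
that any purified batch can be traced back through its supe(s) and cell
line(s) to the exact construct(s) and mature sequence it came from — a
complete chain of custody. On top of the records it runs the reagent
**request** workflow a production group needs: typed requests
(transfection, stable supe, plasmid DNA, purification, aliquot) move
`Pending → Started → Fulfilled`, administrators reorder the per-kind
priority queues, and every submission and status change emits a
notification with an embedded `proteintracker://<ID>` link.

## Sequence-derived properties

Everything derived is computed at submission from the mature amino-acid
sequence and recomputed on every update, never stored stale:

- **Average molecular weight**: `MW = Σ residue masses + 18.0153 Da`
  (standard average residue mass table).
- **Molar extinction at 280 nm** (Gill & von Hippel / Pace
  convention): `ε_reduced = 5500·nTrp + 1490·nTyr`, and
  `ε_oxidized = ε_reduced + 125·⌊nCys/2⌋` with all cysteines paired as
  cystine. Both are exposed; the reduced value feeds the default A280.
- **0.1 % absorbance**: `A280(1 mg/mL) = ε_reduced / MW`
  (mL·mg⁻¹·cm⁻¹).
- **N-glycosylation sequons**: occurrences of `N-X-S/T` with `X ≠ P`,
  overlaps counted.
- **Mass bookkeeping** on batches: `total = concentration × volume`,
  `remaining = total × current_aliquots / original_aliquots`.

## Worked example

```r
library(protrack)
st <- open_store(tempfile(fileext = ".sqlite"))

seq <- paste0("APTSSSTKKTQLQLEHLLLDLQMILNGINNYKNPKLTRMLTFKFYMPKKATELKHLQ",
              "CLEEELKPLEEVLNLAQSKNFHLRPRDLISNINVIVLELKGSETTFMCEYADETATI",
              "VEFLNRWITFCQSIISTLT")     # mature human IL-2
str(sequence_properties(seq))
#> $ molecular_weight   : num 15418
#> $ extinction_reduced : num 9970      # 1 Trp, 3 Tyr
#> $ extinction_oxidized: num 10095     # + one cystine pair
#> $ absorbance_0_1pct  : num 0.65      # mL/mg/cm at 280 nm
#> $ n_glyc_sites       : int 0

id <- create_record(st, dna_construct("hIL2-His", seq, project = "cytokines",
                                      vector = "pTT5", tag = "His6"),
                    role = "record_admin")
cl <- create_record(st, cell_line("HEK293-host", "parental"), role = "record_admin")
sp <- create_record(st, supe(cl, transfection_construct_ids = id),
                    role = "record_admin")
b  <- create_record(st, protein_batch(sp, concentration = 1.8, volume = 6.5,
                                      original_aliquots = 12, current_aliquots = 12,
                                      purification_steps = c("IMAC", "SEC")),
                    role = "record_admin")
get_record(st, b)$total_mass      # 11.7 mg (1.8 mg/mL x 6.5 mL)
chain_of_custody(st, b)
#> PB-00001  11.70 mg total
#>   SUP-00001  from CL-00001
#>     CL-00001  HEK293-host [parental]
#>       DNA-00001  hIL2-His (MW 15418.01 Da)

r <- submit_request(st, "aliquot", b, requestor_email = "alice@lab.org")
update_status(st, r$id, "Started", role = "request_admin")  # notifies alice
close_store(st)
```

A command-line interface mirrors the library
(`exec/protrack`, or `protrack_cli()` from R):

```sh
protrack init --db lab.sqlite
protrack add dna --db lab.sqlite --name hIL2-His --seq APTSSST... \
         --role record_admin
protrack open DNA-00001 --db lab.sqlite --json
protrack request transfection --db lab.sqlite --subject DNA-00001 \
         --volume 500 --want-dna --want-purification
protrack demo --db demo.sqlite --seed 1 --scale small
```

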