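-- protrack embedded store schema.
-- Reagent tables form a directed acyclic lineage:
--   protein_batch -> supe -> cell_line -> dna_construct
-- with junction tables for the many-to-many links (co-transfections,
-- multi-supe batches).  Request tables are kept separate from reagent
-- tables.  QC images and construct map files live outside the database;
-- only their names/links are stored.

CREATE TABLE IF NOT EXISTS meta (
  key   TEXT PRIMARY KEY,
  value TEXT NOT NULL
);

CREATE TABLE IF NOT EXISTS dna_construct (
  id                     TEXT PRIMARY KEY,
  construct_name         TEXT,
  project                TEXT,
  vector                 TEXT,
  tag                    TEXT,
  insert_name            TEXT,
  notebook_ref           TEXT,
  mature_sequence        TEXT NOT NULL,
  construct_map_filename TEXT,
  map_file_found         INTEGER,          -- boolean; NULL when no filename
  molecular_weight       REAL NOT NULL,
  extinction_reduced     REAL NOT NULL,
  extinction_oxidized    REAL NOT NULL,
  absorbance_0_1pct      REAL NOT NULL,
  n_glyc_sites           INTEGER NOT NULL,
  created_at             INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS cell_line (
  id                TEXT PRIMARY KEY,
  name              TEXT,
  cell_type         TEXT NOT NULL CHECK (cell_type IN ('parental','stable','hybridoma')),
  origin            TEXT,
  freezer_location  TEXT,
  mycoplasma_result TEXT,
  annotations       TEXT,
  bank_date         TEXT,
  culture_time      TEXT,
  created_at        INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS cellline_construct (
  cell_line_id TEXT NOT NULL REFERENCES cell_line(id),
  construct_id TEXT NOT NULL REFERENCES dna_construct(id),
  ord          INTEGER NOT NULL,
  PRIMARY KEY (cell_line_id, construct_id)
);

CREATE TABLE IF NOT EXISTS supe (
  id                 TEXT PRIMARY KEY,
  cell_line_id       TEXT NOT NULL REFERENCES cell_line(id),
  expression_level   TEXT,
  quality            TEXT,
  western_blot_link  TEXT,
  endotoxin_result   TEXT,
  harvest_info       TEXT,
  location           TEXT,
  culture_media      TEXT,
  notebook_ref       TEXT,
  qc_file_link       TEXT,
  concentration      REAL,
  remaining_quantity TEXT,
  aliquot_count      INTEGER,
  created_at         INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS supe_construct (
  supe_id      TEXT NOT NULL REFERENCES supe(id),
  construct_id TEXT NOT NULL REFERENCES dna_construct(id),
  ord          INTEGER NOT NULL,
  PRIMARY KEY (supe_id, construct_id)
);

CREATE TABLE IF NOT EXISTS protein_batch (
  id                  TEXT PRIMARY KEY,
  formulation_buffer  TEXT,
  concentration       REAL NOT NULL,
  volume              REAL NOT NULL,
  original_aliquots   INTEGER NOT NULL,
  current_aliquots    INTEGER NOT NULL,
  endotoxin_result    TEXT,
  qc_notes            TEXT,
  gel_qc_link         TEXT,
  total_mass          REAL NOT NULL,
  remaining_mass      REAL NOT NULL,
  molecular_weight    REAL,
  extinction_reduced  REAL,
  extinction_oxidized REAL,
  absorbance_0_1pct   REAL,
  n_glyc_sites        INTEGER,
  created_at          INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS batch_supe (
  batch_id TEXT NOT NULL REFERENCES protein_batch(id),
  supe_id  TEXT NOT NULL REFERENCES supe(id),
  ord      INTEGER NOT NULL,
  PRIMARY KEY (batch_id, supe_id)
);

CREATE TABLE IF NOT EXISTS batch_step (
  batch_id TEXT NOT NULL REFERENCES protein_batch(id),
  ord      INTEGER NOT NULL,
  step     TEXT NOT NULL,
  PRIMARY KEY (batch_id, ord)
);

CREATE TABLE IF NOT EXISTS request (
  id                 TEXT PRIMARY KEY,
  kind               TEXT NOT NULL CHECK
    (kind IN ('transfection','stable_supe','dna','purification','aliquot')),
  status             TEXT NOT NULL CHECK
    (status IN ('Pending','Started','Fulfilled')),
  requestor_email    TEXT,
  priority_rank      INTEGER,              -- NULL once work has begun
  subject_record_id  TEXT,
  parent_request_id  TEXT REFERENCES request(id),
  quantity_type      TEXT,                 -- 'volume_ml' or 'flasks'
  quantity           REAL,
  cell_type          TEXT,
  created_at         INTEGER NOT NULL
);

CREATE TABLE IF NOT EXISTS notification (
  seq       INTEGER PRIMARY KEY AUTOINCREMENT,
  recipient TEXT NOT NULL,
  subject   TEXT NOT NULL,
  body      TEXT NOT NULL,
  link      TEXT NOT NULL,
  timestamp INTEGER NOT NULL
);

CREATE INDEX IF NOT EXISTS idx_supe_cell_line ON supe(cell_line_id);
CREATE INDEX IF NOT EXISTS idx_request_queue ON request(kind, status, priority_rank);
CREATE INDEX IF NOT EXISTS idx_request_parent ON request(parent_request_id);
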