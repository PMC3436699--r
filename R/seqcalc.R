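# Sequence-derived properties and mass bookkeeping.
#
# Conventions (the ones a protein chemist would expect at the bench):
# average (not monoisotopic) residue masses; 280 nm molar extinction
# from Trp/Tyr content with an optional cystine term (Gill & von Hippel
# as refined by Pace); A280(0.1%) = epsilon_reduced / MW.  Masses and
# A280 are reported to 2 decimals, extinction coefficients as integers;
# all internal arithmetic is carried at full double precision.

# Average residue (= amino acid minus one water) masses, daltons.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.0153

# 280 nm molar extinction coefficients, M^-1 cm^-1.
EXT_TRP     <- 5500
EXT_TYR     <- 1490
EXT_CYSTINE <- 125

AA_ALPHABET <- names(AA_RESIDUE_MASS)

#' Normalize a raw amino-acid sequence
#'
#' Strips whitespace, digits and `*` (stop/terminator marks common in
#' pasted sequences), uppercases, and validates against the 20 standard
#' one-letter codes.  Ambiguity codes (B, J, O, U, X, Z) are rejected
#' rather than silently assigned zero mass, because a wrong molecular
#' weight would propagate into absorbance and mass bookkeeping.
#'
#' @param raw Free text containing a mature protein sequence.
#' @return A single uppercase string over `ACDEFGHIKLMNPQRSTVWY`.
#' @examples
#' normalize_sequence("  M K 1 V *")  # "MKV"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  cleaned <- toupper(gsub("[[:space:][:digit:]*]", "", raw))
  if (nchar(cleaned) == 0L)
    pt_abort("empty_sequence", "sequence is empty after normalization")
  chars <- strsplit(cleaned, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L)
    pt_abort("illegal_residue",
             sprintf("illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]),
             residue = chars[bad[1L]], position = bad[1L])
  cleaned
}

# normalize each element of a character vector
norm_each <- function(seqs) vapply(seqs, normalize_sequence, character(1), USE.NAMES = FALSE)

aa_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  tabulate(match(chars, AA_ALPHABET), nbins = 20L)
}

#' Average molecular weight of a mature protein
#'
#' Sum of average residue masses plus one water (18.0153 Da) for the
#' terminal H and OH.
#'
#' @param seq Character vector of sequences (normalized on the fly).
#' @param digits Decimals for the reported value; `NULL` for full
#'   precision.
#' @return Numeric vector of monomeric molecular weights in daltons.
#' @examples
#' molecular_weight("G")   # 75.07
#' molecular_weight("GG")  # 132.12
#' @export
molecular_weight <- function(seq, digits = 2) {
  mw <- vapply(norm_each(seq), function(s) {
    sum(aa_counts(s) * AA_RESIDUE_MASS) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  if (is.null(digits)) mw else round(mw, digits)
}

#' Molar extinction coefficients at 280 nm
#'
#' Reduced form counts free Trp and Tyr only; the oxidized form adds
#' 125 M^-1 cm^-1 per cystine (every two cysteines paired).  Both are
#' exposed because which state applies depends on the protein's
#' disulfide status, which the record does not know.
#'
#' @param seq Character vector of sequences.
#' @return For a single sequence, a named numeric vector
#'   `c(reduced =, oxidized =)`; for several, a two-column matrix with
#'   one row per sequence.
#' @examples
#' extinction_coefficient("CCWY")  # reduced 6990, oxidized 7115
#' @export
extinction_coefficient <- function(seq) {
  m <- t(vapply(norm_each(seq), function(s) {
    n <- aa_counts(s)
    reduced <- EXT_TRP * n[[match("W", AA_ALPHABET)]] +
      EXT_TYR * n[[match("Y", AA_ALPHABET)]]
    oxidized <- reduced + EXT_CYSTINE * (n[[match("C", AA_ALPHABET)]] %/% 2L)
    c(reduced = reduced, oxidized = oxidized)
  }, numeric(2), USE.NAMES = FALSE))
  colnames(m) <- c("reduced", "oxidized")
  if (nrow(m) == 1L) m[1L, ] else m
}

#' Absorbance of a 0.1% (1 mg/mL) solution at 280 nm
#'
#' `epsilon_reduced / MW`, in mL mg^-1 cm^-1; zero is a legal result for
#' chromophore-free sequences.  Computed from full-precision factors
#' before rounding.
#'
#' @inheritParams molecular_weight
#' @examples
#' absorbance_0_1pct("W")  # 26.93
#' @export
absorbance_0_1pct <- function(seq, digits = 2) {
  seqs <- norm_each(seq)
  eps <- extinction_coefficient(seqs)
  reduced <- if (is.matrix(eps)) eps[, "reduced"] else eps[["reduced"]]
  a <- reduced / molecular_weight(seqs, digits = NULL)
  if (is.null(digits)) a else round(a, digits)
}

#' Count potential N-linked glycosylation sites
#'
#' Scans for the sequon N-X-S/T with X != P; overlapping sequons are
#' each counted.  No exclusion is applied for a proline following the
#' S/T position.
#'
#' @param seq Character vector of sequences.
#' @return Integer vector of sequon counts.
#' @examples
#' count_nglyc_sites("NGT")   # 1
#' count_nglyc_sites("NPT")   # 0
#' count_nglyc_sites("NNTT")  # 2
#' @export
count_nglyc_sites <- function(seq) {
  vapply(norm_each(seq), function(s) {
    hits <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' All sequence-derived properties at once
#'
#' The set calculated at construct submission and copied read-only onto
#' downstream batch views.
#'
#' @param seq A single sequence.
#' @return A list with `molecular_weight`, `extinction_reduced`,
#'   `extinction_oxidized`, `absorbance_0_1pct` and `n_glyc_sites`.
#' @export
sequence_properties <- function(seq) {
  seq <- normalize_sequence(seq)
  eps <- extinction_coefficient(seq)
  list(
    molecular_weight    = molecular_weight(seq),
    extinction_reduced  = as.numeric(eps[["reduced"]]),
    extinction_oxidized = as.numeric(eps[["oxidized"]]),
    absorbance_0_1pct   = absorbance_0_1pct(seq),
    n_glyc_sites        = count_nglyc_sites(seq)
  )
}

#' Total purified mass of a batch
#'
#' @param concentration mg/mL, non-negative.
#' @param volume mL, non-negative.
#' @return Mass in mg, reported to 2 decimals (half-even).
#' @examples
#' batch_mass(1.37, 3.3)  # 4.52
#' @export
batch_mass <- function(concentration, volume) {
  if (any(concentration < 0) || any(volume < 0))
    pt_abort("negative_quantity", "concentration and volume must be non-negative")
  round(concentration * volume, 2)
}

#' Remaining mass from aliquot counts
#'
#' The batch record tracks original and current aliquot numbers; the
#' remaining mass is the total scaled by the remaining aliquot fraction
#' (aliquots are taken as equal portions).
#'
#' @param total_mass mg.
#' @param original_aliquots Count at batch creation, at least 1.
#' @param current_aliquots Count still in the freezer, in
#'   `[0, original_aliquots]`.
#' @return Remaining mass in mg, to 2 decimals.
#' @examples
#' remaining_mass(10, 10, 4)  # 4
#' @export
remaining_mass <- function(total_mass, original_aliquots, current_aliquots) {
  if (any(original_aliquots < 1) || any(current_aliquots < 0) ||
      any(current_aliquots > original_aliquots))
    pt_abort("aliquot_bounds",
             "need original_aliquots >= 1 and 0 <= current_aliquots <= original_aliquots")
  round(total_mass * current_aliquots / original_aliquots, 2)
}
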