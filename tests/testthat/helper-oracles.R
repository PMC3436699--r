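# Independent brute-force oracles for the sequence calculators.  The
# mass/extinction tables are typed here separately from the package so
# the oracle shares no code path with the implementation.

ORACLE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
ORACLE_WATER <- 18.0153

# character-by-character accumulation (no vectorised table lookup)
oracle_mw <- function(seq) {
  total <- ORACLE_WATER
  for (ch in strsplit(seq, "")[[1L]]) total <- total + ORACLE_MASS[[ch]]
  total
}

oracle_extinction <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  nW <- 0L; nY <- 0L; nC <- 0L
  for (ch in chars) {
    if (ch == "W") nW <- nW + 1L
    if (ch == "Y") nY <- nY + 1L
    if (ch == "C") nC <- nC + 1L
  }
  red <- 5500 * nW + 1490 * nY
  c(reduced = red, oxidized = red + 125 * (nC %/% 2L))
}

# sliding-window scan for N-{P}-[S/T], counting overlaps
oracle_sequons <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- 0L
  if (length(chars) >= 3L) {
    for (i in seq_len(length(chars) - 2L)) {
      if (chars[i] == "N" && chars[i + 1L] != "P" &&
          chars[i + 2L] %in% c("S", "T")) n <- n + 1L
    }
  }
  n
}

# second, regex-based sequon oracle: match N[^P][ST] at every offset
oracle_sequons_regex <- function(seq) {
  n <- 0L
  len <- nchar(seq)
  if (len >= 3L) {
    for (i in seq_len(len - 2L)) {
      if (grepl("^N[^P][ST]$", substr(seq, i, i + 2L))) n <- n + 1L
    }
  }
  n
}

# Cross-implementation spot checks (average MW and 280 nm extinction
# computed with an unrelated reference implementation; that tool uses a
# slightly different atomic-weight vintage, hence the relative
# tolerance on MW; extinction coefficients agree exactly).
XREF_PROPS <- data.frame(
  seq = c("MKWVTFISLLLLFSSAYS", "NGTWYCC", "ACDEFGHIKLMNPQRSTVWY", "W",
          "GNSTNATNPSNGTC"),
  mw  = c(2106.5243, 845.942, 2395.7134, 204.2252, 1337.3306),
  ext_reduced  = c(6990, 6990, 6990, 5500, 0),
  ext_oxidized = c(6990, 7115, 6990, 5500, 0),
  stringsAsFactors = FALSE)
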