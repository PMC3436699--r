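# Sequence-derived property calculations.

test_that("normalization strips noise, uppercases, and validates", {
  expect_identical(normalize_sequence("gws"), "GWS")
  expect_identical(normalize_sequence("  M K 1 V *"), "MKV")
  expect_identical(normalize_sequence("mkv\n\tgws2"), "MKVGWS")

  expect_error(normalize_sequence("  12 * "), class = "protrack_empty_sequence")
  err <- tryCatch(normalize_sequence("MXV"), condition = identity)
  expect_s3_class(err, "protrack_illegal_residue")
  expect_identical(err$residue, "X")
  expect_identical(err$position, 2L)
  for (bad in c("B", "J", "O", "U", "X", "Z"))
    expect_error(normalize_sequence(paste0("AA", bad)),
                 class = "protrack_illegal_residue")
})

test_that("molecular weight matches residue-sum values and the condensation identity", {
  expect_equal(molecular_weight("G"), 75.07)
  expect_equal(molecular_weight("GG"), 132.12)
  # condensation: MW(a++b) = MW(a) + MW(b) - water
  set.seed(42)
  for (i in 1:25) {
    a <- random_sequence(sample(1:80, 1))
    b <- random_sequence(sample(1:80, 1))
    expect_equal(molecular_weight(paste0(a, b), digits = NULL),
                 molecular_weight(a, digits = NULL) +
                   molecular_weight(b, digits = NULL) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("calculators agree with an unrelated reference implementation", {
  for (i in seq_len(nrow(XREF_PROPS))) {
    row <- XREF_PROPS[i, ]
    expect_equal(molecular_weight(row$seq, digits = NULL), row$mw,
                 tolerance = 5e-5)
    eps <- extinction_coefficient(row$seq)
    expect_equal(unname(eps[["reduced"]]), row$ext_reduced)
    expect_equal(unname(eps[["oxidized"]]), row$ext_oxidized)
  }
})

test_that("extinction coefficients follow the Trp/Tyr/cystine convention", {
  expect_equal(unname(extinction_coefficient("W")), c(5500, 5500))
  expect_equal(unname(extinction_coefficient("G")), c(0, 0))
  expect_equal(unname(extinction_coefficient("CCWY")), c(6990, 7115))
  # the cystine term is exactly 125 per pair, odd cysteines ignored
  set.seed(7)
  for (i in 1:50) {
    s <- random_sequence(sample(1:200, 1))
    eps <- extinction_coefficient(s)
    nC <- lengths(regmatches(s, gregexpr("C", s)))
    expect_identical(unname(eps[["oxidized"]] - eps[["reduced"]]),
                     125 * (nC %/% 2))
  }
})

test_that("0.1% absorbance is the reduced-extinction-to-mass ratio", {
  expect_equal(absorbance_0_1pct("W"), 26.93)
  expect_equal(absorbance_0_1pct("G"), 0)
  set.seed(11)
  for (i in 1:25) {
    s <- random_sequence(sample(1:150, 1))
    expect_equal(absorbance_0_1pct(s, digits = NULL),
                 unname(extinction_coefficient(s)[["reduced"]]) /
                   molecular_weight(s, digits = NULL))
  }
})

test_that("sequon counting honours the N-{P}-[S/T] rule with overlaps", {
  expect_identical(count_nglyc_sites("NGT"), 1L)
  expect_identical(count_nglyc_sites("NPT"), 0L)
  expect_identical(count_nglyc_sites("NNTT"), 2L)
  expect_identical(count_nglyc_sites("NGS"), 1L)
  expect_identical(count_nglyc_sites("NG"), 0L)
  expect_identical(count_nglyc_sites("GNSTNATNPSNGTC"), 3L)
})

test_that("appending residues never decreases MW and a buffered NGT adds one sequon", {
  set.seed(13)
  for (i in 1:25) {
    s <- random_sequence(sample(1:100, 1))
    extra <- random_sequence(1)
    expect_gte(molecular_weight(paste0(s, extra), digits = NULL),
               molecular_weight(s, digits = NULL))
    # the AA buffer prevents any cross-boundary sequon
    expect_identical(count_nglyc_sites(paste0(s, "AANGT")),
                     count_nglyc_sites(s) + 1L)
  }
})

test_that("mass bookkeeping is exact arithmetic with guarded bounds", {
  expect_equal(batch_mass(2, 5), 10)
  expect_equal(batch_mass(0, 5), 0)
  expect_equal(batch_mass(1.37, 3.3), 4.52)
  expect_error(batch_mass(-1, 5), class = "protrack_negative_quantity")

  expect_equal(remaining_mass(10, 10, 4), 4)
  expect_equal(remaining_mass(10, 10, 10), 10)
  expect_equal(remaining_mass(7.5, 3, 0), 0)
  expect_error(remaining_mass(10, 10, 11), class = "protrack_aliquot_bounds")
  expect_error(remaining_mass(10, 0, 0), class = "protrack_aliquot_bounds")
  expect_error(remaining_mass(10, 5, -1), class = "protrack_aliquot_bounds")
})
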