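test_that("glycan composition parsing handles written counts, aliases and rejects junk", {
  comp <- parse_glycan_composition("HexNAc(4)Hex(5)NeuAc(2)")
  expect_equal(unclass(comp),
               c(hexnac = 4L, hex = 5L, neuac = 2L, neugc = 0L, fuc = 0L))
  expect_equal(unclass(parse_glycan_composition("HexNAc(2)Hex(5)")),
               c(hexnac = 2L, hex = 5L, neuac = 0L, neugc = 0L, fuc = 0L))
  # dHex is an alias of Fuc and repeated tokens accumulate
  expect_equal(parse_glycan_composition("Fuc(1)dHex(1)")[["fuc"]], 2L)
  expect_error(parse_glycan_composition("HexNAc(4)Hex(5)NeuAc(2)Xyl(1)"),
               "Xyl")
  expect_error(parse_glycan_composition("HexNAc(1.5)"), "count")
  expect_error(parse_glycan_composition("HexNAc 4"), "token")
})

test_that("composition round-trips through its string form", {
  cases <- c("HexNAc(4)Hex(5)NeuAc(2)", "HexNAc(2)Hex(9)",
             "HexNAc(5)Hex(6)NeuAc(2)Fuc(1)", "Hex(1)", "NeuGc(3)Fuc(2)")
  for (txt in cases) {
    comp <- parse_glycan_composition(txt)
    expect_equal(parse_glycan_composition(format_glycan_composition(comp)),
                 comp, info = txt)
  }
})

test_that("glycan mass is the additive residue sum", {
  expect_equal(glycan_mass("Hex(1)"), 162.05282, tolerance = 1e-7)
  expect_equal(glycan_mass(as_glycan_composition(c(hexnac = 0L))), 0)
  # frozen independent sum: 2*203.07937 + 3*162.05282
  expect_equal(glycan_mass("HexNAc(2)Hex(3)"), 892.31720, tolerance = 1e-7)
  # additivity over component-wise composition sums
  a <- parse_glycan_composition("HexNAc(2)Hex(5)")
  b <- parse_glycan_composition("HexNAc(2)NeuAc(1)Fuc(1)")
  ab <- as_glycan_composition(unclass(a) + unclass(b))
  expect_equal(glycan_mass(ab), glycan_mass(a) + glycan_mass(b))
})

test_that("peptide mass matches residue-sum oracle with fixed mods", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_mass("ENGTISR"), 775.38242, tolerance = 1e-5)
  # carbamidomethyl-Cys on by default, removable
  expect_equal(peptide_mass("C"), 178.04121, tolerance = 1e-5)
  expect_equal(peptide_mass("C", fixed_mods = NULL), 121.01975,
               tolerance = 1e-5)
  expect_error(peptide_mass("ENGTIZR"), "non-canonical")
  expect_error(peptide_mass(""), "empty")
})

test_that("theoretical m/z follows the proton-adduct formula", {
  sp <- glycopeptide_species("ENGTISR", "HexNAc(2)Hex(3)", 2)
  expect_equal(theoretical_mz(sp), 834.85709, tolerance = 1e-5)
  # same neutral mass at higher charge gives lower m/z, monotonically
  mzs <- vapply(1:4, function(z)
    theoretical_mz(glycopeptide_species("ENGTISR", "HexNAc(2)Hex(3)", z)),
    numeric(1))
  expect_true(all(diff(mzs) < 0))
  expect_error(glycopeptide_species("ENGTISR", "HexNAc(2)Hex(3)", 0),
               "charge")
})

test_that("mobile proton count is charge minus basic sites, unclamped", {
  expect_equal(mobile_proton_count(
    glycopeptide_species("ENGTISR", "Hex(1)", 2)), 0)
  expect_equal(mobile_proton_count(
    glycopeptide_species("QDQCIYNTTYLNVQR", "Hex(1)", 4)), 2)
  expect_equal(mobile_proton_count(
    glycopeptide_species("HKR", "Hex(1)", 2)), -2)
  # increments by exactly one per added charge
  for (z in 1:5)
    expect_equal(mobile_proton_count(
      glycopeptide_species("QDQCIYNTTYLNVQR", "Hex(1)", z)), z - 2)
})

test_that("hydrophobicity is the additive scale sum and permutation invariant", {
  expect_equal(hydrophobicity("III"), 13.5)
  expect_equal(hydrophobicity("RRR"), -13.5)
  expect_equal(hydrophobicity("A"), kyte_doolittle_scale()[["A"]])
  set.seed(7)
  for (i in 1:5) {
    seqn <- paste(sample(names(kyte_doolittle_scale()), 12, replace = TRUE),
                  collapse = "")
    shuffled <- paste(sample(strsplit(seqn, "")[[1]]), collapse = "")
    expect_equal(hydrophobicity(seqn), hydrophobicity(shuffled))
  }
  expect_error(hydrophobicity("AAA", scale = c(A = 1)), "lacks")
})

test_that("glycan features classify sialylation, antennae and high-mannose", {
  f <- glycan_features("HexNAc(4)Hex(5)NeuAc(2)")
  expect_equal(f[c("n_sialic", "n_fucose", "n_antennae")],
               list(n_sialic = 2L, n_fucose = 0L, n_antennae = 2L))
  expect_false(f$is_high_mannose)
  f9 <- glycan_features("HexNAc(2)Hex(9)")
  expect_true(f9$is_high_mannose)
  expect_equal(f9$n_antennae, 0L)
  expect_equal(glycan_features("HexNAc(5)Hex(6)NeuAc(2)")$n_antennae, 3L)
  # fucosylated Man5-like composition is not high-mannose
  expect_false(glycan_features("HexNAc(2)Hex(5)Fuc(1)")$is_high_mannose)
  expect_equal(glycan_features("HexNAc(2)Hex(5)NeuGc(1)")$n_sialic, 1L)
})

test_that("feature vectors are internally consistent", {
  sim <- small_cohort()
  ft <- sim$features
  expect_equal(ft$total_mass, ft$peptide_mass + ft$glycan_mass,
               tolerance = 1e-9)
  expect_equal(ft$mz, (ft$total_mass + ft$charge * 1.00727646) / ft$charge,
               tolerance = 1e-9)
  expect_equal(ft$mono_neuac + ft$mono_neugc, ft$n_sialic)
  expect_true(all(ft$peptide_length >= 7 & ft$peptide_length <= 25))
  # mobile protons consistent with the aa counts
  expect_equal(ft$mobile_protons,
               ft$charge - (ft$aa_K + ft$aa_R + ft$aa_H + 1))
})

test_that("species list files round-trip", {
  sim <- small_cohort()
  sp <- sim$species[1:5]
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(
    sequence = vapply(sp, function(s) s$sequence, character(1)),
    glycan_composition = vapply(sp, function(s)
      format_glycan_composition(s$glycan), character(1)),
    charge = vapply(sp, function(s) s$charge, integer(1))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_species_list(path)
  expect_equal(vapply(back, species_key, character(1)),
               vapply(sp, species_key, character(1)))
  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sequence = "AAK"), bad, sep = "\t",
              row.names = FALSE)
  expect_error(read_species_list(bad), "glycan_composition")
})
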