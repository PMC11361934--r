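# Whole-sequence descriptor computations against hand evaluations and
# brute-force table lookups.

test_that("sequence validation normalizes case and rejects bad residues", {
  expect_identical(validate_sequence("casslgf"), "CASSLGF")
  expect_identical(validate_sequence("  CA SS\t"), "CASS")
  expect_error(validate_sequence("CA XS"), "'X' at position 3")
  expect_error(validate_sequence("SIINFEKL*"), "'\\*' at position 9")
  expect_error(validate_sequence(""), "empty")
  expect_error(validate_sequence("   "), "empty")
  expect_error(validate_sequence("PEPT1DE"), "'1'")
})

test_that("scale averages obey homopolymer, two-term and permutation identities", {
  kf1 <- scale_table("KF1")
  expect_equal(scale_average("GGGG", kf1), unname(kf1[["G"]]))
  expect_equal(scale_average("AG", kf1), (kf1[["A"]] + kf1[["G"]]) / 2)
  s <- "CASSLGQAYEQYF"
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(scale_average(s, kf1), scale_average(perm, kf1))
})

test_that("family descriptors have the documented dimensionality", {
  dims <- c(blosum_indices = 10, cruciani = 3, fasgai = 6, kidera = 10,
            mswhim = 3, pcp = 5, physical = 2, protfp = 8, sneath = 4,
            svger = 11, st_scales = 8, t_scales = 5, vhse = 8, z_scales = 5)
  fams <- aa_scale_families()
  expect_identical(names(fams), names(dims))
  expect_identical(lengths(fams), vapply(dims, as.integer, integer(1)))
  expect_identical(sum(lengths(fams)), 88L)
  for (f in names(dims)) {
    expect_length(family_descriptors("ARN", f), dims[[f]])
  }
  expect_error(family_descriptors("ARN", "atchley"), "unknown")
})

test_that("family descriptors equal a brute-force per-residue recomputation", {
  tab <- raw_scale_rows()
  fams <- aa_scale_families()
  seqs <- random_peptides(25, c(5, 20), seed = 71)
  for (s in seqs) {
    for (f in names(fams)) {
      got <- family_descriptors(s, f)
      want <- vapply(fams[[f]], brute_scale_average, numeric(1), seq = s,
                     tab = tab)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # homopolymer identity across every family dimension
  m <- raw_scale_rows()
  for (f in names(fams)) {
    got <- family_descriptors("WWWW", f)
    expect_equal(unname(got), unname(unlist(m[fams[[f]], "W"])),
                 tolerance = 1e-12)
  }
})

test_that("boman index is a per-residue mean of solubility values", {
  tab <- raw_scale_rows()
  expect_equal(boman("R"), tab["boman", "R"])
  expect_equal(boman("RRRR"), tab["boman", "R"])
  expect_equal(boman("FF"), boman("F"))
  expect_equal(boman("LK"), (tab["boman", "L"] + tab["boman", "K"]) / 2)
})

test_that("net charge follows the Henderson-Hasselbalch sum and decreases in pH", {
  pk <- pka_set()
  # independent three-term hand evaluation for "E" at pH 7
  hand <- 1 / (1 + 10^(7 - pk[["nterm"]])) -
    1 / (1 + 10^(pk[["cterm"]] - 7)) -
    1 / (1 + 10^(pk[["E"]] - 7))
  expect_equal(net_charge("E", pH = 7), hand, tolerance = 1e-12)
  # low-pH limit: protonated N-terminus + Lys, neutral C-terminus
  expect_equal(net_charge("K", pH = 0), 2, tolerance = 1e-2)
  for (s in random_peptides(10, c(5, 15), seed = 13)) {
    phs <- seq(0, 14, by = 0.5)
    qs <- vapply(phs, function(p) net_charge(s, p), numeric(1))
    expect_true(all(diff(qs) < 0))
  }
})

test_that("isoelectric point brackets the zero of the charge curve", {
  for (s in c("G", "KKKK", "DDEE", random_peptides(5, c(6, 12), seed = 3))) {
    pi_hat <- isoelectric_point(s, tol = 1e-6)
    expect_lt(abs(net_charge(s, pi_hat)), 1e-4)
  }
  # dense grid-search oracle for glycine
  grid <- seq(0, 14, by = 1e-4)
  qg <- vapply(grid, function(p) net_charge("G", p), numeric(1))
  zero_at <- grid[which.min(abs(qg))]
  expect_equal(isoelectric_point("G"), zero_at, tolerance = 1e-3)
  expect_gt(isoelectric_point("KKKK"), 7)
})

test_that("hydrophobicity is a mean over the chosen bundled scale", {
  tab <- raw_scale_rows()
  expect_equal(hydrophobicity("II"), tab["kyte_doolittle", "I"])
  expect_equal(hydrophobicity("IL"),
               (tab["kyte_doolittle", "I"] + tab["kyte_doolittle", "L"]) / 2)
  s <- "CASSLGQAYEQYF"
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(hydrophobicity(s), hydrophobicity(perm))
  expect_equal(hydrophobicity("W", "eisenberg"), tab["eisenberg", "W"])
  expect_error(hydrophobicity("W", "hopp_woods"), "unknown")
})

test_that("hydrophobic moment matches a direct trigonometric evaluation", {
  tab <- raw_scale_rows()
  # single residue: N = 1, cos 0 = 1, sin 0 = 0
  expect_equal(hydrophobic_moment("D"), abs(tab["eisenberg", "D"]))
  # angle 0: all phases aligned, best window's |mean hydrophobicity|
  s11 <- "LKALKDLKALW"
  h <- unlist(tab["eisenberg", strsplit(s11, "")[[1]]])
  expect_equal(hydrophobic_moment(s11, angle_deg = 0), abs(mean(h)))
  # independent direct evaluation of the trig sums for an 11-mer
  delta <- 100 * pi / 180
  i <- 0:10
  mu <- sqrt(sum(h * sin(i * delta))^2 + sum(h * cos(i * delta))^2) / 11
  expect_equal(hydrophobic_moment(s11), mu, tolerance = 1e-12)
  # windowing: a 12-mer takes the max over the two 11-windows
  s12 <- paste0(s11, "F")
  h2 <- unlist(tab["eisenberg", strsplit(s12, "")[[1]]])
  mus <- vapply(1:2, function(st) {
    hw <- h2[st:(st + 10)]
    sqrt(sum(hw * sin(i * delta))^2 + sum(hw * cos(i * delta))^2) / 11
  }, numeric(1))
  expect_equal(hydrophobic_moment(s12), max(mus), tolerance = 1e-12)
})

test_that("instability index sums dipeptide weights from the bundled table", {
  W <- diwv_table()
  expect_equal(instability_index("GG"), 10 / 2 * W["G", "G"])
  expect_equal(instability_index("WW"), 10 / 2 * W["W", "W"])
  s <- "CASSL"
  hand <- 10 / 5 * (W["C", "A"] + W["A", "S"] + W["S", "S"] + W["S", "L"])
  expect_equal(instability_index(s), hand, tolerance = 1e-12)
  expect_warning(v <- instability_index("W"), "length-1")
  expect_identical(v, 0)
})

test_that("instability and molecular weight agree with an external reference", {
  # biopython's ProtParam implements the same published dipeptide table and
  # average masses; cross-check on a fixed peptide
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "from Bio.SeqUtils.ProtParam import ProteinAnalysis;",
    "p=ProteinAnalysis('CASSLGQAYEQYF');",
    "print(p.instability_index(), p.molecular_weight())"))),
    stdout = TRUE, stderr = TRUE), warning = function(w) w)
  skip_if(inherits(out, "warning") || length(out) != 1L,
          "python reference unavailable")
  ref <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(instability_index("CASSLGQAYEQYF"), ref[1], tolerance = 1e-6)
  expect_equal(molecular_weight("CASSLGQAYEQYF"), ref[2], tolerance = 0.1)
})

test_that("molecular weight and m/z follow mass bookkeeping", {
  masses <- residue_masses()
  expect_equal(molecular_weight("G"), masses[["G"]] + 18.01524,
               tolerance = 1e-9)
  # appending any residue strictly increases the mass
  s <- "CASS"
  for (r in c("G", "W", "A")) {
    expect_gt(molecular_weight(paste0(s, r)), molecular_weight(s))
  }
  perm <- "SSCA"
  expect_equal(molecular_weight(s), molecular_weight(perm))
  expect_equal(mass_over_charge("G"), molecular_weight("G") + 1.00728)
  expect_lt(mass_over_charge("CASSLGF", z = 2), mass_over_charge("CASSLGF"))
  expect_equal(mass_over_charge("CASS", z = 2),
               (molecular_weight("CASS") + 2 * 1.00728) / 2)
  expect_error(mass_over_charge("CASS", z = 0), "z")
})

test_that("feature vectors have 96 named finite values in canonical order", {
  fv <- feature_vector("CASSLGQAYEQYF")
  expect_length(fv, 96)
  expect_true(all(is.finite(fv)))
  expect_identical(anyDuplicated(names(fv)), 0L)
  fams <- aa_scale_families()
  expect_identical(names(fv),
                   c(unlist(fams, use.names = FALSE),
                     c("boman", "charge", "hydrophobic_moment",
                       "hydrophobicity", "instability", "isoelectric_point",
                       "mw", "mz")))
  # determinism and composition with the standalone family call
  expect_identical(fv, feature_vector("CASSLGQAYEQYF"))
  expect_equal(fv[fams$kidera],
               family_descriptors("CASSLGQAYEQYF", "kidera"))
  expect_equal(fv[["charge"]], net_charge("CASSLGQAYEQYF", pH = 7))
})

test_that("descriptors except moment and instability are permutation invariant", {
  s <- "CASSLGQAYEQYF"
  perm <- "QAYCGLSSEQYFA"  # same residue multiset
  expect_identical(sort(strsplit(s, "")[[1]]), sort(strsplit(perm, "")[[1]]))
  fv_s <- feature_vector(s)
  fv_p <- feature_vector(perm)
  variant <- c("hydrophobic_moment", "instability")
  expect_equal(fv_s[setdiff(names(fv_s), variant)],
               fv_p[setdiff(names(fv_p), variant)], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(fv_s[["instability"]], fv_p[["instability"]])))
})

test_that("paired featurization concatenates prefixed blocks", {
  fp <- featurize_pair("SIINFEKL", "CASSLGQAYEQYF")
  expect_length(fp, 192)
  expect_equal(unname(fp[1:96]), unname(feature_vector("SIINFEKL")))
  expect_identical(names(fp)[1], "epi_BLOSUM1")
  expect_identical(names(fp)[97], "cdr_BLOSUM1")
  swapped <- featurize_pair("CASSLGQAYEQYF", "SIINFEKL")
  expect_equal(unname(swapped[97:192]), unname(fp[1:96]))
})

test_that("every scale average stays within its table's range", {
  fams <- aa_scale_families()
  tab <- raw_scale_rows()
  for (s in random_peptides(10, c(5, 18), seed = 99)) {
    for (f in names(fams)) {
      d <- family_descriptors(s, f)
      for (nm in names(d)) {
        row <- unlist(tab[nm, AA20])
        expect_gte(d[[nm]], min(row))
        expect_lte(d[[nm]], max(row))
      }
    }
  }
})
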