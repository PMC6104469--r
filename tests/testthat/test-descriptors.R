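twoAtomPair <- function(d = 1.0, q = c(1, -1)) {
  Molecule3D("pair", c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)),
             charges = list(N = q))
}

test_that("RDF blocks evaluate the Gaussian pair sum exactly", {
  cfg <- rdfConfig()
  m <- twoAtomPair(1.0, c(1, -1))
  mixed <- descriptorValues(rdfPairBlock(m, "N", "mixed", cfg))
  # single +1/-1 pair at its exact distance: product 1 * (-1), exponent 0
  expect_equal(unname(mixed[["RDF_N_a_10"]]), -1.0, tolerance = 1e-12)
  # Gaussian decay one Angstrom off the pair distance with B = 100
  expect_lt(abs(mixed[["RDF_N_a_20"]]), 1e-40)
  expect_true(all(mixed <= 0))
  expect_equal(max(abs(descriptorValues(
    rdfPairBlock(m, "N", "both_positive", cfg)))), 0)
  expect_equal(max(abs(descriptorValues(
    rdfPairBlock(m, "N", "both_negative", cfg)))), 0)
})

test_that("single atoms and single-sign molecules give empty pair classes", {
  lone <- Molecule3D("c", "C", matrix(0, 1, 3), charges = list(N = 0.1))
  full <- descriptorValues(rdfFull(lone, "N"))
  expect_length(full, 384)
  expect_equal(max(abs(full)), 0)
  allPos <- Molecule3D("pp", c("C", "C", "C"),
                       rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0)),
                       charges = list(N = c(0.2, 0.3, 0.1)))
  v <- descriptorValues(rdfFull(allPos, "N"))
  expect_equal(max(abs(v[1:128])), 0)        # mixed third
  expect_gt(max(abs(v[129:256])), 0)         # both-positive third
  expect_equal(max(abs(v[257:384])), 0)      # both-negative third
  # charge exactly zero belongs to no sign class
  zeroed <- attachCharges(allPos, c(0.2, 0, 0.1), "N")
  v0 <- descriptorValues(rdfFull(zeroed, "N"))
  pairSum <- oracleRDF(zeroed, "N", "both_positive", 1.2, 100)
  expect_equal(unname(v0[["RDF_N_b_12"]]), pairSum, tolerance = 1e-12)
})

test_that("RDF matches the brute-force oracle on random molecules", {
  set.seed(21)
  cfg <- rdfConfig()
  for (rep in 1:10) {
    m <- generateMolecule(smallSynthCfg())
    for (pc in c("mixed", "both_positive", "both_negative")) {
      fast <- descriptorValues(rdfPairBlock(m, "N", pc, cfg))
      slow <- vapply(cfg$grid, function(r) oracleRDF(m, "N", pc, r, cfg$B),
                     0)
      expect_equal(unname(fast), slow, tolerance = 1e-12)
    }
  }
})

test_that("dm axis follows the dipole and falls back to the principal mass axis", {
  m <- twoAtomPair(2.0, c(0.6, -0.6))
  dm <- pointChargeDipole(m, "N")
  ax <- dmAxis(dm, m)
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-12)
  expect_equal(abs(sum(ax * c(1, 0, 0))), 1, tolerance = 1e-12)
  # zero dipole, linear molecule along x -> (1, 0, 0) by the sign rule
  lin <- Molecule3D("lin", c("C", "C", "C"),
                    rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0)),
                    charges = list(N = c(0, 0, 0)))
  expect_equal(dmAxis(pointChargeDipole(lin, "N"), lin), c(1, 0, 0))
  # fully degenerate single atom -> conventional (1, 0, 0)
  lone <- Molecule3D("c", "C", matrix(0, 1, 3), charges = list(N = 0))
  expect_equal(dmAxis(pointChargeDipole(lone, "N"), lone), c(1, 0, 0))
})

test_that("PchmDM places masses and charges in the documented bins", {
  lone <- Molecule3D("c", "C", matrix(0, 1, 3), charges = list(N = 0))
  v <- descriptorValues(pchmBlock(lone, "N"))
  expect_length(v, 360)
  # single carbon at the com projects to t = 0, bin [0, 0.5) = bin 31
  expect_equal(unname(v[["PCHM_N_desc_mass_31"]]), 12.011)
  expect_equal(sum(abs(v[1:300])), 0)   # all five charge series zero
  expect_equal(sum(v[301:360]), 12.011)
})

test_that("PchmDM partition and conservation identities hold", {
  set.seed(22)
  for (rep in 1:5) {
    m <- generateMolecule(smallSynthCfg())
    v <- descriptorValues(pchmBlock(m, "N"))
    desc <- v[1:60]; plus <- v[61:120]; minus <- v[121:180]
    noH <- v[181:240]; hh <- v[241:300]; mass <- v[301:360]
    expect_equal(unname(desc), unname(plus + minus), tolerance = 1e-12)
    expect_equal(unname(desc), unname(noH + hh), tolerance = 1e-12)
    expect_equal(sum(desc), sum(charges(m, "N")), tolerance = 1e-9)
    expect_equal(sum(mass), sum(atomMasses(m)), tolerance = 1e-9)
  }
})

test_that("projections outside the range are clamped into terminal bins", {
  wide <- Molecule3D("wide", c("C", "C"),
                     rbind(c(-16, 0, 0), c(16, 0, 0)),
                     charges = list(N = c(0.3, -0.3)))
  expect_warning(v <- descriptorValues(pchmBlock(wide, "N")), "clamped")
  expect_equal(sum(v[301:360]), 2 * 12.011)  # mass conserved under clamping
})

test_that("descriptors are invariant to rigid motion and atom reordering", {
  set.seed(23)
  for (rep in 1:4) {
    m <- generateMolecule(smallSynthCfg())
    R <- randomRotation()
    mT <- transformMol(m, R, shift = stats::runif(3, -4, 4))
    expect_equal(descriptorValues(rdfFull(mT, "N")),
                 descriptorValues(rdfFull(m, "N")), tolerance = 1e-8)
    expect_equal(descriptorValues(pchmBlock(mT, "N")),
                 descriptorValues(pchmBlock(m, "N")), tolerance = 1e-8)
    perm <- sample(nAtoms(m))
    mP <- permuteMol(m, perm)
    expect_equal(descriptorValues(rdfFull(mP, "N")),
                 descriptorValues(rdfFull(m, "N")), tolerance = 1e-12)
    expect_equal(descriptorValues(pchmBlock(mP, "N")),
                 descriptorValues(pchmBlock(m, "N")), tolerance = 1e-12)
  }
})

test_that("MACCS keys are 166 binary values with the nitrile key behaving", {
  fpM <- descriptorValues(maccsBlock(fixMethane()))
  fpA <- descriptorValues(maccsBlock(fixAcetonitrile()))
  expect_length(fpM, 166)
  expect_true(all(fpM %in% c(0, 1)) && all(fpA %in% c(0, 1)))
  expect_equal(unname(fpM[["MACCS_41"]]), 0)  # no nitrile in methane
  expect_equal(unname(fpA[["MACCS_41"]]), 1)  # nitrile pattern key fires
  # batch interface agrees with the single-molecule path
  batch <- maccsMatrix(list(fixMethane(), fixAcetonitrile()))
  expect_equal(unname(batch[1, ]), unname(fpM))
  expect_equal(unname(batch[2, ]), unname(fpA))
})

test_that("feature recipes have the documented fixed layouts", {
  set.seed(24)
  m <- generateMolecule(smallSynthCfg())
  fC <- assembleFeatures(m, "C")
  fF <- assembleFeatures(m, "F")
  fM <- assembleFeatures(m, "MACCS_DM")
  expect_length(fC, 746)
  expect_length(fF, 912)
  expect_length(fM, 168)
  expect_identical(utils::tail(descriptorLabels(fC), 2), c("DM_N", "DM_P"))
  expect_identical(utils::tail(descriptorLabels(fM), 2), c("DM_N", "DM_P"))
  expect_false(anyDuplicated(descriptorLabels(fF)) > 0)
  # DM columns carry the Debye magnitudes
  expect_equal(unname(descriptorValues(fC)[["DM_N"]]),
               dipoleDebye(pointChargeDipole(m, "N")))
  # missing schemes are reported by name
  bare <- Molecule3D("bare", atomElements(m), atomCoords(m))
  expect_error(assembleFeatures(bare, "C"), "N, P")
})

test_that("featureMatrix stacks per-molecule blocks consistently", {
  set.seed(25)
  mols <- replicate(3, generateMolecule(smallSynthCfg()), simplify = FALSE)
  X <- featureMatrix(mols, "MACCS_DM")
  expect_equal(dim(X), c(3, 168))
  one <- descriptorValues(assembleFeatures(mols[[2]], "MACCS_DM"))
  expect_equal(unname(X[2, ]), unname(one))
  expect_identical(colnames(X), names(one))
})
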