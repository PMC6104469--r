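# Hand-written fixture molecules with bond blocks (for topology-based
# operations: PEOE, MACCS) and frozen reference charges.

fixMethane <- function() {
  Molecule3D("methane", c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0),
          c(0.6291, 0.6291, 0.6291), c(0.6291, -0.6291, -0.6291),
          c(-0.6291, 0.6291, -0.6291), c(-0.6291, -0.6291, 0.6291)),
    bonds = cbind(1L, 2:5, 1L))
}

fixWater <- function() {
  Molecule3D("water", c("O", "H", "H"),
    rbind(c(0, 0, 0.1173),
          c(0, 0.7572, -0.4692), c(0, -0.7572, -0.4692)),
    bonds = rbind(c(1L, 2L, 1L), c(1L, 3L, 1L)))
}

fixAcetonitrile <- function() {
  Molecule3D("acetonitrile", c("C", "C", "N", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.617, 0, 0),
          c(-0.36, 1.02, 0), c(-0.36, -0.51, 0.88),
          c(-0.36, -0.51, -0.88)),
    bonds = rbind(c(1L, 2L, 1L), c(2L, 3L, 3L), c(1L, 4L, 1L),
                  c(1L, 5L, 1L), c(1L, 6L, 1L)))
}

fixChloromethane <- function() {
  Molecule3D("chloromethane", c("C", "Cl", "H", "H", "H"),
    rbind(c(0, 0, 0), c(0, 0, 1.785),
          c(1.0277, 0, -0.3633), c(-0.5139, 0.8901, -0.3633),
          c(-0.5139, -0.8901, -0.3633)),
    bonds = rbind(c(1L, 2L, 1L), c(1L, 3L, 1L), c(1L, 4L, 1L),
                  c(1L, 5L, 1L)))
}

# Converged PEOE charges for the fixtures, computed with an independent
# reference implementation of the Gasteiger scheme (RDKit 2024.09,
# 12 iterations).  Frozen here as cross-check oracles.
refPEOE <- list(
  methane = c(-0.077558, 0.019389, 0.019389, 0.019389, 0.019389),
  water = c(-0.411510, 0.205755, 0.205755),
  acetonitrile = c(0.023601, 0.058715, -0.198658,
                   0.038781, 0.038781, 0.038781),
  chloromethane = c(0.010839, -0.130431, 0.039864, 0.039864, 0.039864)
)

# Uniform random proper rotation matrix (QR of a Gaussian matrix,
# determinant fixed to +1).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Rigidly transform a molecule's coordinates (charges untouched).
transformMol <- function(mol, R = diag(3), shift = c(0, 0, 0)) {
  Molecule3D(molId(mol), atomElements(mol),
             sweep(atomCoords(mol) %*% t(R), 2, -shift),
             bonds = bondBlock(mol), formalCharge = formalCharge(mol),
             charges = charges(mol), dmLabel = dmLabel(mol))
}

# Permute atom order (and bond/charge bookkeeping) of a molecule.
permuteMol <- function(mol, perm) {
  inv <- order(perm)
  bonds <- bondBlock(mol)
  if (nrow(bonds))
    bonds <- cbind(matrix(inv[bonds[, 1:2]], ncol = 2), bonds[, 3])
  Molecule3D(molId(mol), atomElements(mol)[perm],
             atomCoords(mol)[perm, , drop = FALSE],
             bonds = bonds, formalCharge = formalCharge(mol),
             charges = lapply(charges(mol), function(q) q[perm]),
             dmLabel = dmLabel(mol))
}

smallSynthCfg <- function(...) synthConfig(nAtomsRange = c(3L, 12L), ...)
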