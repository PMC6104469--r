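# Descriptor families:
#  - sign-partitioned charge-weighted radial distribution functions
#    RDF(r) = sum_{i<j in class} p_i p_j exp(-B (r - r_ij)^2)
#    sampled on an equally spaced radial grid;
#  - PchmDM: charges and masses binned along the dipole axis through the
#    center of mass;
#  - the 166-key MACCS substructure fingerprint (delegated to OpenBabel
#    through ChemmineOB).

#' RDF descriptor configuration
#'
#' Defaults match the standard setup: 128 grid points between 0 and
#' 12.8 Angstrom (step 0.1, grid r_k = k * 0.1 for k = 1..128; r = 0 is
#' excluded since no atom pair has zero distance) and fuzziness B = 100
#' per square Angstrom.
#'
#' @param nPoints number of radial grid points.
#' @param rMax largest grid radius (Angstrom).
#' @param B Gaussian fuzziness parameter (Angstrom^-2).
#' @return A list with the grid and parameters.
#' @export
rdfConfig <- function(nPoints = 128L, rMax = 12.8, B = 100) {
  stopifnot(nPoints >= 1, rMax > 0, B > 0)
  list(nPoints = as.integer(nPoints), rMax = rMax, B = B,
       grid = seq_len(nPoints) * (rMax / nPoints))
}

.PAIR_CLASSES <- c(mixed = "a", both_positive = "b", both_negative = "c")

.pairIndices <- function(q, pairClass) {
  n <- length(q)
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  keep <- switch(pairClass,
    mixed = (q[i] > 0 & q[j] < 0) | (q[i] < 0 & q[j] > 0),
    both_positive = q[i] > 0 & q[j] > 0,
    both_negative = q[i] < 0 & q[j] < 0,
    stop("unknown pair class: ", pairClass))
  cbind(i = i[keep], j = j[keep])
}

#' Sign-partitioned charge-weighted RDF descriptors (one pair class)
#'
#' Evaluates, at each grid radius r, the sum over unordered atom pairs in
#' the requested charge-sign class of \eqn{p_i p_j \exp(-B (r -
#' r_{ij})^2)}.  Raw signed charge products are kept, so the mixed block
#' is non-positive everywhere and the like-sign blocks non-negative.
#' Atoms with charge exactly zero belong to no class.
#'
#' @param mol a \linkS4class{Molecule3D} with \code{scheme} attached.
#' @param scheme charge scheme name.
#' @param pairClass one of \code{"mixed"} (one positive, one negative
#'   charge), \code{"both_positive"}, \code{"both_negative"}.
#' @param cfg an \code{\link{rdfConfig}} list.
#' @return A \linkS4class{DescriptorBlock} of length \code{cfg$nPoints},
#'   labeled \code{RDF_<scheme>_<a|b|c>_<k>} (classes a, b, c in the
#'   order above).
#' @export
rdfPairBlock <- function(mol, scheme, pairClass = c("mixed",
                         "both_positive", "both_negative"),
                         cfg = rdfConfig()) {
  pairClass <- match.arg(pairClass)
  q <- charges(mol, scheme)
  pairs <- .pairIndices(q, pairClass)
  vals <- numeric(cfg$nPoints)
  if (nrow(pairs)) {
    xyz <- atomCoords(mol)
    d <- sqrt(rowSums((xyz[pairs[, "i"], , drop = FALSE] -
                       xyz[pairs[, "j"], , drop = FALSE])^2))
    p <- q[pairs[, "i"]] * q[pairs[, "j"]]
    # pairs x grid Gaussian matrix, then charge-product weighted sum
    g <- exp(-cfg$B * (outer(d, cfg$grid, "-"))^2)
    vals <- as.numeric(colSums(p * g))
  }
  new("DescriptorBlock",
      labels = sprintf("RDF_%s_%s_%d", scheme, .PAIR_CLASSES[[pairClass]],
                       seq_len(cfg$nPoints)),
      values = vals, family = "RDF", scheme = scheme,
      config = cfg[c("nPoints", "rMax", "B")])
}

#' Full RDF descriptor set (three pair classes)
#'
#' Concatenates the mixed, both-positive and both-negative RDF blocks in
#' that order; with the default grid this is 3 x 128 = 384 descriptors.
#'
#' @inheritParams rdfPairBlock
#' @return A \linkS4class{DescriptorBlock} of length
#'   \code{3 * cfg$nPoints}.
#' @export
rdfFull <- function(mol, scheme, cfg = rdfConfig()) {
  blocks <- lapply(names(.PAIR_CLASSES), function(pc)
    rdfPairBlock(mol, scheme, pc, cfg))
  new("DescriptorBlock",
      labels = unlist(lapply(blocks, descriptorLabels)),
      values = unlist(lapply(blocks, function(b) b@values)),
      family = "RDF", scheme = scheme,
      config = cfg[c("nPoints", "rMax", "B")])
}

#' PchmDM configuration
#'
#' Defaults: 60 half-open bins of width 0.5 Angstrom covering [-15, 15)
#' on the dipole axis, origin at the center of mass.
#'
#' @param nBins number of bins.
#' @param binWidth bin width (Angstrom).
#' @param range length-2 numeric, the projected interval covered.
#' @return A list with the binning parameters.
#' @export
pchmConfig <- function(nBins = 60L, binWidth = 0.5, range = c(-15, 15)) {
  stopifnot(nBins >= 1, binWidth > 0, length(range) == 2)
  if (abs(diff(range) - nBins * binWidth) > 1e-9)
    stop("nBins * binWidth must span the range exactly")
  list(nBins = as.integer(nBins), binWidth = binWidth, range = range)
}

#' Dipole axis of a molecule
#'
#' Unit vector along the point-charge dipole.  When the dipole is
#' degenerate (|mu| < 1e-10 e*Angstrom) the principal axis of the mass
#' distribution with the largest gyration eigenvalue is used instead,
#' with the sign fixed so that the first nonzero component is positive;
#' a single atom (fully degenerate) yields (1, 0, 0) by convention.
#'
#' @param dm a \linkS4class{DipoleResult} computed for \code{mol}.
#' @param mol the corresponding \linkS4class{Molecule3D}.
#' @return A unit length-3 vector.
#' @export
dmAxis <- function(dm, mol) {
  v <- dipoleVector(dm)
  nv <- sqrt(sum(v^2))
  if (nv >= 1e-10) return(v / nv)
  # fallback: dominant principal axis of the mass distribution
  m <- atomMasses(mol)
  centered <- sweep(atomCoords(mol), 2, centerOfMass(mol))
  gyr <- crossprod(centered * sqrt(m))
  if (max(abs(gyr)) < 1e-18) return(c(1, 0, 0))
  ev <- eigen(gyr, symmetric = TRUE)
  ax <- ev$vectors[, 1]
  nz <- which(abs(ax) > 1e-12)
  if (!length(nz)) return(c(1, 0, 0))
  if (ax[nz[1]] < 0) ax <- -ax
  ax
}

.PCHM_SERIES <- c("desc", "desc_plus", "desc_minus", "desc_noH",
                  "desc_H", "desc_mass")

#' PchmDM descriptors: charge/mass projections along the dipole axis
#'
#' Each atom is projected onto the dipole axis of the same charge
#' scheme, t = (r - com) . axis, and accumulated into half-open bins
#' [lo, lo + width) starting at the lower range limit.  Projections
#' outside the range are clamped into the terminal bins (with a warning),
#' which preserves the conservation identities.  Six series are produced
#' in fixed order: desc (all charges), desc_plus (charges > 0),
#' desc_minus (charges < 0), desc_noH (charges on non-hydrogen atoms),
#' desc_H (charges on hydrogens), desc_mass (atomic masses).
#'
#' @param mol a \linkS4class{Molecule3D} with \code{scheme} attached.
#' @param scheme charge scheme name; the dipole axis is derived from the
#'   same scheme's point-charge dipole.
#' @param cfg a \code{\link{pchmConfig}} list.
#' @return A \linkS4class{DescriptorBlock} of length
#'   \code{6 * cfg$nBins} (360 with defaults), labeled
#'   \code{PCHM_<scheme>_<series>_<k>}.
#' @export
pchmBlock <- function(mol, scheme, cfg = pchmConfig()) {
  q <- charges(mol, scheme)
  dm <- pointChargeDipole(mol, scheme)
  axis <- dmAxis(dm, mol)
  t <- as.numeric(sweep(atomCoords(mol), 2, dm@com) %*% axis)
  bin <- floor((t - cfg$range[1]) / cfg$binWidth) + 1L
  if (any(bin < 1L | bin > cfg$nBins)) {
    warning("projection(s) outside [", cfg$range[1], ", ", cfg$range[2],
            ") for molecule '", molId(mol),
            "'; clamped into terminal bins")
    bin <- pmin(pmax(bin, 1L), cfg$nBins)
  }
  acc <- function(w) {
    out <- numeric(cfg$nBins)
    s <- tapply(w, bin, sum)
    out[as.integer(names(s))] <- s
    out
  }
  isH <- atomElements(mol) == "H"
  series <- list(
    desc = acc(q),
    desc_plus = acc(q * (q > 0)),
    desc_minus = acc(q * (q < 0)),
    desc_noH = acc(q * (!isH)),
    desc_H = acc(q * isH),
    desc_mass = acc(atomMasses(mol))
  )
  new("DescriptorBlock",
      labels = unlist(lapply(.PCHM_SERIES, function(s)
        sprintf("PCHM_%s_%s_%d", scheme, s, seq_len(cfg$nBins)))),
      values = unlist(series, use.names = FALSE),
      family = "PCHM", scheme = scheme,
      config = cfg)
}

# Molecule3D (or list) -> ChemmineR SDFset, via the package's own V2000
# writer; used to hand structures to OpenBabel.
.toSDFset <- function(mols) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeSDF(mols, tmp)
  suppressWarnings(ChemmineR::read.SDFset(tmp))
}

#' MACCS fingerprint block
#'
#' Standard 166-key MACCS substructure fingerprint as 0/1 values,
#' computed by OpenBabel (via ChemmineOB).  For molecules without a bond
#' block the keys are evaluated on the atoms as given (no bond
#' perception), so only composition-type keys can fire.
#'
#' @param mol a \linkS4class{Molecule3D}.
#' @return A \linkS4class{DescriptorBlock} of length 166, labels
#'   \code{MACCS_1..MACCS_166}.
#' @export
maccsBlock <- function(mol) {
  m <- maccsMatrix(list(mol))
  new("DescriptorBlock",
      labels = colnames(m), values = as.numeric(m[1, ]),
      family = "MACCS", scheme = "", config = list())
}

#' MACCS fingerprints for a list of molecules
#'
#' @param mols list of \linkS4class{Molecule3D}.
#' @return Integer matrix (molecules x 166 keys) of 0/1 values with
#'   columns \code{MACCS_1..MACCS_166} and molecule ids as row names.
#' @export
maccsMatrix <- function(mols) {
  if (is(mols, "Molecule3D")) mols <- list(mols)
  sdfset <- .toSDFset(mols)
  if (length(sdfset) != length(mols))
    stop("MACCS fingerprinting failed: ", length(mols) - length(sdfset),
         " molecule(s) could not be converted")
  fp <- tryCatch(ChemmineR::fingerprintOB(sdfset, "MACCS"),
                 error = function(e)
                   stop("MACCS fingerprint engine failed: ",
                        conditionMessage(e)))
  bits <- fp@fpma[, seq_len(166L), drop = FALSE]  # FPset bit matrix
  dimnames(bits) <- list(vapply(mols, molId, ""),
                         sprintf("MACCS_%d", seq_len(166L)))
  bits
}
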