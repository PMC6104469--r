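# Synthetic charged point-charge clouds emulating the envelope of small
# neutral organic molecules (3-19 atoms of H/C/N/O/F/S/Cl/Br/P, partial
# charges of a few tenths of an elementary charge summing exactly to the
# net charge, coordinates within a ~12 Angstrom extent).  No bonds are
# generated: operations needing connectivity (PEOE, MACCS substructure
# keys) are exercised on real hand-written structures instead.
#
# This file also hosts the deliberately naive brute-force oracles used
# to cross-check the vectorized descriptor and dipole code.

#' Synthetic molecule configuration
#'
#' Defaults emulate the composition envelope of small neutral organics:
#' 3-19 atoms drawn from H/C/N/O/F/S/Cl/Br/P with organic-like
#' frequencies, coordinates rejection-sampled in a cube of side
#' \code{maxExtent} with a minimum interatomic distance, and per-atom
#' charges drawn from a centered Gaussian of scale \code{chargeScale}
#' then mean-shifted to hit the net charge exactly.
#'
#' @param nAtomsRange length-2 integer range of atom counts.
#' @param elementFreq named numeric vector of element sampling weights.
#' @param minDist minimum interatomic distance (Angstrom).
#' @param maxExtent cube side for coordinate sampling (Angstrom).
#' @param chargeScale standard deviation of the charge draws (e).
#' @param netCharge net molecular charge (e).
#' @return Configuration list.
#' @export
synthConfig <- function(nAtomsRange = c(3L, 19L),
                        elementFreq = c(H = 0.44, C = 0.35, N = 0.07,
                                        O = 0.09, F = 0.015, S = 0.012,
                                        Cl = 0.012, Br = 0.005,
                                        P = 0.006),
                        minDist = 0.9, maxExtent = 12,
                        chargeScale = 0.3, netCharge = 0L) {
  stopifnot(minDist > 0, maxExtent > 0,
            all(names(elementFreq) %in% .SUPPORTED_ELEMENTS),
            nAtomsRange[1] >= 1, nAtomsRange[2] >= nAtomsRange[1])
  list(nAtomsRange = as.integer(nAtomsRange), elementFreq = elementFreq,
       minDist = minDist, maxExtent = maxExtent,
       chargeScale = chargeScale, netCharge = as.integer(netCharge))
}

#' Generate one synthetic molecule
#'
#' Draws the atom count, elements, coordinates and two independent
#' charge schemes (\code{"N"} and \code{"P"}) under \code{cfg}.  The two
#' schemes are drawn independently so their dipoles differ, as the two
#' empirical charge schemes do on real molecules.  Uses the current RNG
#' state; seed with \code{set.seed} for reproducibility.
#'
#' @param cfg a \code{\link{synthConfig}} list.
#' @param id molecule identifier.
#' @return A \linkS4class{Molecule3D} with schemes \code{"N"} and
#'   \code{"P"} attached and no bonds.
#' @export
generateMolecule <- function(cfg = synthConfig(), id = "synth") {
  n <- if (cfg$nAtomsRange[1] == cfg$nAtomsRange[2]) cfg$nAtomsRange[1]
       else sample(cfg$nAtomsRange[1]:cfg$nAtomsRange[2], 1L)
  elements <- sample(names(cfg$elementFreq), n, replace = TRUE,
                     prob = cfg$elementFreq)
  half <- cfg$maxExtent / 2
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      cand <- stats::runif(3, -half, half)
      if (i == 1L || all(sqrt(colSums((t(coords[seq_len(i - 1L), ,
                          drop = FALSE]) - cand)^2)) >= cfg$minDist)) {
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place atom ", i, " within 10000 attempts; ",
           "increase maxExtent or reduce the atom count")
  }
  drawCharges <- function() {
    q <- stats::rnorm(n, 0, cfg$chargeScale)
    q - mean(q) + cfg$netCharge / n
  }
  Molecule3D(id, elements, coords, formalCharge = cfg$netCharge,
             charges = list(N = drawCharges(), P = drawCharges()))
}

#' Generate a labeled synthetic dataset
#'
#' Labels are planted as |point-charge dipole magnitude under scheme
#' \code{"N"}| plus Gaussian noise (clipped at zero), so that descriptor
#' and model code can be validated on data whose signal is known by
#' construction.
#'
#' @param n number of molecules.
#' @param cfg a \code{\link{synthConfig}} list.
#' @param noiseSd label noise standard deviation (Debye), default 0.3.
#' @param seed integer seed.
#' @return List of labeled \linkS4class{Molecule3D} objects.
#' @export
generateLabeledDataset <- function(n, cfg = synthConfig(), noiseSd = 0.3,
                                   seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- generateMolecule(cfg, id = sprintf("synth_%05d", i))
    dm <- dipoleDebye(pointChargeDipole(m, "N"))
    dmLabel(m) <- max(0, dm + stats::rnorm(1, 0, noiseSd))
    m
  })
}

#' Brute-force RDF oracle (single grid point)
#'
#' Deliberately naive reference implementation: a plain double loop over
#' all atom pairs, scalar arithmetic only, sharing no code with
#' \code{\link{rdfPairBlock}}.  Used to cross-check the vectorized
#' descriptor engine.
#'
#' @param mol a \linkS4class{Molecule3D}.
#' @param scheme charge scheme name.
#' @param pairClass \code{"mixed"}, \code{"both_positive"} or
#'   \code{"both_negative"}.
#' @param r radius (Angstrom) at which to evaluate.
#' @param B Gaussian fuzziness (Angstrom^-2).
#' @return Scalar RDF value.
#' @export
oracleRDF <- function(mol, scheme, pairClass, r, B = 100) {
  q <- charges(mol, scheme)
  xyz <- atomCoords(mol)
  n <- length(q)
  total <- 0
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      qi <- q[i]
      qj <- q[j]
      inClass <- switch(pairClass,
        mixed = (qi > 0 && qj < 0) || (qi < 0 && qj > 0),
        both_positive = qi > 0 && qj > 0,
        both_negative = qi < 0 && qj < 0,
        stop("unknown pair class: ", pairClass))
      if (!inClass) next
      dx <- xyz[i, 1] - xyz[j, 1]
      dy <- xyz[i, 2] - xyz[j, 2]
      dz <- xyz[i, 3] - xyz[j, 3]
      dij <- sqrt(dx * dx + dy * dy + dz * dz)
      total <- total + qi * qj * exp(-B * (r - dij)^2)
    }
  }
  total
}

#' Brute-force point-charge dipole oracle
#'
#' Independent loop-based summation of \eqn{q_i (r_i - com)}, sharing no
#' code with \code{\link{pointChargeDipole}}.
#'
#' @param mol a \linkS4class{Molecule3D}.
#' @param scheme charge scheme name.
#' @return Length-3 dipole vector (e*Angstrom).
#' @export
oracleDipole <- function(mol, scheme) {
  q <- charges(mol, scheme)
  xyz <- atomCoords(mol)
  m <- atomMasses(mol)
  com <- c(0, 0, 0)
  for (i in seq_along(m)) com <- com + m[i] * xyz[i, ]
  com <- com / sum(m)
  v <- c(0, 0, 0)
  for (i in seq_along(q)) v <- v + q[i] * (xyz[i, ] - com)
  v
}
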