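# Point-charge dipole moment: mu = sum_i q_i (r_i - com), with the
# center of mass as origin.  For neutral molecules the vector is
# origin-independent; for ions it is not, and the center-of-mass origin
# is the documented convention.

#' Debye per elementary-charge-Angstrom
#'
#' Unit conversion constant: 1 e*Angstrom = 4.803205 D (from the
#' elementary charge and the definition of the Debye).
#'
#' @export
DEBYE_PER_EA <- 4.803205

#' Center of mass
#'
#' Mass-weighted mean position using conventional atomic weights.
#'
#' @param mol a \linkS4class{Molecule3D}.
#' @return Numeric length-3 vector (Angstrom).
#' @examples
#' co <- Molecule3D("co", c("C", "O"), rbind(c(0, 0, 0), c(1.128, 0, 0)))
#' centerOfMass(co)  # x ~ 0.6443
#' @export
centerOfMass <- function(mol) {
  stopifnot(is(mol, "Molecule3D"))
  m <- atomMasses(mol)
  as.numeric(colSums(atomCoords(mol) * m) / sum(m))
}

#' Point-charge dipole moment
#'
#' Treats the attached partial charges of \code{scheme} as point charges
#' at the nuclei and sums \eqn{q_i (r_i - r_{com})}.  The magnitude is
#' reported in Debye.  For molecules with nonzero net charge the
#' magnitude depends on the origin; the center of mass is always used,
#' and a message notes the origin dependence.
#'
#' @param mol a \linkS4class{Molecule3D} with \code{scheme} attached.
#' @param scheme charge scheme name (e.g. \code{"N"}, \code{"P"}).
#' @return A \linkS4class{DipoleResult}.
#' @examples
#' m <- Molecule3D("pair", c("C", "C"), rbind(c(1, 0, 0), c(-1, 0, 0)),
#'                 charges = list(N = c(0.5, -0.5)))
#' pointChargeDipole(m, "N")  # |mu| = 1 e*A = 4.803205 D
#' @export
pointChargeDipole <- function(mol, scheme) {
  stopifnot(is(mol, "Molecule3D"))
  q <- charges(mol, scheme)
  com <- centerOfMass(mol)
  centered <- sweep(atomCoords(mol), 2, com)
  vec <- as.numeric(colSums(centered * q))
  if (formalCharge(mol) != 0L)
    message("molecule '", molId(mol), "' carries net charge ",
            formalCharge(mol),
            " e: dipole magnitude is origin-dependent (center of mass used)")
  new("DipoleResult", scheme = scheme, vector = vec,
      magnitudeDebye = sqrt(sum(vec^2)) * DEBYE_PER_EA, com = com)
}

#' @rdname dipole-accessors
#' @export
setGeneric("dipoleVector", function(x) standardGeneric("dipoleVector"))
#' @rdname dipole-accessors
#' @export
setGeneric("dipoleDebye", function(x) standardGeneric("dipoleDebye"))

#' Accessors for DipoleResult
#'
#' @param x a \linkS4class{DipoleResult}.
#' @return \code{dipoleVector}: the dipole vector in e*Angstrom;
#'   \code{dipoleDebye}: the magnitude in Debye.
#' @name dipole-accessors
NULL

#' @rdname dipole-accessors
setMethod("dipoleVector", "DipoleResult", function(x) x@vector)
#' @rdname dipole-accessors
setMethod("dipoleDebye", "DipoleResult", function(x) x@magnitudeDebye)
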