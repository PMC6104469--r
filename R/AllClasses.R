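#' @import methods
NULL

# Conventional (IUPAC) standard atomic weights for the supported element set.
# Isotope annotations in input files are ignored.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  S = 32.06, Cl = 35.45, Br = 79.904, P = 30.974
)

.SUPPORTED_ELEMENTS <- names(.ATOMIC_WEIGHTS)

#' Supported chemical elements
#'
#' The element set covered by the molecular data model: H, C, N, O, F, S,
#' Cl, Br and P (the composition envelope of small neutral organic
#' molecules this package targets).
#'
#' @return Character vector of element symbols.
#' @export
supportedElements <- function() .SUPPORTED_ELEMENTS

#' Molecule3D: a 3D molecular structure with per-atom charge sets
#'
#' The central data container: an ordered set of atoms with element
#' symbols, conventional atomic weights, Cartesian coordinates in
#' Angstrom, optional connectivity (bond block), and any number of named
#' per-atom partial-charge schemes (e.g. \code{"P"} for PEOE charges,
#' \code{"N"} for externally predicted NBO-style charges).  An optional
#' dipole-moment label (Debye) makes the object a labeled record for
#' supervised modeling.
#'
#' @slot id character(1), molecule identifier.
#' @slot elements character vector of element symbols, one per atom.
#' @slot masses numeric vector of atomic masses (amu), aligned to atoms.
#' @slot coords numeric n x 3 matrix of coordinates (Angstrom).
#' @slot bonds integer m x 3 matrix (atom1, atom2, order); zero rows when
#'   connectivity is unknown (e.g. synthetic point-charge clouds).
#' @slot charges named list of numeric vectors; each element is a full
#'   per-atom charge set (elementary charge units) for one scheme.
#' @slot formalCharge integer(1), net molecular charge (e).
#' @slot dmLabel numeric(1), reference dipole magnitude in Debye, or
#'   \code{NA_real_} when absent.
#' @slot flags character vector of quality flags (e.g. \code{"suspect2D"}
#'   for all-zero z coordinates).
#'
#' @exportClass Molecule3D
setClass("Molecule3D",
  representation(
    id = "character",
    elements = "character",
    masses = "numeric",
    coords = "matrix",
    bonds = "matrix",
    charges = "list",
    formalCharge = "integer",
    dmLabel = "numeric",
    flags = "character"
  ),
  prototype(
    id = "mol", elements = character(0), masses = numeric(0),
    coords = matrix(numeric(0), 0, 3), bonds = matrix(integer(0), 0, 3),
    charges = list(), formalCharge = 0L, dmLabel = NA_real_,
    flags = character(0)
  )
)

setValidity("Molecule3D", function(object) {
  n <- length(object@elements)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "molecule must contain at least one atom")
  bad <- setdiff(unique(object@elements), .SUPPORTED_ELEMENTS)
  if (length(bad))
    msgs <- c(msgs, paste0("unsupported element(s): ",
                           paste(bad, collapse = ", ")))
  if (length(object@masses) != n || any(object@masses <= 0))
    msgs <- c(msgs, "masses must be positive and aligned to atoms")
  if (!is.numeric(object@coords) || nrow(object@coords) != n ||
      ncol(object@coords) != 3 || any(!is.finite(object@coords)))
    msgs <- c(msgs, "coords must be a finite n x 3 numeric matrix")
  if (ncol(object@bonds) != 3)
    msgs <- c(msgs, "bonds must have three columns (atom1, atom2, order)")
  if (nrow(object@bonds) > 0) {
    idx <- object@bonds[, 1:2]
    if (any(idx < 1L) || any(idx > n))
      msgs <- c(msgs, "bond atom indices out of range")
  }
  for (s in names(object@charges)) {
    if (length(object@charges[[s]]) != n || any(!is.finite(object@charges[[s]])))
      msgs <- c(msgs, paste0("charge scheme '", s,
                             "' must cover all atoms with finite values"))
  }
  if (length(object@dmLabel) != 1L ||
      (!is.na(object@dmLabel) && object@dmLabel < 0))
    msgs <- c(msgs, "dmLabel must be a single non-negative value or NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule3D
#'
#' @param id molecule identifier.
#' @param elements character vector of element symbols (H, C, N, O, F, S,
#'   Cl, Br, P).
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param bonds optional m x 3 matrix (atom1, atom2, order), 1-based
#'   indices in atom order; omit for structures without connectivity.
#' @param formalCharge net molecular charge (e).
#' @param charges optional named list of per-atom charge vectors.
#' @param dmLabel optional reference dipole magnitude (Debye).
#' @param flags optional character vector of quality flags.
#'
#' @return A validated \linkS4class{Molecule3D}.
#' @examples
#' m <- Molecule3D("hf", c("H", "F"),
#'                 rbind(c(0, 0, 0), c(0.92, 0, 0)))
#' nAtoms(m)
#' @export
Molecule3D <- function(id, elements, coords,
                       bonds = matrix(integer(0), 0, 3),
                       formalCharge = 0L, charges = list(),
                       dmLabel = NA_real_, flags = character(0)) {
  elements <- as.character(elements)
  bad <- setdiff(unique(elements), .SUPPORTED_ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  coords <- matrix(as.numeric(coords), ncol = 3)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  new("Molecule3D",
      id = as.character(id), elements = elements,
      masses = unname(.ATOMIC_WEIGHTS[elements]), coords = coords,
      bonds = bonds, charges = charges,
      formalCharge = as.integer(formalCharge),
      dmLabel = as.numeric(dmLabel), flags = flags)
}

#' DipoleResult: a point-charge dipole for one molecule and scheme
#'
#' @slot scheme charge scheme name used.
#' @slot vector dipole vector in e*Angstrom, about the center of mass.
#' @slot magnitudeDebye dipole magnitude in Debye.
#' @slot com center of mass (Angstrom) used as origin.
#'
#' @exportClass DipoleResult
setClass("DipoleResult",
  representation(scheme = "character", vector = "numeric",
                 magnitudeDebye = "numeric", com = "numeric"))

setValidity("DipoleResult", function(object) {
  msgs <- character(0)
  if (length(object@vector) != 3 || length(object@com) != 3)
    msgs <- c(msgs, "vector and com must have length 3")
  mu <- sqrt(sum(object@vector^2)) * DEBYE_PER_EA
  if (object@magnitudeDebye < 0)
    msgs <- c(msgs, "magnitude must be non-negative")
  if (abs(mu - object@magnitudeDebye) > 1e-9 * max(1, mu))
    msgs <- c(msgs, "magnitude inconsistent with vector")
  if (length(msgs)) msgs else TRUE
})

#' DescriptorBlock: a named fixed-length descriptor vector
#'
#' @slot labels ordered column labels.
#' @slot values aligned numeric values.
#' @slot family descriptor family tag (e.g. "RDF", "PCHM", "MACCS",
#'   "recipe_C").
#' @slot scheme charge scheme the block was derived from ("" when not
#'   charge-based).
#' @slot config list of the configuration the block was computed under.
#'
#' @exportClass DescriptorBlock
setClass("DescriptorBlock",
  representation(labels = "character", values = "numeric",
                 family = "character", scheme = "character",
                 config = "list"))

setValidity("DescriptorBlock", function(object) {
  msgs <- character(0)
  if (length(object@labels) != length(object@values))
    msgs <- c(msgs, "labels and values must have equal length")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: regression metrics for one prediction set
#'
#' @slot mae mean absolute error (Debye).
#' @slot rmse root-mean-square error (Debye).
#' @slot r2 squared correlation between predicted and reference values.
#' @slot n number of evaluated molecules.
#' @slot context one of "oob", "test", "cv", "y_random", "train".
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(mae = "numeric", rmse = "numeric", r2 = "numeric",
                 n = "integer", context = "character"))

setValidity("EvalReport", function(object) {
  msgs <- character(0)
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (object@mae > object@rmse + 1e-12)
    msgs <- c(msgs, "MAE cannot exceed RMSE")
  if (length(msgs)) msgs else TRUE
})

#' ModelBundle: a trained random forest plus its feature manifest
#'
#' Prediction is refused unless the incoming feature matrix carries
#' exactly the manifest's columns in order; no imputation is performed.
#'
#' @slot forest the trained \code{randomForest} regressor.
#' @slot featureManifest ordered feature column labels.
#' @slot hyperparams list with nTrees, mtry, seed, mtryGrid, oobRmseGrid.
#' @slot oobReport out-of-bag \linkS4class{EvalReport}.
#'
#' @exportClass ModelBundle
setClass("ModelBundle",
  representation(forest = "ANY", featureManifest = "character",
                 hyperparams = "list", oobReport = "EvalReport"))
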