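#' @rdname Molecule3D-accessors
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomMasses", function(x) standardGeneric("atomMasses"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("bondBlock", function(x) standardGeneric("bondBlock"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("charges", function(x, scheme = NULL) standardGeneric("charges"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("chargeSchemes", function(x) standardGeneric("chargeSchemes"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("formalCharge", function(x) standardGeneric("formalCharge"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("dmLabel", function(x) standardGeneric("dmLabel"))
#' @rdname Molecule3D-accessors
#' @export
setGeneric("dmLabel<-", function(x, value) standardGeneric("dmLabel<-"))

#' Accessors for Molecule3D
#'
#' @param x a \linkS4class{Molecule3D}.
#' @param scheme charge scheme name; \code{NULL} returns the full named
#'   list of attached schemes.
#' @param value replacement dipole label (Debye, non-negative or NA).
#' @return \code{molId}: the identifier; \code{nAtoms}: atom count;
#'   \code{atomElements}/\code{atomMasses}: per-atom vectors;
#'   \code{atomCoords}: n x 3 coordinate matrix; \code{bondBlock}: m x 3
#'   bond matrix; \code{charges}: per-atom charge vector (or list);
#'   \code{chargeSchemes}: names of attached schemes; \code{formalCharge}:
#'   net charge; \code{dmLabel}: reference dipole magnitude.
#' @name Molecule3D-accessors
NULL

#' @rdname Molecule3D-accessors
setMethod("molId", "Molecule3D", function(x) x@id)
#' @rdname Molecule3D-accessors
setMethod("nAtoms", "Molecule3D", function(x) length(x@elements))
#' @rdname Molecule3D-accessors
setMethod("atomElements", "Molecule3D", function(x) x@elements)
#' @rdname Molecule3D-accessors
setMethod("atomMasses", "Molecule3D", function(x) x@masses)
#' @rdname Molecule3D-accessors
setMethod("atomCoords", "Molecule3D", function(x) x@coords)
#' @rdname Molecule3D-accessors
setMethod("bondBlock", "Molecule3D", function(x) x@bonds)
#' @rdname Molecule3D-accessors
setMethod("chargeSchemes", "Molecule3D", function(x) names(x@charges))
#' @rdname Molecule3D-accessors
setMethod("formalCharge", "Molecule3D", function(x) x@formalCharge)
#' @rdname Molecule3D-accessors
setMethod("dmLabel", "Molecule3D", function(x) x@dmLabel)
#' @rdname Molecule3D-accessors
setMethod("dmLabel<-", "Molecule3D", function(x, value) {
  x@dmLabel <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname Molecule3D-accessors
setMethod("charges", "Molecule3D", function(x, scheme = NULL) {
  if (is.null(scheme)) return(x@charges)
  if (!scheme %in% names(x@charges))
    stop("charge scheme '", scheme, "' not attached to molecule '",
         x@id, "' (available: ",
         if (length(x@charges)) paste(names(x@charges), collapse = ", ")
         else "none", ")")
  x@charges[[scheme]]
})

setMethod("show", "Molecule3D", function(object) {
  cat("Molecule3D '", object@id, "': ", nAtoms(object), " atoms (",
      paste(names(sort(table(object@elements), decreasing = TRUE)),
            sort(table(object@elements), decreasing = TRUE),
            sep = "", collapse = " "),
      "), ", nrow(object@bonds), " bonds\n", sep = "")
  cat("  charge schemes: ",
      if (length(object@charges)) paste(names(object@charges), collapse = ", ")
      else "none", "\n", sep = "")
  if (!is.na(object@dmLabel))
    cat("  reference DM: ", format(object@dmLabel), " D\n", sep = "")
  if (length(object@flags))
    cat("  flags: ", paste(object@flags, collapse = ", "), "\n", sep = "")
})

setMethod("show", "DipoleResult", function(object) {
  cat("DipoleResult [scheme ", object@scheme, "]: |mu| = ",
      format(object@magnitudeDebye, digits = 6), " D; vector (e*A) = (",
      paste(format(object@vector, digits = 6), collapse = ", "), ")\n",
      sep = "")
})

#' @rdname descriptor-accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname descriptor-accessors
#' @export
setGeneric("descriptorLabels", function(x) standardGeneric("descriptorLabels"))

#' Accessors for DescriptorBlock
#'
#' @param x a \linkS4class{DescriptorBlock}.
#' @return \code{descriptorValues}: named numeric vector of descriptor
#'   values; \code{descriptorLabels}: the ordered column labels.
#' @name descriptor-accessors
NULL

#' @rdname descriptor-accessors
setMethod("descriptorValues", "DescriptorBlock", function(x) {
  stats::setNames(x@values, x@labels)
})
#' @rdname descriptor-accessors
setMethod("descriptorLabels", "DescriptorBlock", function(x) x@labels)

setMethod("length", "DescriptorBlock", function(x) length(x@values))

setMethod("show", "DescriptorBlock", function(object) {
  cat("DescriptorBlock [", object@family,
      if (nzchar(object@scheme)) paste0(", scheme ", object@scheme) else "",
      "]: ", length(object@values), " columns\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s, n=%d]: MAE %.4f D, RMSE %.4f D, R2 %.4f\n",
              object@context, object@n, object@mae, object@rmse, object@r2))
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle: random forest,", object@hyperparams$nTrees, "trees, mtry",
      object@hyperparams$mtry, "on", length(object@featureManifest),
      "features\n")
  show(object@oobReport)
})
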