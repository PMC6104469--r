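# Fixed-layout feature assembly.  Three recipes are defined:
#   C        : RDF (scheme N, 384) + PchmDM (scheme N, 360) + DM_N + DM_P
#              -> 746 columns
#   F        : recipe C blocks + MACCS (166)                -> 912 columns
#   MACCS_DM : MACCS (166) + DM_N + DM_P                    -> 168 columns
# DM_N / DM_P are the point-charge dipole magnitudes (Debye) under the
# "N" (NBO-style) and "P" (PEOE) charge schemes.  The two DM scalars are
# always the last two columns.

.RECIPES <- c("C", "F", "MACCS_DM")

.recipeSchemes <- function(recipe) {
  switch(recipe, C = c("N", "P"), F = c("N", "P"), MACCS_DM = c("N", "P"))
}

#' Assemble a fixed-layout feature vector
#'
#' Builds the named descriptor vector for one of the modeling recipes.
#' Column order is fixed and documented: descriptor blocks in recipe
#' order, then the two dipole scalars \code{DM_N} and \code{DM_P}
#' (Debye).  Missing charge schemes raise an error naming them.
#'
#' @param mol a \linkS4class{Molecule3D} with schemes \code{"N"} and
#'   \code{"P"} attached.
#' @param recipe one of \code{"C"} (RDF + PchmDM + DMs, 746 columns),
#'   \code{"F"} (recipe C + MACCS, 912), \code{"MACCS_DM"} (MACCS + DMs,
#'   168).
#' @param rdfCfg,pchmCfg descriptor configurations.
#' @return A \linkS4class{DescriptorBlock}.
#' @export
assembleFeatures <- function(mol, recipe = c("C", "F", "MACCS_DM"),
                             rdfCfg = rdfConfig(), pchmCfg = pchmConfig()) {
  recipe <- match.arg(recipe)
  miss <- setdiff(.recipeSchemes(recipe), chargeSchemes(mol))
  if (length(miss))
    stop("recipe ", recipe, " requires charge scheme(s) ",
         paste(miss, collapse = ", "), " missing on molecule '",
         molId(mol), "'")
  vals <- featureMatrix(list(mol), recipe, rdfCfg = rdfCfg,
                        pchmCfg = pchmCfg)
  new("DescriptorBlock", labels = colnames(vals),
      values = as.numeric(vals[1, ]), family = paste0("recipe_", recipe),
      scheme = "", config = list(rdf = rdfCfg[c("nPoints", "rMax", "B")],
                                 pchm = pchmCfg))
}

#' Feature matrix for a list of molecules
#'
#' Row-binds \code{\link{assembleFeatures}} layouts efficiently
#' (MACCS fingerprints are computed in one batch).
#'
#' @param mols list of \linkS4class{Molecule3D}.
#' @inheritParams assembleFeatures
#' @return Numeric matrix, molecules x features, with molecule ids as
#'   row names.
#' @export
featureMatrix <- function(mols, recipe = c("C", "F", "MACCS_DM"),
                          rdfCfg = rdfConfig(), pchmCfg = pchmConfig()) {
  recipe <- match.arg(recipe)
  if (is(mols, "Molecule3D")) mols <- list(mols)
  for (m in mols) {
    miss <- setdiff(.recipeSchemes(recipe), chargeSchemes(m))
    if (length(miss))
      stop("recipe ", recipe, " requires charge scheme(s) ",
           paste(miss, collapse = ", "), " missing on molecule '",
           molId(m), "'")
  }
  dmN <- vapply(mols, function(m) dipoleDebye(pointChargeDipole(m, "N")),
                0)
  dmP <- vapply(mols, function(m) dipoleDebye(pointChargeDipole(m, "P")),
                0)
  dmCols <- cbind(DM_N = dmN, DM_P = dmP)
  blocks <- list()
  if (recipe %in% c("C", "F")) {
    rdf <- t(vapply(mols, function(m)
      descriptorValues(rdfFull(m, "N", rdfCfg)),
      numeric(3L * rdfCfg$nPoints)))
    pchm <- t(vapply(mols, function(m)
      descriptorValues(pchmBlock(m, "N", pchmCfg)),
      numeric(6L * pchmCfg$nBins)))
    blocks <- c(blocks, list(rdf, pchm))
  }
  if (recipe %in% c("F", "MACCS_DM"))
    blocks <- c(blocks, list(maccsMatrix(mols)))
  out <- do.call(cbind, c(blocks, list(dmCols)))
  rownames(out) <- vapply(mols, molId, "")
  out
}

#' Write a feature matrix as CSV
#'
#' First column \code{mol_id}, then the fixed-order feature columns.
#'
#' @param X feature matrix from \code{\link{featureMatrix}}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeFeatureCSV <- function(X, path) {
  df <- data.frame(mol_id = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
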