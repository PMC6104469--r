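#' @importClassesFrom ChemmineR SDFstr SDFset
NULL

# SDF / XYZ input-output and charge-table ingestion.
#
# SDF reading delegates the V2000 block parsing to ChemmineR; files are
# split at "$$$$" first so that one malformed block never takes down the
# whole file (skipped blocks are counted and reported in one warning).

.parseMCHG <- function(blockLines) {
  chg <- integer(0)
  for (ln in grep("^M  CHG", blockLines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- toks[1]
    for (i in seq_len(k)) chg[toks[2 * i]] <- toks[2 * i + 1]
  }
  chg
}

# Explicit-hydrogen heuristic: in a neutral organic molecule every carbon
# has valence 4, so a carbon whose explicit bond orders sum to less than 4
# signals implicit hydrogens.  Only applied when a bond block is present.
.checkExplicitH <- function(elements, bonds) {
  if (nrow(bonds) == 0) return(invisible(TRUE))
  valence <- numeric(length(elements))
  ord <- ifelse(bonds[, 3] == 4L, 1.5, bonds[, 3])  # aromatic as 1.5
  for (b in seq_len(nrow(bonds))) {
    valence[bonds[b, 1]] <- valence[bonds[b, 1]] + ord[b]
    valence[bonds[b, 2]] <- valence[bonds[b, 2]] + ord[b]
  }
  under <- which(elements == "C" & valence < 4 - 1e-9)
  if (length(under))
    stop("carbon atom(s) ", paste(under, collapse = ", "),
         " have explicit valence < 4: hydrogens must be explicit")
  invisible(TRUE)
}

.parseSDFBlock <- function(blockLines, dmField, chargePrefix) {
  sdfset <- suppressWarnings(
    methods::as(methods::new("SDFstr", a = list(blockLines)), "SDFset"))
  if (length(sdfset) != 1L) stop("invalid SDF block")
  # bond count from the counts line; ChemmineR's bond block can pick up
  # trailing "M  END" rows for zero-bond molecules (which also fail its
  # validSDF check, so that check is applied only when bonds exist)
  counts <- blockLines[4]
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nb)) nb <- 0L
  if (nb > 0L && !ChemmineR::validSDF(sdfset))
    stop("invalid SDF block")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (!nrow(coords) || any(!is.finite(coords)))
    stop("invalid or missing coordinates in SDF block")
  bonds <- matrix(integer(0), 0, 3)
  if (nb > 0) {
    bb <- ChemmineR::bondblock(sdf)
    bonds <- matrix(as.integer(bb[seq_len(nb), 1:3]), ncol = 3)
  }
  .checkExplicitH(elements, bonds)
  atomChg <- .parseMCHG(blockLines)
  fc <- if (length(atomChg)) sum(atomChg, na.rm = TRUE) else 0L
  db <- tryCatch(ChemmineR::datablock(sdf), error = function(e) character(0))
  dm <- NA_real_
  if (dmField %in% names(db)) {
    dm <- suppressWarnings(as.numeric(db[[dmField]]))
    if (is.na(dm)) stop("non-numeric value in property '", dmField, "'")
  }
  chargeList <- list()
  for (nm in grep(paste0("^", chargePrefix), names(db), value = TRUE)) {
    scheme <- sub(paste0("^", chargePrefix), "", nm)
    vals <- suppressWarnings(
      as.numeric(strsplit(trimws(db[[nm]]), "\\s+")[[1]]))
    if (length(vals) != length(elements) || any(is.na(vals)))
      stop("charge property '", nm, "' does not provide one finite value ",
           "per atom")
    chargeList[[scheme]] <- vals
  }
  id <- trimws(blockLines[1])
  if (!nzchar(id)) id <- "unnamed"
  flags <- character(0)
  if (nrow(coords) > 1 && all(abs(coords[, 3]) < 1e-12))
    flags <- "suspect2D"
  Molecule3D(id, elements, coords, bonds = bonds, formalCharge = fc,
             charges = chargeList, dmLabel = dm, flags = flags)
}

#' Read molecules from an SDF (V2000) file
#'
#' Reads every molfile block into a \linkS4class{Molecule3D}.  A dipole
#' label (Debye) is taken from the property field \code{dmField} when
#' present, and per-atom charge sets from whitespace-separated lists in
#' property fields named \code{<chargePrefix><scheme>} (e.g.
#' \code{ATOM_CHARGES_N}).  Malformed blocks are skipped with a single
#' summary warning rather than aborting the read; structures whose z
#' coordinates are all zero are flagged \code{"suspect2D"} but kept.
#' Hydrogens must be explicit: a molecule with a bond block in which a
#' carbon has explicit valence below four is rejected (and counted as
#' skipped).
#'
#' @param path SDF file path.
#' @param dmField property field holding the reference dipole magnitude
#'   (default \code{"DFT_DM"}).
#' @param chargePrefix prefix of per-scheme charge property fields
#'   (default \code{"ATOM_CHARGES_"}).
#' @return List of \linkS4class{Molecule3D} objects.
#' @seealso \code{\link{writeSDF}}, \code{\link{attachCharges}}
#' @export
readSDF <- function(path, dmField = "DFT_DM",
                    chargePrefix = "ATOM_CHARGES_") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("no '$$$$' record terminator found in ", path)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- list()
  skipped <- 0L
  for (b in seq_along(ends)) {
    if (starts[b] > ends[b] - 1L) next
    blk <- lines[starts[b]:ends[b]]
    if (all(!nzchar(trimws(blk[blk != "$$$$"])))) next
    m <- tryCatch(.parseSDFBlock(blk, dmField, chargePrefix),
                  error = function(e) e)
    if (inherits(m, "error")) {
      skipped <- skipped + 1L
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (skipped > 0)
    warning("skipped ", skipped, " malformed SDF block(s) in ", path)
  mols
}

.chargeCode <- function(fc) {
  # V2000 atom-block charge codes: 0 none, 1 +3, 2 +2, 3 +1, 5 -1, 6 -2, 7 -3
  code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
            `-1` = 5L, `-2` = 6L, `-3` = 7L)
  out <- code[as.character(fc)]
  ifelse(is.na(out), 0L, out)
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates are written with four decimals (the V2000 field width).
#' Attached charge schemes are stored as whitespace-separated lists under
#' \code{<chargePrefix><scheme>} properties and the dipole label, when
#' present, under \code{dmField}, so that \code{\link{readSDF}}
#' round-trips both.
#'
#' @param mols a \linkS4class{Molecule3D} or list thereof.
#' @param path output file path.
#' @inheritParams readSDF
#' @return Invisibly, the path.
#' @export
writeSDF <- function(mols, path, dmField = "DFT_DM",
                     chargePrefix = "ATOM_CHARGES_") {
  if (is(mols, "Molecule3D")) mols <- list(mols)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in mols) {
    n <- nAtoms(m)
    nb <- nrow(m@bonds)
    out <- c(molId(m), "  dipolegrid", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (i in seq_len(n))
      out <- c(out, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        m@coords[i, 1], m@coords[i, 2], m@coords[i, 3], m@elements[i]))
    for (b in seq_len(nb))
      out <- c(out, sprintf("%3d%3d%3d  0", m@bonds[b, 1], m@bonds[b, 2],
                            m@bonds[b, 3]))
    if (m@formalCharge != 0L)
      out <- c(out, sprintf("M  CHG  1%4d%4d", 1L, m@formalCharge))
    out <- c(out, "M  END")
    if (!is.na(dmLabel(m)))
      out <- c(out, paste0("> <", dmField, ">"),
               format(dmLabel(m), digits = 10), "")
    for (s in chargeSchemes(m))
      out <- c(out, paste0("> <", chargePrefix, s, ">"),
               paste(sprintf("%.6f", m@charges[[s]]), collapse = " "), "")
    out <- c(out, "$$$$")
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' \code{element x y z} row per atom.  No charges or bonds are attached.
#'
#' @param path XYZ file path.
#' @param id molecule identifier; defaults to the comment line (or the
#'   file name when the comment is empty).
#' @return A \linkS4class{Molecule3D}.
#' @export
readXYZ <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("line 1 of ", path, " is not a valid atom count")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n)
    stop("atom count on line 1 is ", n, " but ", length(body),
         " atom rows found (", path, ")")
  toks <- strsplit(trimws(body), "\\s+")
  elements <- vapply(toks, `[[`, "", 1L)
  bad <- setdiff(unique(elements), .SUPPORTED_ELEMENTS)
  if (length(bad))
    stop("unsupported element(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(coords))) stop("non-numeric coordinates in ", path)
  if (is.null(id)) {
    id <- trimws(lines[2])
    if (!nzchar(id)) id <- basename(path)
  }
  Molecule3D(id, elements, coords)
}

#' Attach a per-atom charge set from a charge table
#'
#' The table is either a numeric vector (one charge per atom, in atom
#' order) or a data frame with columns \code{mol_id}, \code{atom_index}
#' (1-based, in SDF atom-block order) and \code{charge}.  Every atom must
#' be covered: partial charge sets are refused.  Charges of magnitude
#' above 2 e trigger a warning (likely unit or indexing mistakes).
#' Re-attaching the same scheme replaces it, so the operation is
#' idempotent for a fixed table.
#'
#' @param mol a \linkS4class{Molecule3D}.
#' @param table numeric vector or data frame as described.
#' @param scheme charge scheme name to attach under (e.g. \code{"N"}).
#' @return The annotated molecule.
#' @export
attachCharges <- function(mol, table, scheme) {
  stopifnot(is(mol, "Molecule3D"), is.character(scheme), length(scheme) == 1)
  n <- nAtoms(mol)
  if (is.numeric(table)) {
    if (length(table) != n)
      stop("charge vector has ", length(table), " values but molecule '",
           molId(mol), "' has ", n, " atoms")
    vals <- as.numeric(table)
  } else {
    table <- as.data.frame(table)
    need <- c("mol_id", "atom_index", "charge")
    if (!all(need %in% names(table)))
      stop("charge table must have columns ", paste(need, collapse = ", "))
    rows <- table[table$mol_id == molId(mol), , drop = FALSE]
    if (!nrow(rows))
      stop("no charge rows for molecule '", molId(mol), "'")
    if (anyDuplicated(rows$atom_index))
      stop("duplicated atom_index rows for molecule '", molId(mol), "'")
    missing <- setdiff(seq_len(n), rows$atom_index)
    if (length(missing))
      stop("charge table misses atom(s) ", paste(missing, collapse = ", "),
           " of molecule '", molId(mol),
           "' (partial charge sets are not allowed)")
    extra <- setdiff(rows$atom_index, seq_len(n))
    if (length(extra))
      stop("charge table references nonexistent atom(s) ",
           paste(extra, collapse = ", "))
    vals <- rows$charge[order(rows$atom_index)]
  }
  if (any(abs(vals) > 2))
    warning("charge magnitude above 2 e for molecule '", molId(mol),
            "', scheme '", scheme, "' - check units/indexing")
  mol@charges[[scheme]] <- as.numeric(vals)
  validObject(mol)
  mol
}

#' Read a charge table CSV
#'
#' Expects columns \code{mol_id}, \code{atom_index}, \code{charge}.
#'
#' @param path CSV file path.
#' @return A data frame suitable for \code{\link{attachCharges}}.
#' @export
readChargeCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mol_id", "atom_index", "charge")
  if (!all(need %in% names(tab)))
    stop("charge CSV must have columns ", paste(need, collapse = ", "))
  tab
}
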