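BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.checkFile <- function(path) {
    if (!file.exists(path)) stop("file not found: '", path, "'")
    invisible(path)
}


# Element symbol from a PDB atom name: strip leading digits, take the first
# letter. Covers standard protein atom names (CA, HN, 1HB2, OXT, ...).
.elementFromName <- function(atom) {
    stripped <- sub("^[0-9]+", "", atom)
    toupper(substr(stripped, 1L, 1L))
}

# Pre-scan a PDB text for malformed ATOM records and roster mismatches
# across models. Returns per-model keys invisibly; stops with informative
# errors. bio3d does the actual coordinate parsing afterwards.
.validatePdbText <- function(lines, path) {
    rec <- substr(lines, 1, 6)
    isAtom <- rec %in% c("ATOM  ", "HETATM")
    isModel <- rec == "MODEL "
    isEnd <- rec == "ENDMDL"
    if (!any(isAtom))
        stop("no ATOM records found in '", path, "'")
    model <- cumsum(isModel)
    if (!any(isModel)) model <- rep(1L, length(lines))
    atomLines <- which(isAtom)
    for (i in atomLines) {
        xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                             substr(lines[i], 39, 46),
                                             substr(lines[i], 47, 54))))
        if (any(is.na(xyz)) || nchar(lines[i]) < 54)
            stop("malformed ATOM record at line ", i, " of '", path, "'")
    }
    keyOf <- function(i) {
        ch <- trimws(substr(lines[i], 22, 22))
        ch[ch == ""] <- "A"
        paste(ch, as.integer(substr(lines[i], 23, 26)),
              trimws(substr(lines[i], 13, 16)))
    }
    split(keyOf(atomLines), model[atomLines])
}

.checkRosters <- function(keysByModel, path) {
    if (length(keysByModel) < 2L) return(invisible(TRUE))
    ref <- keysByModel[[1]]
    for (m in seq_along(keysByModel)[-1]) {
        cur <- keysByModel[[m]]
        miss <- setdiff(ref, cur)
        extra <- setdiff(cur, ref)
        if (length(miss) || length(extra))
            stop("inconsistent atom roster in '", path, "': model ", m,
                 if (length(miss)) paste0(" lacks [",
                     paste(utils::head(miss, 5), collapse = "; "), "]") else "",
                 if (length(extra)) paste0(" adds [",
                     paste(utils::head(extra, 5), collapse = "; "), "]") else "")
        if (!identical(ref, cur))
            stop("inconsistent atom order in '", path, "': model ", m,
                 " lists the shared roster in a different order (first at [",
                 cur[which(ref != cur)[1]], "])")
    }
    invisible(TRUE)
}

#' Read a (multi-model) PDB file into a StructureEnsemble
#'
#' Models are delimited by MODEL/ENDMDL records; a file without them is a
#' single implicit model. Residue numbering is taken verbatim from the
#' file. When alternate locations are present, the highest-occupancy
#' conformer is kept (ties broken by altloc letter). A missing chain
#' identifier becomes chain "A". Hydrogens are retained.
#'
#' @param path path to a PDB file.
#' @param format input format; only \code{"pdb"} is supported.
#' @return A [StructureEnsemble-class].
#' @examples
#' ens <- makeEnsemble(nResidues = 10, nModels = 3, sigma = 0.2, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeEnsemble(ens, f)
#' readEnsemble(f)
#' @export
readEnsemble <- function(path, format = c("pdb")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: '", path, "'")
    lines <- readLines(path, warn = FALSE)
    keys <- .validatePdbText(lines, path)
    .checkRosters(keys, path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    a <- pdb$atom
    xyz <- pdb$xyz                       # n_models x (3*natoms)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    keep <- rep(TRUE, nrow(a))
    alt <- a$alt
    if (any(!is.na(alt) & alt != "")) {
        grp <- paste(a$chain, a$resno, a$elety)
        occ <- ifelse(is.na(a$o), 1, a$o)
        for (g in unique(grp[duplicated(grp)])) {
            idx <- which(grp == g)
            best <- idx[order(-occ[idx], ifelse(is.na(alt[idx]), "", alt[idx]))][1]
            keep[setdiff(idx, best)] <- FALSE
        }
    }
    a <- a[keep, , drop = FALSE]
    nat <- nrow(a)
    colIdx <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                              3 * which(keep)))
    xyz <- xyz[, colIdx, drop = FALSE]
    nm <- nrow(xyz)
    coords <- array(NA_real_, c(nat, 3, nm))
    for (m in seq_len(nm))
        coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    chain <- a$chain
    chain[is.na(chain) | chain == ""] <- "A"
    elem <- a$elesy
    bad <- is.na(elem) | elem == ""
    elem[bad] <- .elementFromName(a$elety[bad])
    atoms <- data.frame(chain = chain, resno = a$resno, resname = a$resid,
                        atom = a$elety, element = toupper(trimws(elem)),
                        stringsAsFactors = FALSE)
    new("StructureEnsemble", atoms = atoms, coords = coords)
}

#' Write a StructureEnsemble to a PDB file
#'
#' Multi-model ensembles are written with MODEL/ENDMDL records; coordinates
#' use the standard 3-decimal fixed-width fields.
#'
#' @param x a [StructureEnsemble-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEnsemble <- function(x, path) {
    a <- x@atoms
    multi <- nModels(x) > 1L
    con <- file(path, "w")
    on.exit(close(con))
    for (m in seq_len(nModels(x))) {
        if (multi) writeLines(sprintf("MODEL     %4d", m), con)
        xyz <- x@coords[, , m]
        nm4 <- ifelse(nchar(a$atom) >= 4, a$atom,
                      sprintf(" %-3s", a$atom))
        writeLines(sprintf(
            "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(a)), nm4, a$resname, a$chain, a$resno,
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element), con)
        if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Export the roster sequence as FASTA
#'
#' @param x a [StructureEnsemble-class].
#' @param path output FASTA path.
#' @param id sequence identifier.
#' @return Invisibly, \code{path}.
#' @export
writeRosterFASTA <- function(x, path, id = "roster") {
    seq3 <- rosterSequence(x)
    seq1 <- paste(bio3d::aa321(seq3), collapse = "")
    aa <- Biostrings::AAStringSet(stats::setNames(seq1, id))
    Biostrings::writeXStringSet(aa, path)
    invisible(path)
}

#' Atom/residue selection
#'
#' @param resno residue numbers to select (NULL = all residues).
#' @param atoms atom names, or the symbolic classes \code{"backbone"}
#'   (exactly N, CA, C, O) or \code{"heavy"} (all non-hydrogen atoms).
#' @param chain chain identifiers (NULL = all chains).
#' @return A selection object usable by [extractCoordinates()] and
#'   [ensemblePrecision()].
#' @export
atomSelection <- function(resno = NULL, atoms = "backbone", chain = NULL) {
    structure(list(resno = resno, atoms = atoms, chain = chain),
              class = "atomSelection")
}

# Resolve a selection to roster row indices in canonical order:
# ascending chain, residue number, then N, CA, C, O, then remaining
# atom names alphabetically.
.canonicalAtomRank <- function(atom) {
    r <- match(atom, BACKBONE_ATOMS)
    ifelse(is.na(r), length(BACKBONE_ATOMS) + as.integer(factor(atom)), r)
}

.resolveSelection <- function(x, sel) {
    a <- x@atoms
    keep <- rep(TRUE, nrow(a))
    if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
    if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
    atoms <- sel$atoms
    if (identical(atoms, "backbone")) {
        keep <- keep & a$atom %in% BACKBONE_ATOMS
    } else if (identical(atoms, "heavy")) {
        keep <- keep & a$element != "H"
    } else {
        unknown <- setdiff(atoms, unique(a$atom))
        if (length(unknown))
            stop("unknown atom name(s) in selection: ",
                 paste(unknown, collapse = ", "))
        keep <- keep & a$atom %in% atoms
    }
    idx <- which(keep)
    if (!length(idx)) stop("selection resolves to no atoms")
    idx[order(a$chain[idx], a$resno[idx], .canonicalAtomRank(a$atom[idx]))]
}

#' Extract an ordered coordinate matrix from an ensemble
#'
#' Atom order is deterministic: ascending chain, residue number, then a
#' fixed canonical atom-name order (N, CA, C, O first, remaining names
#' alphabetically), so the result does not depend on the atom order of the
#' source file.
#'
#' @param x a [StructureEnsemble-class].
#' @param selection an [atomSelection()].
#' @param model integer model index, or \code{"mean"} for the unweighted
#'   per-atom average over models.
#' @return numeric matrix, n_atoms x 3, Angstroms; row names
#'   \code{chain:resno:atom}.
#' @export
extractCoordinates <- function(x, selection = atomSelection(),
                               model = "mean") {
    idx <- .resolveSelection(x, selection)
    if (length(idx) < 3L)
        stop("selection must resolve to at least 3 atoms")
    if (identical(model, "mean")) {
        m <- apply(x@coords[idx, , , drop = FALSE], c(1, 2), mean)
    } else {
        model <- as.integer(model)
        if (model < 1L || model > nModels(x))
            stop("model index out of range")
        m <- x@coords[idx, , model]
    }
    a <- x@atoms[idx, ]
    dimnames(m) <- list(paste(a$chain, a$resno, a$atom, sep = ":"),
                        c("x", "y", "z"))
    m
}
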