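SEPARATION_CLASSES <- c("intraresidue", "sequential", "medium", "long")

#' Classify an NOE contact by sequence separation
#'
#' Standard restraint-table classes: |i-j| = 0 intraresidue, = 1
#' sequential, 2-4 medium-range, >= 5 long-range. The function is
#' vectorised and symmetric in its arguments.
#'
#' @param residueI,residueJ residue numbers (>= 1).
#' @return factor with levels intraresidue, sequential, medium, long.
#' @examples
#' classifySeparation(c(5, 5, 2, 3), c(5, 6, 5, 8))
#' @export
classifySeparation <- function(residueI, residueJ) {
    if (any(residueI < 1) || any(residueJ < 1))
        stop("residue numbers must be >= 1")
    d <- abs(residueI - residueJ)
    cls <- ifelse(d == 0, "intraresidue",
           ifelse(d == 1, "sequential",
           ifelse(d < 5, "medium", "long")))
    factor(cls, levels = SEPARATION_CLASSES)
}

#' Default NOE intensity-to-distance binning scheme
#'
#' Four intensity classes map to interproton distance bounds with a
#' uniform 1.8 A lower limit: strong 1.8-2.7 A (upper 2.9 A when the NOE
#' involves an HN proton), medium 1.8-3.3 A (3.5 A for HN), weak 1.8-5.0 A
#' and very weak 1.8-6.0 A. Pseudo-atom upper-bound corrections default to
#' +1.0 A for methyl groups, +0.7 A for non-stereospecifically assigned
#' methylene protons and +2.0 A for aromatic ring protons.
#'
#' @return list with elements \code{lower}, \code{upper}, \code{upperHN},
#'   \code{pseudo}.
#' @export
defaultBinningScheme <- function() {
    list(lower = 1.8,
         upper = c(strong = 2.7, medium = 3.3, weak = 5.0, very_weak = 6.0),
         upperHN = c(strong = 2.9, medium = 3.5, weak = 5.0, very_weak = 6.0),
         pseudo = c(methyl = 1.0, methylene = 0.7, aromatic = 2.0))
}

#' Distance bounds for an NOE intensity class
#'
#' @param intensityClass one of strong, medium, weak, very_weak.
#' @param involvesHN does the contact involve an HN proton? (uses the
#'   HN-adjusted upper bound where the scheme defines one)
#' @param pseudoCorrection upper-bound increment in Angstroms for
#'   pseudo-atom representations (>= 0), or the name of a correction group
#'   in the scheme (\code{"methyl"}, \code{"methylene"}, \code{"aromatic"}).
#' @param scheme a binning scheme, see [defaultBinningScheme()].
#' @return numeric c(lower, upper) in Angstroms.
#' @examples
#' assignBounds("strong", involvesHN = TRUE)          # 1.8 2.9
#' assignBounds("very_weak", pseudoCorrection = "methyl")  # 1.8 7.0
#' @export
assignBounds <- function(intensityClass, involvesHN = FALSE,
                         pseudoCorrection = 0,
                         scheme = defaultBinningScheme()) {
    if (!intensityClass %in% names(scheme$upper))
        stop("unknown intensity class: ", intensityClass)
    if (is.character(pseudoCorrection)) {
        if (!pseudoCorrection %in% names(scheme$pseudo))
            stop("unknown pseudo-atom correction group: ", pseudoCorrection)
        pseudoCorrection <- scheme$pseudo[[pseudoCorrection]]
    }
    if (pseudoCorrection < 0) stop("pseudo-atom correction must be >= 0")
    up <- if (involvesHN) scheme$upperHN[[intensityClass]] else
        scheme$upper[[intensityClass]]
    c(lower = scheme$lower, upper = up + pseudoCorrection)
}

#' Build a restraint table from atom-pair contacts
#'
#' @param residueI,atomI,residueJ,atomJ vectors describing each contact.
#' @param intensityClass per-restraint intensity class.
#' @param involvesHN logical; defaults to whether either atom name starts
#'   with H and is an amide proton name (\code{HN} or \code{H}).
#' @param pseudoCorrection per-restraint upper-bound increment, Angstroms.
#' @param scheme binning scheme.
#' @return data.frame with the input columns plus \code{separation},
#'   \code{lower} and \code{upper}.
#' @export
restraintTable <- function(residueI, atomI, residueJ, atomJ,
                           intensityClass,
                           involvesHN = (atomI %in% c("H", "HN")) |
                                        (atomJ %in% c("H", "HN")),
                           pseudoCorrection = 0,
                           scheme = defaultBinningScheme()) {
    n <- length(residueI)
    pseudoCorrection <- rep_len(pseudoCorrection, n)
    involvesHN <- rep_len(involvesHN, n)
    bounds <- t(mapply(assignBounds, intensityClass, involvesHN,
                       pseudoCorrection, MoreArgs = list(scheme = scheme)))
    data.frame(residueI = residueI, atomI = atomI,
               residueJ = residueJ, atomJ = atomJ,
               intensityClass = intensityClass, involvesHN = involvesHN,
               separation = classifySeparation(residueI, residueJ),
               lower = bounds[, 1], upper = bounds[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise a restraint list
#'
#' Counts NOE restraints by sequence-separation class (the four classes
#' partition all contacts, so they sum to the total), dihedral restraints
#' by angle type, and hydrogen-bond restraints as two distance restraints
#' per bond.
#'
#' @param restraints data.frame with columns \code{residueI} and
#'   \code{residueJ} (e.g. from [restraintTable()]); may be empty.
#' @param dihedrals optional data.frame with a column \code{angle}
#'   (phi, psi, chi1, chi2).
#' @param hbonds optional integer: number of hydrogen bonds (each
#'   contributes two distance restraints).
#' @return list with \code{noe} (named class counts), \code{totalNOE},
#'   \code{dihedral} (named counts), \code{hbondRestraints}.
#' @export
summarizeRestraints <- function(restraints = NULL, dihedrals = NULL,
                                hbonds = 0L) {
    counts <- stats::setNames(integer(4), SEPARATION_CLASSES)
    if (!is.null(restraints) && nrow(restraints)) {
        cls <- classifySeparation(restraints$residueI, restraints$residueJ)
        tab <- table(cls)
        counts[names(tab)] <- as.integer(tab)
    }
    dih <- stats::setNames(integer(4), c("phi", "psi", "chi1", "chi2"))
    if (!is.null(dihedrals) && nrow(dihedrals)) {
        tab <- table(factor(dihedrals$angle, levels = names(dih)))
        dih[names(tab)] <- as.integer(tab)
    }
    list(noe = counts, totalNOE = sum(counts), dihedral = dih,
         hbondRestraints = 2L * as.integer(hbonds))
}

#' Dihedral restraint bounds from a centre and halfwidth
#'
#' Side-chain rotamer restraints default to centre +/- 30 degrees;
#' backbone phi/psi halfwidths are supplied by the caller (from a
#' chemical-shift-based prediction table).
#'
#' @param center degrees.
#' @param halfwidth degrees; default 30 for chi1/chi2 rotamers.
#' @return numeric c(lower, upper), degrees.
#' @export
dihedralBounds <- function(center, halfwidth = 30) {
    if (halfwidth < 0) stop("halfwidth must be >= 0")
    c(lower = center - halfwidth, upper = center + halfwidth)
}

#' Read / write the native restraint TSV format
#'
#' Columns: residueI, atomI, residueJ, atomJ, intensityClass, involvesHN,
#' pseudoCorrection. Bounds and separation classes are recomputed on read.
#'
#' @param path file path.
#' @param scheme binning scheme applied on read.
#' @return [restraintTable()] data.frame.
#' @export
readRestraintTSV <- function(path, scheme = defaultBinningScheme()) {
    .checkFile(path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("residueI", "atomI", "residueJ", "atomJ", "intensityClass")
    if (!all(need %in% names(d)))
        stop("restraint TSV must have columns: ", paste(need, collapse = ", "))
    if (is.null(d$pseudoCorrection)) d$pseudoCorrection <- 0
    if (is.null(d$involvesHN))
        d$involvesHN <- d$atomI %in% c("H", "HN") | d$atomJ %in% c("H", "HN")
    restraintTable(d$residueI, d$atomI, d$residueJ, d$atomJ,
                   d$intensityClass, d$involvesHN, d$pseudoCorrection,
                   scheme = scheme)
}

#' @rdname readRestraintTSV
#' @param x restraint data.frame to write.
#' @export
writeRestraintTSV <- function(x, path) {
    utils::write.table(
        x[, c("residueI", "atomI", "residueJ", "atomJ", "intensityClass",
              "involvesHN")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
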