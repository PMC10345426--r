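#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation that superpose \code{a} onto
#' \code{b} with minimum (optionally weighted) RMSD, by singular value
#' decomposition of the covariance matrix. Reflections are corrected by
#' flipping the sign of the smallest singular direction, so the returned
#' rotation always has determinant +1.
#'
#' @param a,b numeric n x 3 coordinate matrices (Angstroms), n >= 3.
#' @param weights optional non-negative weights, length n.
#' @return list with components \code{rotation} (3 x 3), \code{translation}
#'   (length 3) and \code{rmsd}; the superposed coordinates are
#'   \code{a \%*\% rotation + translation} (row-wise).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch(a, a)$rmsd  # 0
#' @export
kabsch <- function(a, b, weights = NULL) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
        stop("coordinate matrices must be the same n x 3 shape")
    n <- nrow(a)
    if (n < 3L) stop("at least 3 points are required")
    if (is.null(weights)) weights <- rep(1, n)
    if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
        stop("weights must be non-negative with positive sum")
    w <- weights / sum(weights)
    ca <- colSums(a * w); cb <- colSums(b * w)
    a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
    # rank of the weighted point cloud must be >= 2 (not all collinear)
    cov <- t(a0 * w) %*% b0
    sv <- svd(crossprod(a0 * sqrt(w)))
    if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
        stop("degenerate geometry: points are (near-)collinear")
    s <- svd(cov)
    d <- sign(det(s$u %*% t(s$v)))
    D <- diag(c(1, 1, d))
    rot <- s$u %*% D %*% t(s$v)
    trans <- cb - as.vector(ca %*% rot)
    fitted <- a %*% rot + matrix(trans, n, 3, byrow = TRUE)
    rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
    list(rotation = rot, translation = trans, rmsd = rmsd)
}

# Representative coordinates of an ensemble over a residue correspondence.
# atomClass "backbone": N, CA, C, O per residue. "heavy": atom names are
# intersected per residue pair by the caller.
.representativeCoords <- function(ens, resno, atomClass, representative) {
    sel <- atomSelection(resno = resno, atoms = atomClass)
    model <- if (identical(representative, "mean")) "mean" else
        as.integer(representative)
    extractCoordinates(ens, sel, model = model)
}

#' Cross-structure RMSD over a residue correspondence
#'
#' Superposes the corresponded atoms of two structures by [kabsch()] and
#' reports the resulting RMSD. For \code{atomClass = "backbone"} the atoms
#' N, CA, C and O of every corresponded residue pair are used; for
#' \code{"heavy"}, the non-hydrogen atom names shared by each residue pair.
#'
#' @param ensA,ensB [StructureEnsemble-class] objects.
#' @param corr residue correspondence: data.frame whose first two columns
#'   are residue numbers in \code{ensA} and \code{ensB} (one-to-one).
#' @param atomClass \code{"backbone"} or \code{"heavy"}.
#' @param representative \code{"mean"} (default: the unweighted mean
#'   structure of each ensemble) or an integer model index applied to both.
#' @return RMSD in Angstroms (scalar).
#' @export
regionRMSD <- function(ensA, ensB, corr,
                       atomClass = c("backbone", "heavy"),
                       representative = "mean") {
    atomClass <- match.arg(atomClass)
    corr <- as.data.frame(corr)
    resA <- corr[[1]]; resB <- corr[[2]]
    if (anyDuplicated(resA) || anyDuplicated(resB))
        stop("correspondence must be one-to-one (duplicated residues)")
    aAtoms <- ensA@atoms; bAtoms <- ensB@atoms
    gaps <- character()
    rowsA <- integer(); rowsB <- integer()
    for (k in seq_along(resA)) {
        ia <- which(aAtoms$resno == resA[k])
        ib <- which(bAtoms$resno == resB[k])
        if (!length(ia)) { gaps <- c(gaps, paste0("A:", resA[k])); next }
        if (!length(ib)) { gaps <- c(gaps, paste0("B:", resB[k])); next }
        if (atomClass == "backbone") {
            want <- BACKBONE_ATOMS
            na <- aAtoms$atom[ia]; nb <- bAtoms$atom[ib]
            if (!all(want %in% na)) gaps <- c(gaps, paste0(
                "A:", resA[k], " missing ",
                paste(setdiff(want, na), collapse = ",")))
            if (!all(want %in% nb)) gaps <- c(gaps, paste0(
                "B:", resB[k], " missing ",
                paste(setdiff(want, nb), collapse = ",")))
            common <- want
        } else {
            na <- aAtoms$atom[ia][aAtoms$element[ia] != "H"]
            nb <- bAtoms$atom[ib][bAtoms$element[ib] != "H"]
            common <- intersect(na, nb)
            if (!length(common)) {
                gaps <- c(gaps, paste0("pair ", resA[k], "/", resB[k],
                                       " shares no heavy atoms"))
                next
            }
        }
        ord <- order(.canonicalAtomRank(common))
        common <- common[ord]
        rowsA <- c(rowsA, ia[match(common, aAtoms$atom[ia])])
        rowsB <- c(rowsB, ib[match(common, bAtoms$atom[ib])])
    }
    if (length(gaps))
        stop("correspondence not covered by the structures: ",
             paste(utils::head(gaps, 10), collapse = "; "))
    coordsOf <- function(ens, rows, representative) {
        if (identical(representative, "mean"))
            apply(ens@coords[rows, , , drop = FALSE], c(1, 2), mean)
        else ens@coords[rows, , as.integer(representative)]
    }
    ca <- coordsOf(ensA, rowsA, representative)
    cb <- coordsOf(ensB, rowsB, representative)
    kabsch(ca, cb)$rmsd
}

#' Ensemble coordinate precision
#'
#' Average pairwise RMSD of the ensemble models from their mean structure
#' over a selection. The mean structure is computed by iterative
#' superposition: every model is superposed onto the current mean, the mean
#' is recomputed, and the cycle repeats until the mean moves less than
#' \code{tol} (maximum \code{maxIter} iterations). The reported spread is
#' the sample (n-1) standard deviation of the per-model RMSDs.
#'
#' @param x a [StructureEnsemble-class] with >= 2 models.
#' @param selection an [atomSelection()].
#' @param tol convergence tolerance on the mean coordinates, Angstroms.
#' @param maxIter iteration cap.
#' @return list with \code{mean} (mean RMSD, Angstroms), \code{sd} (sample
#'   sd), \code{perModel} (per-model RMSD vector), \code{selection},
#'   \code{iterations}.
#' @export
ensemblePrecision <- function(x, selection = atomSelection(),
                              tol = 1e-6, maxIter = 100L) {
    if (nModels(x) < 2L)
        stop("coordinate precision is undefined for a single-model ensemble")
    idx <- .resolveSelection(x, selection)
    if (length(idx) < 3L) stop("selection must resolve to at least 3 atoms")
    nm <- nModels(x)
    models <- lapply(seq_len(nm), function(m) x@coords[idx, , m])
    meanC <- Reduce(`+`, models) / nm
    iter <- 0L
    repeat {
        iter <- iter + 1L
        fitted <- lapply(models, function(mc) {
            k <- kabsch(mc, meanC)
            mc %*% k$rotation + matrix(k$translation, nrow(mc), 3, byrow = TRUE)
        })
        newMean <- Reduce(`+`, fitted) / nm
        shift <- max(abs(newMean - meanC))
        meanC <- newMean
        models <- fitted
        if (shift < tol || iter >= maxIter) break
    }
    perModel <- vapply(models, function(mc)
        sqrt(mean(rowSums((mc - meanC)^2))), numeric(1))
    list(mean = mean(perModel), sd = stats::sd(perModel),
         perModel = perModel, selection = selection, iterations = iter)
}
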