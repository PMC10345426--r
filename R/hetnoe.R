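#' Steady-state heteronuclear NOE from peak intensities
#'
#' The NOE is the intensity ratio of the proton-saturated and reference
#' spectra; its uncertainty comes from first-order propagation of the
#' per-spectrum background-noise standard deviations:
#' \deqn{\sigma_{NOE} = |NOE| \sqrt{(\sigma_{sat}/I_{sat})^2 +
#'   (\sigma_{ref}/I_{ref})^2}}
#'
#' @param iSat,iRef peak intensities with and without proton saturation
#'   (vectorised); \code{iRef} must be positive.
#' @param sigmaSat,sigmaRef noise standard deviations; when only
#'   \code{sigmaSat} is given it is used for both spectra.
#' @param residue optional residue numbers carried through to the output.
#' @return data.frame: \code{residue} (if given), \code{noe},
#'   \code{sigma}.
#' @examples
#' computeNOE(0.8, 1.0, 0.02)  # noe 0.8, sigma ~0.0256
#' @export
computeNOE <- function(iSat, iRef, sigmaSat = 0, sigmaRef = sigmaSat,
                       residue = NULL) {
    if (any(iRef <= 0, na.rm = TRUE))
        stop("reference intensity must be positive (undefined ratio)")
    if (any(sigmaSat < 0) || any(sigmaRef < 0))
        stop("noise standard deviations must be >= 0")
    noe <- iSat / iRef
    relSat <- ifelse(iSat == 0, 0, sigmaSat / iSat)
    sigma <- abs(noe) * sqrt(relSat^2 + (sigmaRef / iRef)^2)
    sigma[iSat == 0] <- (sigmaSat / iRef)[iSat == 0]
    out <- data.frame(noe = noe, sigma = sigma)
    if (!is.null(residue)) out <- cbind(residue = residue, out)
    out
}

#' Flag mobile residues by heteronuclear NOE
#'
#' Residues with NOE strictly below the threshold (default 0.5) are
#' flagged as mobile on the fast timescale; records with missing NOE
#' (overlapped or unreliable peaks, prolines) are never flagged.
#'
#' @param records data.frame with columns \code{residue} and \code{noe}.
#' @param threshold dimensionless NOE cutoff; strict inequality.
#' @return integer vector of mobile residue numbers.
#' @export
flagMobile <- function(records, threshold = 0.5) {
    hit <- !is.na(records$noe) & records$noe < threshold
    records$residue[hit]
}

#' Read / write hetNOE intensity tables
#'
#' TSV columns: residue, iSat, iRef and optionally sigmaSat, sigmaRef.
#' Missing-intensity rows (NA) are carried as missing NOE values.
#'
#' @param path file path.
#' @return data.frame with residue, noe, sigma.
#' @export
readHetNOETSV <- function(path) {
    .checkFile(path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("residue", "iSat", "iRef")
    if (!all(need %in% names(d)))
        stop("hetNOE TSV must have columns: ", paste(need, collapse = ", "))
    sSat <- if (is.null(d$sigmaSat)) 0 else d$sigmaSat
    sRef <- if (is.null(d$sigmaRef)) sSat else d$sigmaRef
    ok <- !is.na(d$iSat) & !is.na(d$iRef)
    out <- data.frame(residue = d$residue, noe = NA_real_, sigma = NA_real_)
    if (any(ok)) {
        r <- computeNOE(d$iSat[ok], d$iRef[ok],
                        if (length(sSat) > 1) sSat[ok] else sSat,
                        if (length(sRef) > 1) sRef[ok] else sRef)
        out$noe[ok] <- r$noe
        out$sigma[ok] <- r$sigma
    }
    out
}

#' @rdname readHetNOETSV
#' @param x data.frame with residue, noe, sigma to write.
#' @export
writeHetNOETSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
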