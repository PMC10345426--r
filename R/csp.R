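#' Combined amide chemical-shift change
#'
#' The weighted Euclidean combination of the 1H and 15N shift changes,
#' with the nitrogen axis compressed by the fixed factor 5 so that both
#' nuclei contribute on a comparable ppm scale:
#' \deqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N/5)^2}}
#'
#' @param dh 1H shift change, ppm (vectorised).
#' @param dn 15N shift change, ppm.
#' @return combined shift change, ppm (non-negative).
#' @examples
#' deltaDelta(0.03, 0.25)  # 0.05831
#' @export
deltaDelta <- function(dh, dn) {
    if (any(!is.finite(dh)) || any(!is.finite(dn)))
        stop("shift changes must be finite")
    sqrt(dh^2 + (dn / 5)^2)
}

# Minimum-cost one-to-one assignment between two peak sets. The position
# term is the Euclidean distance in scaled (dH, dN/5) space; an optional
# intensity term penalises log-intensity mismatch, which arbitrates
# positional coincidences (two peaks meeting within the noise). Pairs
# whose positional distance exceeds maxStep get no edge. Returns the index
# into `to` (NA = unmatched) for each row of `from`.
.assignPeaks <- function(from, to, maxStep, intensityWeight = 0) {
    nf <- nrow(from); nt <- nrow(to)
    pos <- outer(seq_len(nf), seq_len(nt), function(i, j)
        sqrt((from$dH[i] - to$dH[j])^2 + ((from$dN[i] - to$dN[j]) / 5)^2))
    cost <- pos
    if (intensityWeight > 0 && !is.null(from$intensity) &&
        !is.null(to$intensity)) {
        ints <- outer(seq_len(nf), seq_len(nt), function(i, j)
            (intensityWeight *
             log(pmax(from$intensity[i], 1e-12) /
                 pmax(to$intensity[j], 1e-12)))^2)
        cost <- sqrt(pos^2 + ints)
    }
    edges <- which(pos <= maxStep, arr.ind = TRUE)
    if (!nrow(edges)) return(rep(NA_integer_, nf))
    # weight = bonus for matching at all, minus the cost: maximising total
    # weight then matches as many peaks as possible at minimum total cost
    bonus <- max(cost[edges]) * (min(nf, nt) + 1) + 1
    g <- igraph::make_bipartite_graph(
        c(rep(FALSE, nf), rep(TRUE, nt)),
        edges = as.vector(t(cbind(edges[, 1], nf + edges[, 2]))))
    igraph::E(g)$weight <- bonus - cost[edges]
    m <- igraph::max_bipartite_match(g)$matching
    out <- m[seq_len(nf)] - nf
    out[is.na(out) | out < 1] <- NA_integer_
    as.integer(out)
}

#' Track assigned peaks across a titration
#'
#' Links each assigned reference peak (molar ratio 0) through the
#' successive spectra by global minimum-cost one-to-one matching. The
#' matching cost is the Euclidean distance in scaled (dH, dN/5) space from
#' a velocity-extrapolated prediction of each peak's next position (in
#' fast exchange, peaks move along straight lines with step size
#' proportional to the change in bound fraction, so the previous
#' displacement scaled by the molar-ratio increment is a good forecast).
#' A weak log-intensity penalty (weight \code{intensityWeight})
#' disambiguates peaks that meet within the noise. A link whose positional
#' step exceeds \code{maxStep} is left unmatched; the peak's shifts at
#' that and later ratios are reported as missing (typical of
#' intermediate-exchange broadening), never as zero.
#'
#' @param series a [TitrationSeries-class]; reference peaks must carry
#'   unique residue assignments.
#' @param maxStep largest allowed per-step displacement in scaled ppm.
#' @param intensityWeight weight of the log-intensity term in the matching
#'   cost; 0 restores a purely positional cost.
#' @return data.frame in long format: \code{residue}, \code{ratio},
#'   \code{dH}, \code{dN}, \code{dd} (combined shift change from the
#'   reference position; NA when the peak was lost).
#' @export
trackPeaks <- function(series, maxStep = 0.25, intensityWeight = 0.2) {
    ref <- series@peaks[[1]]
    if (any(is.na(ref$residue)))
        stop("all reference peaks must carry residue assignments")
    if (anyDuplicated(ref$residue))
        stop("duplicate residue assignment in the reference peak list")
    rs <- series@ratios
    cur <- ref
    prev <- ref
    prevStep <- 1
    traj <- vector("list", length(rs))
    traj[[1]] <- data.frame(residue = ref$residue, ratio = rs[1],
                            dH = ref$dH, dN = ref$dN, dd = 0)
    alive <- rep(TRUE, nrow(ref))
    for (k in seq_along(rs)[-1]) {
        nxt <- series@peaks[[k]]
        g <- (rs[k] - rs[k - 1]) / prevStep
        pred <- cur
        pred$dH <- cur$dH + g * (cur$dH - prev$dH)
        pred$dN <- cur$dN + g * (cur$dN - prev$dN)
        match_k <- rep(NA_integer_, nrow(ref))
        if (any(alive) && nrow(nxt) > 0)
            match_k[alive] <- .assignPeaks(pred[alive, , drop = FALSE],
                                           nxt, maxStep, intensityWeight)
        lost <- is.na(match_k)
        dH <- ifelse(lost, NA_real_, nxt$dH[match_k])
        dN <- ifelse(lost, NA_real_, nxt$dN[match_k])
        dd <- ifelse(lost, NA_real_,
                     deltaDelta(ifelse(lost, 0, dH - ref$dH),
                                ifelse(lost, 0, dN - ref$dN)))
        traj[[k]] <- data.frame(residue = ref$residue, ratio = rs[k],
                                dH = dH, dN = dN, dd = dd)
        alive <- alive & !lost
        prev <- cur
        prevStep <- rs[k] - rs[k - 1]
        cur <- data.frame(residue = ref$residue,
                          dH = ifelse(lost, cur$dH, dH),
                          dN = ifelse(lost, cur$dN, dN),
                          intensity = ifelse(lost, cur$intensity,
                                             nxt$intensity[match_k]))
    }
    out <- do.call(rbind, traj)
    rownames(out) <- NULL
    out
}

#' Per-residue CSP table
#'
#' Reshapes a [trackPeaks()] trajectory into one row per residue with the
#' combined shift change at each molar ratio; \code{ddFinal} is the value
#' at the last titration point.
#'
#' @param tracked output of [trackPeaks()].
#' @return data.frame: \code{residue}, one \code{dd_<ratio>} column per
#'   ratio, \code{ddFinal}.
#' @export
cspTable <- function(tracked) {
    rs <- sort(unique(tracked$ratio))
    res <- sort(unique(tracked$residue))
    out <- data.frame(residue = res)
    for (r in rs) {
        sub <- tracked[tracked$ratio == r, ]
        out[[paste0("dd_", format(r))]] <- sub$dd[match(res, sub$residue)]
    }
    out$ddFinal <- out[[paste0("dd_", format(rs[length(rs)]))]]
    out
}

#' Call perturbed residues from a CSP table
#'
#' A residue is perturbed when its combined shift change at the final
#' titration point strictly exceeds the threshold (default 0.100 ppm).
#' Graded magnitude bins are also returned for structure colouring.
#'
#' @param table a [cspTable()] data.frame (needs \code{residue} and
#'   \code{ddFinal}).
#' @param threshold ppm; strict inequality.
#' @return list with \code{perturbed} (residue numbers), \code{bins}
#'   (factor per residue: none / weak / medium / strong), \code{threshold}.
#' @export
callPerturbed <- function(table, threshold = 0.100) {
    dd <- table$ddFinal
    if (all(is.na(dd)))
        stop("no final-ratio shift changes available")
    hit <- !is.na(dd) & dd > threshold
    bins <- cut(ifelse(is.na(dd), -Inf, dd),
                breaks = c(-Inf, threshold, 2 * threshold, 4 * threshold, Inf),
                labels = c("none", "weak", "medium", "strong"),
                right = TRUE)
    list(perturbed = table$residue[hit],
         bins = stats::setNames(bins, table$residue),
         threshold = threshold)
}

#' Read a titration series from per-ratio peak-list TSVs
#'
#' @param paths TSV files (columns residue, dH, dN, intensity), one per
#'   titration point, in ratio order.
#' @param ratios the molar ratios, same length/order as \code{paths}.
#' @return a [TitrationSeries-class].
#' @export
readTitrationTSV <- function(paths, ratios) {
    peaks <- lapply(paths, function(p) {
        .checkFile(p)
        d <- utils::read.delim(p, stringsAsFactors = FALSE)
        need <- c("residue", "dH", "dN", "intensity")
        if (!all(need %in% names(d)))
            stop("peak list '", p, "' must have columns: ",
                 paste(need, collapse = ", "))
        d[, need]
    })
    titrationSeries(ratios, peaks)
}

#' Write a titration series as per-ratio peak-list TSVs
#'
#' @param series a [TitrationSeries-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeTitrationTSV <- function(series, dir, prefix = "titration") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(length(series@ratios))
    for (k in seq_along(series@ratios)) {
        paths[k] <- file.path(dir, sprintf("%s_ratio_%s.tsv", prefix,
                                           format(series@ratios[k])))
        utils::write.table(series@peaks[[k]], paths[k], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(paths)
}
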