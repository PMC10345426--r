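AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

.checkAlphabet <- function(s, label) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(ch), AA_ALPHABET)
    if (length(bad))
        stop("invalid residue character(s) in ", label, ": ",
             paste(bad, collapse = ", "))
    ch
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh global alignment of two amino-acid sequences
#' under match/mismatch scoring and affine gap penalties (a gap of length L
#' costs \code{gapOpen + L * gapExtend}). Traceback ties are broken
#' deterministically: diagonal (align) first, then up (gap in \code{b}),
#' then left (gap in \code{a}).
#'
#' @param a,b character strings of 1-letter residue codes (20 canonical
#'   letters plus X).
#' @param match,mismatch substitution scores.
#' @param gapOpen,gapExtend affine gap parameters (negative).
#' @return data.frame with columns \code{posA}, \code{posB} (1-based
#'   positions; NA marks a gap), \code{resA}, \code{resB}; attribute
#'   \code{score} holds the optimal alignment score.
#' @examples
#' globalAlign("ACDE", "ACE")
#' @export
globalAlign <- function(a, b, match = 1, mismatch = 0,
                        gapOpen = -10, gapExtend = -0.5) {
    ca <- .checkAlphabet(a, "sequence a")
    cb <- .checkAlphabet(b, "sequence b")
    n <- length(ca); m <- length(cb)
    if (n == 0L || m == 0L) stop("sequences must be non-empty")
    NEG <- -Inf
    # M: ends in a match/mismatch; X: gap in b (consumes a); Y: gap in a
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)
    Y <- matrix(NEG, n + 1, m + 1)
    M[1, 1] <- 0
    for (i in 2:(n + 1)) X[i, 1] <- gapOpen + (i - 1) * gapExtend
    for (j in 2:(m + 1)) Y[1, j] <- gapOpen + (j - 1) * gapExtend
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- if (ca[i - 1] == cb[j - 1]) match else mismatch
            M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                           Y[i - 1, j - 1]) + s
            X[i, j] <- max(M[i - 1, j] + gapOpen + gapExtend,
                           X[i - 1, j] + gapExtend,
                           Y[i - 1, j] + gapOpen + gapExtend)
            Y[i, j] <- max(M[i, j - 1] + gapOpen + gapExtend,
                           Y[i, j - 1] + gapExtend,
                           X[i, j - 1] + gapOpen + gapExtend)
        }
    }
    # traceback; tie order: diagonal, up, left
    i <- n + 1; j <- m + 1
    state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
    posA <- integer(); posB <- integer()
    while (i > 1 || j > 1) {
        if (state == "M") {
            posA <- c(i - 1, posA); posB <- c(j - 1, posB)
            s <- if (ca[i - 1] == cb[j - 1]) match else mismatch
            prev <- M[i, j] - s
            cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
            state <- c("M", "X", "Y")[which(abs(cand - prev) < 1e-9)[1]]
            i <- i - 1; j <- j - 1
        } else if (state == "X") {
            posA <- c(i - 1, posA); posB <- c(NA, posB)
            v <- X[i, j]
            if (abs(M[i - 1, j] + gapOpen + gapExtend - v) < 1e-9) state <- "M"
            else if (abs(X[i - 1, j] + gapExtend - v) < 1e-9) state <- "X"
            else state <- "Y"
            i <- i - 1
        } else {
            posA <- c(NA, posA); posB <- c(j - 1, posB)
            v <- Y[i, j]
            if (abs(M[i, j - 1] + gapOpen + gapExtend - v) < 1e-9) state <- "M"
            else if (abs(Y[i, j - 1] + gapExtend - v) < 1e-9) state <- "Y"
            else state <- "X"
            j <- j - 1
        }
        if (i == 1 && j == 1) break
        if (i == 1 && state != "Y") state <- "Y"
        if (j == 1 && state != "X") state <- "X"
    }
    out <- data.frame(posA = posA, posB = posB,
                      resA = ifelse(is.na(posA), "-", ca[posA]),
                      resB = ifelse(is.na(posB), "-", cb[posB]),
                      stringsAsFactors = FALSE)
    attr(out, "score") <- max(M[n + 1, m + 1], X[n + 1, m + 1],
                              Y[n + 1, m + 1])
    out
}

# round half-up to `digits` decimals (base round() is round-half-even);
# the epsilon keeps exact rational ties (e.g. 41/80 of 100 = 51.25) from
# slipping below the boundary through floating-point representation
.roundHalfUp <- function(x, digits = 1) {
    f <- 10^digits
    floor(x * f + 0.5 + 1e-9) / f
}

#' Region-restricted percent identity
#'
#' Percent identity over the aligned (non-gap) pairs of an alignment map or
#' residue correspondence: 100 x identical pairs / aligned pairs within the
#' region, rounded half-up to one decimal. Gap columns never enter the
#' denominator.
#'
#' @param map an alignment from [globalAlign()], or a residue
#'   correspondence: data.frame whose first two columns are positions in
#'   \code{a} and \code{b}.
#' @param a,b the sequences (1-letter strings).
#' @param region optional vector of positions in \code{a} restricting the
#'   comparison.
#' @return percent identity, one decimal.
#' @examples
#' percentIdentity(globalAlign("ACDE", "ACDF"), "ACDE", "ACDF")  # 75.0
#' @export
percentIdentity <- function(map, a, b, region = NULL) {
    ca <- .checkAlphabet(a, "sequence a")
    cb <- .checkAlphabet(b, "sequence b")
    map <- as.data.frame(map)
    pa <- map[[1]]; pb <- map[[2]]
    keep <- !is.na(pa) & !is.na(pb)
    if (!is.null(region)) keep <- keep & pa %in% region
    if (!any(keep))
        stop("identity undefined: no aligned pairs in the requested region")
    pa <- pa[keep]; pb <- pb[keep]
    if (any(pa < 1 | pa > length(ca)) || any(pb < 1 | pb > length(cb)))
        stop("correspondence positions outside the sequences")
    .roundHalfUp(100 * mean(ca[pa] == cb[pb]), 1)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of 1-letter sequences.
#' @export
readFASTA <- function(path) {
    .checkFile(path)
    aa <- Biostrings::readAAStringSet(path)
    stats::setNames(as.character(aa), names(aa))
}
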