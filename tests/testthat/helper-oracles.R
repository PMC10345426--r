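# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Minimum RMSD between two point sets by the quaternion eigenvalue method:
# the optimal superposition RMSD is sqrt((Ga + Gb - 2*lmax)/n) where lmax
# is the largest eigenvalue of the 4x4 key matrix built from the
# correlation matrix of the centred coordinates.
quaternionRMSD <- function(a, b) {
    n <- nrow(a)
    a0 <- sweep(a, 2, colMeans(a))
    b0 <- sweep(b, 2, colMeans(b))
    Ga <- sum(a0^2); Gb <- sum(b0^2)
    M <- t(a0) %*% b0
    Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
    Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
    Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
    K <- matrix(c(
        Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
        Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
        Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
        Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
    lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    sqrt(max(0, (Ga + Gb - 2 * lmax) / n))
}

# Exhaustive global-alignment oracle: enumerates every alignment of two
# short sequences and returns the best score under match/mismatch scoring
# with affine gaps costing gapOpen + L*gapExtend for a gap of length L.
enumerateAlignments <- function(a, b, match = 1, mismatch = 0,
                                gapOpen = -10, gapExtend = -0.5) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- new.env(); best$score <- -Inf; best$aln <- NULL
    rec <- function(i, j, score, lastGap, colsA, colsB) {
        if (i > length(ca) && j > length(cb)) {
            if (score > best$score + 1e-9) {
                best$score <- score
                best$aln <- list(colsA = colsA, colsB = colsB)
            }
            return(invisible())
        }
        if (i <= length(ca) && j <= length(cb)) {
            s <- if (ca[i] == cb[j]) match else mismatch
            rec(i + 1, j + 1, score + s, "none",
                c(colsA, i), c(colsB, j))
        }
        if (i <= length(ca)) {
            pen <- gapExtend + if (lastGap == "up") 0 else gapOpen
            rec(i + 1, j, score + pen, "up", c(colsA, i), c(colsB, NA))
        }
        if (j <= length(cb)) {
            pen <- gapExtend + if (lastGap == "left") 0 else gapOpen
            rec(i, j + 1, score + pen, "left", c(colsA, NA), c(colsB, j))
        }
    }
    rec(1L, 1L, 0, "none", integer(0), integer(0))
    list(score = best$score, aln = best$aln)
}

# Brute-force minimum-cost one-to-one assignment between equal-sized peak
# sets (scaled-space Euclidean cost), enumerating all permutations.
bruteForceAssignment <- function(from, to) {
    n <- nrow(from)
    stopifnot(n == nrow(to), n <= 7)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (k in seq_along(v))
            for (p in perms(v[-k])) out <- c(out, list(c(v[k], p)))
        out
    }
    costOf <- function(p) sum(sqrt(
        (from$dH - to$dH[p])^2 + ((from$dN - to$dN[p]) / 5)^2))
    allp <- perms(seq_len(n))
    costs <- vapply(allp, costOf, numeric(1))
    allp[[which.min(costs)]]
}

# Random non-degenerate point set for superposition tests.
randomPoints <- function(n) matrix(stats::rnorm(3 * n, sd = 3), n, 3)

# A minimal hand-written multi-model PDB text.
pdbText <- function(models) {
    fmt <- function(i, name, resno, x, y, z)
        sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
                i, name, resno, x, y, z, substr(name, 1, 1))
    out <- character(0)
    multi <- length(models) > 1
    for (m in seq_along(models)) {
        if (multi) out <- c(out, sprintf("MODEL     %4d", m))
        mm <- models[[m]]
        out <- c(out, mapply(fmt, seq_len(nrow(mm)), mm$name, mm$resno,
                             mm$x, mm$y, mm$z))
        if (multi) out <- c(out, "ENDMDL")
    }
    c(out, "END")
}
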