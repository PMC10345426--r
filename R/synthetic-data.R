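# Run expr with a private RNG stream; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Place atom D from A-B-C with given |C-D|, angle B-C-D (deg) and torsion
# A-B-C-D (deg): standard internal-to-Cartesian (NeRF) construction.
.placeAtom <- function(A, B, C, bond, angle, torsion) {
    ang <- angle * pi / 180
    tor <- torsion * pi / 180
    bc <- C - B
    bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
           bond * sin(ang) * sin(tor))
    C + d[1] * bc + d[2] * m + d[3] * n
}

# Idealised poly-alanine backbone (N, CA, C, O per residue) with a mixed
# alpha/beta secondary-structure layout: beta strands in the first
# three-quarters of the chain, a C-terminal alpha helix, loops between.
.idealBackbone <- function(nResidues) {
    phiPsi <- function(i) {
        f <- i / nResidues
        if (f > 0.75 && f <= 0.97) c(-57, -47)        # helix
        else if (i %% 10 <= 6) c(-120, 130)           # strand
        else c(-80, 150)                              # loop
    }
    coords <- matrix(NA_real_, nResidues * 4, 3)
    atoms <- data.frame(
        chain = "A", resno = rep(seq_len(nResidues), each = 4),
        resname = "ALA", atom = rep(c("N", "CA", "C", "O"), nResidues),
        element = rep(c("N", "C", "C", "O"), nResidues),
        stringsAsFactors = FALSE)
    # first residue: canonical positions
    N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
    C <- CA + 1.525 * c(cos(pi - 111.2 * pi / 180),
                        sin(pi - 111.2 * pi / 180), 0)
    for (i in seq_len(nResidues)) {
        pp <- phiPsi(i)
        if (i > 1) {
            N <- .placeAtom(prevN, prevCA, prevC, 1.329, 116.2, prevPsi)
            CA <- .placeAtom(prevCA, prevC, N, 1.458, 121.7, 180)
            C <- .placeAtom(prevC, N, CA, 1.525, 111.2, pp[1])
        }
        O <- .placeAtom(N, CA, C, 1.231, 120.8, pp[2] + 180)
        coords[(i - 1) * 4 + 1:4, ] <- rbind(N, CA, C, O)
        prevN <- N; prevCA <- CA; prevC <- C; prevPsi <- pp[2]
    }
    list(atoms = atoms, coords = coords)
}

#' Synthetic multi-model structure ensemble
#'
#' Builds an idealised mixed alpha/beta poly-alanine backbone and creates
#' \code{nModels} copies perturbed by iid Gaussian coordinate noise,
#' emulating an NMR conformer bundle of known precision. The unperturbed
#' template is retained in the \code{"template"} attribute.
#'
#' @param nResidues chain length (default 108, a typical PH-domain size).
#' @param nModels number of models (default 20).
#' @param sigma per-coordinate jitter standard deviation, Angstroms.
#' @param seed RNG seed.
#' @return a [StructureEnsemble-class]; attributes \code{template}
#'   (n_atoms x 3 matrix) and \code{sigma}.
#' @export
makeEnsemble <- function(nResidues = 108, nModels = 20, sigma = 0.5,
                         seed = 1) {
    stopifnot(nResidues >= 2, nModels >= 1, sigma >= 0)
    tpl <- .idealBackbone(nResidues)
    nat <- nrow(tpl$coords)
    coords <- .withSeed(seed, {
        x <- array(NA_real_, c(nat, 3, nModels))
        for (m in seq_len(nModels))
            x[, , m] <- tpl$coords + matrix(stats::rnorm(nat * 3, 0, sigma),
                                            nat, 3)
        x
    })
    ens <- new("StructureEnsemble", atoms = tpl$atoms, coords = coords)
    attr(ens, "template") <- tpl$coords
    attr(ens, "sigma") <- sigma
    ens
}

#' Fraction of protein bound at equilibrium
#'
#' Quadratic solution of the 1:1 binding equilibrium used by the
#' fast-exchange titration model.
#'
#' @param protein total protein concentration, uM.
#' @param ligand total ligand concentration, uM.
#' @param kd dissociation constant, nM.
#' @return bound fraction in [0, 1].
#' @examples
#' fractionBound(30, 15, 12.4)  # ~0.5
#' @export
fractionBound <- function(protein, ligand, kd) {
    kdum <- kd / 1000                     # nM -> uM
    s <- protein + ligand + kdum
    f <- (s - sqrt(pmax(s^2 - 4 * protein * ligand, 0))) / (2 * protein)
    pmin(pmax(f, 0), 1)
}

#' Synthetic fast-exchange HSQC titration
#'
#' Assigns every residue a random reference peak position, then moves the
#' planted binding-site residues along fixed per-residue directions by
#' \code{fractionBound(ratio) * ddMax} in combined-shift units (the
#' fast-exchange population-weighted average). Non-site residues receive
#' iid background jitter of typical combined magnitude
#' \code{backgroundSigma} at every non-reference point. Optionally a set
#' of residues vanishes at the final ratio (exchange broadening).
#'
#' @param nResidues number of assigned residues.
#' @param proteinConc protein concentration, uM (0.1 mM design default).
#' @param ratios ligand:protein molar ratios (first 0).
#' @param kd ground-truth dissociation constant, nM.
#' @param siteResidues residues that respond to ligand.
#' @param ddMax saturating combined shift change per site residue, ppm
#'   (recycled).
#' @param backgroundSigma background jitter magnitude, ppm.
#' @param vanishResidues residues whose peaks disappear at the last ratio.
#' @param seed RNG seed.
#' @return a [TitrationSeries-class]; attributes \code{siteResidues},
#'   \code{kd}, \code{fBound} (per-ratio bound fraction).
#' @export
makeTitration <- function(nResidues = 108, proteinConc = 100,
                          ratios = c(0, 0.25, 0.5, 1), kd = 50,
                          siteResidues = c(20, 22, 45, 60, 92),
                          ddMax = 0.3, backgroundSigma = 0.01,
                          vanishResidues = integer(0), seed = 1) {
    stopifnot(ratios[1] == 0, all(siteResidues <= nResidues))
    ddMax <- rep_len(ddMax, length(siteResidues))
    .withSeed(seed, {
        res <- seq_len(nResidues)
        dH0 <- stats::runif(nResidues, 7.5, 9.5)
        dN0 <- stats::runif(nResidues, 105, 130)
        intensity <- stats::runif(nResidues, 0.5, 1)
        dir <- stats::runif(length(siteResidues), 0, 2 * pi)
        fb <- fractionBound(proteinConc, ratios * proteinConc, kd)
        peaks <- vector("list", length(ratios))
        for (k in seq_along(ratios)) {
            dH <- dH0; dN <- dN0
            if (k > 1) {
                jit <- backgroundSigma / sqrt(2)
                bg <- setdiff(res, siteResidues)
                dH[bg] <- dH[bg] + stats::rnorm(length(bg), 0, jit)
                dN[bg] <- dN[bg] + stats::rnorm(length(bg), 0, 5 * jit)
                dd <- fb[k] * ddMax
                dH[siteResidues] <- dH[siteResidues] + dd * cos(dir)
                dN[siteResidues] <- dN[siteResidues] + 5 * dd * sin(dir)
            }
            p <- data.frame(residue = res, dH = dH, dN = dN,
                            intensity = intensity)
            if (k == length(ratios) && length(vanishResidues))
                p <- p[!p$residue %in% vanishResidues, ]
            if (k > 1) p$residue <- NA_integer_  # only the reference is assigned
            peaks[[k]] <- p
        }
        out <- titrationSeries(ratios, peaks)
        attr(out, "siteResidues") <- siteResidues
        attr(out, "kd") <- kd
        attr(out, "fBound") <- fb
        out
    })
}

#' Synthetic noisy ITC experiment
#'
#' Simulates the one-site isotherm for a design and adds iid Gaussian
#' noise to the per-injection heats.
#'
#' @param design an [ITCExperiment-class] (heats ignored); default is the
#'   standard 25 x 20 ul peptide-into-protein design of [itcExperiment()].
#' @param params ground-truth [bindingParams()].
#' @param noiseSigma absolute noise sd, ucal; when NULL,
#'   \code{noiseFraction} of the largest |heat| is used.
#' @param noiseFraction relative noise level (default 2\%).
#' @param seed RNG seed.
#' @return an [ITCExperiment-class] with noisy heats.
#' @export
makeITC <- function(design = itcExperiment(), params,
                    noiseSigma = NULL, noiseFraction = 0.02, seed = 1) {
    pure <- simulateIsotherm(design, params)
    if (is.null(noiseSigma)) noiseSigma <- noiseFraction * max(abs(pure))
    noisy <- .withSeed(seed,
        pure + stats::rnorm(length(pure), 0, noiseSigma))
    heats(design) <- noisy
    design
}

#' Synthetic NOE restraint list with planted class counts
#'
#' Generates atom-pair contacts whose sequence separations realise the
#' requested per-class counts exactly, with random residues, proton names
#' and intensity classes.
#'
#' @param classCounts named integer vector over intraresidue, sequential,
#'   medium, long.
#' @param nResidues chain length over which contacts are drawn.
#' @param seed RNG seed.
#' @return a [restraintTable()] data.frame; attribute \code{classCounts}
#'   holds the planted ground truth.
#' @export
makeRestraints <- function(classCounts = c(intraresidue = 313,
                                           sequential = 685,
                                           medium = 404, long = 1225),
                           nResidues = 108, seed = 1) {
    stopifnot(all(SEPARATION_CLASSES %in% names(classCounts)),
              nResidues >= 10)
    .withSeed(seed, {
        sepOf <- function(cls, k) switch(cls,
            intraresidue = rep(0L, k),
            sequential = rep(1L, k),
            medium = sample(2:4, k, replace = TRUE),
            long = sample(5:(nResidues - 1), k, replace = TRUE))
        resI <- integer(0); sep <- integer(0)
        for (cls in SEPARATION_CLASSES) {
            k <- classCounts[[cls]]
            if (k == 0) next
            s <- sepOf(cls, k)
            resI <- c(resI, vapply(s, function(si)
                sample(seq_len(nResidues - si), 1L), integer(1)))
            sep <- c(sep, s)
        }
        resJ <- resI + sep
        protons <- c("HN", "HA", "HB", "HG", "HD")
        n <- length(resI)
        restraintTable(
            residueI = resI,
            atomI = sample(protons, n, replace = TRUE),
            residueJ = resJ,
            atomJ = sample(protons, n, replace = TRUE),
            intensityClass = sample(names(defaultBinningScheme()$upper), n,
                                    replace = TRUE)) ->
            out
        attr(out, "classCounts") <- classCounts
        out
    })
}

#' Synthetic heteronuclear NOE profile with planted mobile segments
#'
#' Rigid residues sit at a plateau NOE; residues inside the mobile
#' segments sit at a low NOE; Gaussian intensity noise is added to both
#' spectra. Defaults plant flexible termini and one flexible loop, the
#' canonical mobility pattern of a compact globular domain.
#'
#' @param nResidues chain length.
#' @param mobileSegments list of residue-number vectors planted as mobile.
#' @param rigidNOE,mobileNOE ground-truth NOE plateaus.
#' @param iRef reference-peak intensity (arbitrary units).
#' @param noiseSigma intensity noise sd (same units as \code{iRef}).
#' @param missingResidues residues reported with missing intensities
#'   (overlapped peaks, prolines).
#' @param seed RNG seed.
#' @return data.frame: residue, iSat, iRef, sigmaSat, sigmaRef, noe,
#'   sigma; attribute \code{mobileResidues} holds the planted ground
#'   truth.
#' @export
makeHetNOE <- function(nResidues = 108,
                       mobileSegments = list(1:4, 64:68, 104:108),
                       rigidNOE = 0.85, mobileNOE = 0.30, iRef = 1e6,
                       noiseSigma = 0.01 * iRef,
                       missingResidues = integer(0), seed = 1) {
    mobile <- sort(unique(unlist(mobileSegments)))
    stopifnot(all(mobile <= nResidues))
    .withSeed(seed, {
        res <- seq_len(nResidues)
        trueNOE <- ifelse(res %in% mobile, mobileNOE, rigidNOE)
        iR <- iRef + stats::rnorm(nResidues, 0, noiseSigma)
        iS <- trueNOE * iRef + stats::rnorm(nResidues, 0, noiseSigma)
        d <- data.frame(residue = res, iSat = iS, iRef = iR,
                        sigmaSat = noiseSigma, sigmaRef = noiseSigma)
        d[d$residue %in% missingResidues, c("iSat", "iRef")] <- NA_real_
        ok <- !is.na(d$iSat)
        d$noe <- NA_real_; d$sigma <- NA_real_
        r <- computeNOE(d$iSat[ok], d$iRef[ok], noiseSigma, noiseSigma)
        d$noe[ok] <- r$noe; d$sigma[ok] <- r$sigma
        attr(d, "mobileResidues") <- setdiff(mobile, missingResidues)
        d
    })
}
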