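#' @import methods
NULL

#' Multi-model protein structure ensemble
#'
#' Container for a set of structural models (e.g. the 20 lowest-energy
#' conformers of an NMR structure calculation) sharing one atom roster.
#' Coordinates are stored as an \code{n_atoms x 3 x n_models} array in
#' Angstroms; the roster (chain, residue number, residue name, atom name,
#' element) is a data frame parallel to the first array dimension.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}; one row per roster atom.
#' @slot coords numeric array, \code{n_atoms x 3 x n_models}, Angstroms.
#'
#' @seealso [readEnsemble()], [makeEnsemble()], [ensemblePrecision()]
#' @export
setClass("StructureEnsemble",
    representation(atoms = "data.frame", coords = "array"))

setValidity("StructureEnsemble", function(object) {
    a <- object@atoms
    x <- object@coords
    msgs <- character()
    need <- c("chain", "resno", "resname", "atom", "element")
    if (!all(need %in% names(a)))
        msgs <- c(msgs, paste("atoms must have columns:",
                              paste(need, collapse = ", ")))
    if (length(dim(x)) != 3L || dim(x)[2] != 3L)
        msgs <- c(msgs, "coords must be an n_atoms x 3 x n_models array")
    else {
        if (dim(x)[1] != nrow(a))
            msgs <- c(msgs, "coords first dimension must match atom roster")
        if (dim(x)[3] < 1L)
            msgs <- c(msgs, "ensemble must contain at least one model")
        if (!all(is.finite(x)))
            msgs <- c(msgs, "all coordinates must be finite")
    }
    if (all(need %in% names(a)) && nrow(a) > 0L) {
        key <- paste(a$chain, a$resno, a$atom)
        if (anyDuplicated(key))
            msgs <- c(msgs, paste("duplicate (chain, residue, atom) in roster:",
                                  paste(unique(key[duplicated(key)]), collapse = "; ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' HSQC titration series
#'
#' Peak lists acquired at increasing ligand:protein molar ratios. The first
#' ratio must be 0 (the free-protein reference spectrum) and its peaks must
#' carry residue assignments. Later peak lists may be unassigned; residue
#' identity is then recovered by [trackPeaks()].
#'
#' @slot ratios numeric vector of molar ratios, strictly increasing, first 0.
#' @slot peaks list of data.frames (one per ratio) with columns
#'   \code{residue} (integer or NA), \code{dH} (ppm), \code{dN} (ppm),
#'   \code{intensity}.
#'
#' @seealso [titrationSeries()], [makeTitration()], [trackPeaks()]
#' @export
setClass("TitrationSeries",
    representation(ratios = "numeric", peaks = "list"))

setValidity("TitrationSeries", function(object) {
    r <- object@ratios
    msgs <- character()
    if (length(r) < 1L || r[1] != 0)
        msgs <- c(msgs, "first molar ratio must be 0 (reference spectrum)")
    if (any(diff(r) <= 0))
        msgs <- c(msgs, "molar ratios must be strictly increasing")
    if (length(object@peaks) != length(r))
        msgs <- c(msgs, "one peak list required per ratio")
    for (p in object@peaks) {
        if (!all(c("residue", "dH", "dN", "intensity") %in% names(p))) {
            msgs <- c(msgs, "peak lists need columns residue, dH, dN, intensity")
            break
        }
        if (any(!is.finite(p$dH)) || any(!is.finite(p$dN)))
            msgs <- c(msgs, "peak positions must be finite")
        if (any(p$intensity < 0, na.rm = TRUE))
            msgs <- c(msgs, "peak intensities must be non-negative")
    }
    if (length(msgs)) unique(msgs) else TRUE
})

#' Isothermal titration calorimetry experiment
#'
#' Injection schedule, cell/syringe concentrations and (optionally) the
#' integrated per-injection heats of a single ITC run. Heats are in
#' microcalories; concentrations in micromolar; the cell volume in
#' millilitres; injection volumes in microlitres.
#'
#' @slot cellVolume numeric, ml.
#' @slot cellConc numeric, uM macromolecule in the cell.
#' @slot syringeConc numeric, uM ligand in the syringe.
#' @slot injectionVolumes numeric vector, ul per injection.
#' @slot temperature numeric, Kelvin.
#' @slot heats numeric vector of integrated heats (ucal), or length 0 when
#'   the experiment is a pure design (simulation input).
#'
#' @seealso [itcExperiment()], [simulateIsotherm()], [fitSingleSite()]
#' @export
setClass("ITCExperiment",
    representation(cellVolume = "numeric", cellConc = "numeric",
                   syringeConc = "numeric", injectionVolumes = "numeric",
                   temperature = "numeric", heats = "numeric"))

setValidity("ITCExperiment", function(object) {
    msgs <- character()
    if (object@cellVolume <= 0) msgs <- c(msgs, "cell volume must be > 0")
    if (object@cellConc <= 0) msgs <- c(msgs, "cell concentration must be > 0")
    if (object@syringeConc < 0) msgs <- c(msgs, "syringe concentration must be >= 0")
    if (length(object@injectionVolumes) < 1L || any(object@injectionVolumes <= 0))
        msgs <- c(msgs, "injection volumes must be positive")
    if (object@temperature <= 0) msgs <- c(msgs, "temperature must be > 0 K")
    if (length(object@heats) &&
        length(object@heats) != length(object@injectionVolumes))
        msgs <- c(msgs, "heats, when present, must match the injection count")
    if (length(msgs)) msgs else TRUE
})

#' Construct a TitrationSeries
#'
#' @param ratios numeric vector of ligand:protein molar ratios (first 0).
#' @param peaks list of peak data.frames, one per ratio, columns
#'   \code{residue}, \code{dH}, \code{dN}, \code{intensity}.
#' @return A [TitrationSeries-class] object.
#' @export
titrationSeries <- function(ratios, peaks) {
    new("TitrationSeries", ratios = as.numeric(ratios), peaks = peaks)
}

#' Construct an ITCExperiment
#'
#' Defaults reproduce a typical VP-ITC peptide-into-protein design:
#' 2 ml cell containing 30 uM macromolecule, 300 uM ligand in the syringe,
#' 25 injections of 20 ul at 20 degrees C.
#'
#' @param cellConc macromolecule concentration in the cell, uM.
#' @param syringeConc ligand concentration in the syringe, uM.
#' @param cellVolume active cell volume, ml.
#' @param nInjections number of injections (used when
#'   \code{injectionVolumes} is not given).
#' @param injectionVolume volume per injection, ul.
#' @param injectionVolumes explicit per-injection volumes, ul.
#' @param temperature Kelvin.
#' @param heats optional integrated heats, ucal, one per injection.
#' @return An [ITCExperiment-class] object.
#' @export
itcExperiment <- function(cellConc = 30, syringeConc = 300, cellVolume = 2,
                          nInjections = 25, injectionVolume = 20,
                          injectionVolumes = rep(injectionVolume, nInjections),
                          temperature = 293.15, heats = numeric(0)) {
    new("ITCExperiment", cellVolume = cellVolume, cellConc = cellConc,
        syringeConc = syringeConc,
        injectionVolumes = as.numeric(injectionVolumes),
        temperature = temperature, heats = as.numeric(heats))
}

#' @describeIn StructureEnsemble-class number of models in the ensemble
#' @param x,object a \code{StructureEnsemble}
#' @export
nModels <- function(x) dim(x@coords)[3]

#' @describeIn StructureEnsemble-class the atom roster data.frame
#' @export
atomData <- function(x) x@atoms

#' Residue sequence of an ensemble roster
#'
#' @param x a [StructureEnsemble-class]
#' @return named character vector: residue number -> 3-letter residue name.
#' @export
rosterSequence <- function(x) {
    a <- x@atoms[!duplicated(paste(x@atoms$chain, x@atoms$resno)), ]
    stats::setNames(a$resname, a$resno)
}

#' Molar ratios of a titration series
#' @param x a [TitrationSeries-class]
#' @export
ratios <- function(x) x@ratios

#' Peak lists of a titration series
#' @param x a [TitrationSeries-class]
#' @export
peakLists <- function(x) x@peaks

#' Integrated heats of an ITC experiment
#' @param x an [ITCExperiment-class]
#' @export
heats <- function(x) x@heats

#' Replace the heats of an ITC experiment
#' @param x an [ITCExperiment-class]
#' @param value numeric vector of heats, ucal
#' @export
`heats<-` <- function(x, value) {
    x@heats <- as.numeric(value)
    validObject(x)
    x
}

setMethod("show", "StructureEnsemble", function(object) {
    a <- object@atoms
    nres <- length(unique(paste(a$chain, a$resno)))
    cat(sprintf("StructureEnsemble: %d model(s), %d residues, %d atoms\n",
                nModels(object), nres, nrow(a)))
    cat(sprintf("  chains: %s; residues %d-%d\n",
                paste(unique(a$chain), collapse = ","),
                min(a$resno), max(a$resno)))
})

setMethod("show", "TitrationSeries", function(object) {
    cat(sprintf("TitrationSeries: %d points, molar ratios %s\n",
                length(object@ratios),
                paste(format(object@ratios), collapse = ", ")))
    cat(sprintf("  reference peaks: %d\n", nrow(object@peaks[[1]])))
})

setMethod("show", "ITCExperiment", function(object) {
    cat(sprintf(
        "ITCExperiment: %d x %.3g ul into %.3g ml; cell %.3g uM, syringe %.3g uM, %.2f K\n",
        length(object@injectionVolumes), object@injectionVolumes[1],
        object@cellVolume, object@cellConc, object@syringeConc,
        object@temperature))
    if (length(object@heats))
        cat(sprintf("  heats: %.4g .. %.4g ucal\n",
                    object@heats[1], object@heats[length(object@heats)]))
    else cat("  heats: none (design only)\n")
})
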