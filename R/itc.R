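R_KCAL <- 1.9872e-3  # gas constant, kcal/(mol K)

#' One-site binding parameters
#'
#' @param n stoichiometry (sites per macromolecule).
#' @param ka association constant, 1/M (Kd = 1/ka).
#' @param dh binding enthalpy, kcal/mol.
#' @param qOffset per-injection dilution-heat baseline, ucal.
#' @return list of validated parameters.
#' @export
bindingParams <- function(n = 1, ka, dh, qOffset = 0) {
    if (!is.finite(ka) || ka <= 0) stop("ka must be positive and finite")
    if (!is.finite(n) || n <= 0) stop("n must be positive and finite")
    if (!is.finite(dh)) stop("dh must be finite")
    list(n = n, ka = ka, dh = dh, qOffset = qOffset)
}

# Cell concentrations after each injection under the discrete perfusion
# model: inject dv of syringe solution, mix, displace dv of the mixture.
# Returns per-injection macromolecule and ligand concentrations (M).
.cellConcentrations <- function(object) {
    V0 <- object@cellVolume * 1e-3            # L
    dv <- object@injectionVolumes * 1e-6      # L
    M0 <- object@cellConc * 1e-6              # mol/L
    Xs <- object@syringeConc * 1e-6
    ni <- length(dv)
    Mt <- numeric(ni); Xt <- numeric(ni)
    m <- M0; xl <- 0
    for (i in seq_len(ni)) {
        f <- V0 / (V0 + dv[i])
        m <- m * f
        xl <- (xl * V0 + Xs * dv[i]) / (V0 + dv[i])
        Mt[i] <- m; Xt[i] <- xl
    }
    list(Mt = Mt, Xt = Xt, V0 = V0, dv = dv)
}

# Fraction of binding sites occupied: quadratic equilibrium solution for
# sites at concentration n*Mt, ligand Xt, dissociation constant 1/ka.
.boundFraction <- function(Mt, Xt, n, ka) {
    E <- n * Mt
    kd <- 1 / ka
    s <- E + Xt + kd
    theta <- (s - sqrt(pmax(s^2 - 4 * E * Xt, 0))) / (2 * E)
    pmin(pmax(theta, 0), 1)
}

#' Simulate a one-site ITC isotherm
#'
#' Standard single-site (Wiseman) model. After injection i the cumulative
#' heat content of the cell is \eqn{Q_i = n \theta_i M_i \Delta H V_0},
#' with the bound fraction \eqn{\theta_i} from the quadratic equilibrium
#' solution at the post-injection cell concentrations (macromolecule and
#' ligand dilution tracked per injection by the discrete perfusion model).
#' The observed per-injection heat applies the displaced-volume midpoint
#' correction:
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,
#'   \frac{Q_i + Q_{i-1}}{2} + q_{offset}}
#'
#' @param object an [ITCExperiment-class] (heats not required).
#' @param params [bindingParams()].
#' @return numeric vector of per-injection heats, ucal.
#' @export
simulateIsotherm <- function(object, params) {
    params <- bindingParams(params$n, params$ka, params$dh,
                            if (is.null(params$qOffset)) 0 else params$qOffset)
    cc <- .cellConcentrations(object)
    theta <- .boundFraction(cc$Mt, cc$Xt, params$n, params$ka)
    # Q in ucal: mol/L * L * kcal/mol * 1e9 ucal/kcal
    Q <- params$n * theta * cc$Mt * params$dh * cc$V0 * 1e9
    Qprev <- c(0, Q[-length(Q)])
    Q - Qprev + (cc$dv / cc$V0) * (Q + Qprev) / 2 + params$qOffset
}

#' Derived binding thermodynamics
#'
#' @param ka association constant, 1/M.
#' @param dh binding enthalpy, kcal/mol.
#' @param temperature Kelvin.
#' @return list with \code{dg} and \code{tds}, kcal/mol
#'   (dG = -RT ln Ka; TdS = dH - dG).
#' @examples
#' thermodynamics(1 / 52.1e-9, dh = -10, temperature = 293.15)
#' @export
thermodynamics <- function(ka, dh, temperature = 293.15) {
    if (ka <= 0 || temperature <= 0)
        stop("ka and temperature must be positive")
    dg <- -R_KCAL * temperature * log(ka)
    list(dg = dg, tds = dh - dg)
}

#' Fit the one-site model to measured injection heats
#'
#' Least-squares estimation of (n, Ka, dH, q_offset) against
#' [simulateIsotherm()]. Starting values come from a coarse grid over
#' log10(Ka) and n in which dH and q_offset are solved linearly; the grid
#' optimum is refined by Levenberg-Marquardt (Ka parametrised on the log
#' scale). Standard errors come from the local quadratic approximation at
#' the optimum.
#'
#' @param object an [ITCExperiment-class] carrying heats.
#' @param dropFirst drop the first injection before fitting (common
#'   practice for diffusion across the syringe tip).
#' @param temperature Kelvin used for the derived thermodynamics; defaults
#'   to the experiment's.
#' @return object of class \code{itcFit}: \code{params} (n, ka, dh,
#'   qOffset), \code{kd} (nM), \code{dg}, \code{tds} (kcal/mol), \code{se}
#'   (standard errors incl. \code{kd}), \code{rss}, \code{converged},
#'   \code{cValue}, \code{fitted}, \code{residuals}.
#' @export
fitSingleSite <- function(object, dropFirst = FALSE, temperature = NULL) {
    y <- object@heats
    if (!length(y)) stop("experiment carries no heats to fit")
    if (length(y) < 5L) stop("at least 5 injections are required")
    if (is.null(temperature)) temperature <- object@temperature
    use <- seq_along(y)
    if (dropFirst) use <- use[-1]
    yy <- y[use]

    if (max(abs(yy - mean(yy))) < 1e-9 * max(abs(yy), 1) ||
        all(abs(yy) < 1e-12)) {
        warning("heats carry no titration signal; ka is unidentifiable")
        return(structure(list(
            params = list(n = NA_real_, ka = NA_real_, dh = 0,
                          qOffset = mean(yy)),
            kd = NA_real_, dg = NA_real_, tds = NA_real_,
            se = list(n = NA_real_, ka = NA_real_, dh = NA_real_,
                      qOffset = NA_real_, kd = NA_real_),
            rss = sum((yy - mean(yy))^2), converged = FALSE,
            cValue = NA_real_, fitted = rep(mean(yy), length(y)),
            residuals = y - mean(yy)), class = "itcFit"))
    }

    unitHeat <- function(n, ka)   # per-injection heats at dH = 1, offset 0
        simulateIsotherm(object, list(n = n, ka = ka, dh = 1, qOffset = 0))[use]

    # coarse grid: dh and offset are linear given (n, ka)
    best <- NULL
    for (lka in seq(3, 11, by = 0.5)) {
        for (n0 in seq(0.6, 1.6, by = 0.2)) {
            p <- unitHeat(n0, 10^lka)
            fitlm <- stats::lm.fit(cbind(p, 1), yy)
            rss <- sum(fitlm$residuals^2)
            if (is.null(best) || rss < best$rss)
                best <- list(rss = rss, n = n0, lka = log(10^lka),
                             dh = fitlm$coefficients[1],
                             q0 = fitlm$coefficients[2])
        }
    }

    residFun <- function(par)
        simulateIsotherm(object, list(n = par[1], ka = exp(par[2]),
                                   dh = par[3], qOffset = par[4]))[use] - yy
    start <- c(best$n, best$lka, best$dh, best$q0)
    fit <- minpack.lm::nls.lm(
        par = start, fn = residFun,
        lower = c(1e-3, log(1), -1e6, -1e6),
        upper = c(1e3, log(1e15), 1e6, 1e6),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    par <- fit$par
    converged <- fit$info %in% 1:4
    n <- par[1]; ka <- exp(par[2]); dh <- par[3]; q0 <- par[4]

    dof <- length(yy) - 4L
    se <- rep(NA_real_, 4)
    if (dof > 0) {
        covm <- tryCatch(fit$deviance / dof * solve(fit$hessian),
                         error = function(e) NULL)
        if (!is.null(covm)) {
            dg <- sqrt(pmax(diag(covm), 0))
            se <- c(dg[1], ka * dg[2], dg[3], dg[4])  # delta method for ka
        }
    }
    kd <- 1e9 / ka
    seKd <- if (is.na(se[2])) NA_real_ else kd * se[2] / ka
    cValue <- ka * object@cellConc * 1e-6
    if (is.finite(cValue) && (cValue < 1 || cValue > 1e4))
        warning(sprintf(
            "c-value %.3g outside ~1-1e4: Kd is poorly determined", cValue))
    th <- thermodynamics(ka, dh, temperature)
    fitted <- simulateIsotherm(object, list(n = n, ka = ka, dh = dh,
                                         qOffset = q0))
    structure(list(
        params = list(n = n, ka = ka, dh = dh, qOffset = q0),
        kd = kd, dg = th$dg, tds = th$tds,
        se = list(n = se[1], ka = se[2], dh = se[3], qOffset = se[4],
                  kd = seKd),
        rss = fit$deviance, converged = converged, cValue = cValue,
        fitted = fitted, residuals = y - fitted), class = "itcFit")
}

#' @export
print.itcFit <- function(x, ...) {
    cat("One-site ITC fit\n")
    cat(sprintf("  n       = %.4g +/- %.2g\n", x$params$n, x$se$n))
    cat(sprintf("  Kd      = %.4g nM (+/- %.2g)\n", x$kd, x$se$kd))
    cat(sprintf("  dH      = %.4g kcal/mol (+/- %.2g)\n",
                x$params$dh, x$se$dh))
    cat(sprintf("  dG      = %.4g kcal/mol;  TdS = %.4g kcal/mol\n",
                x$dg, x$tds))
    cat(sprintf("  c-value = %.3g; converged: %s\n", x$cValue, x$converged))
    invisible(x)
}

#' Read / write injection-heat TSVs
#'
#' Columns: index, volume_ul, heat_ucal. Experiment geometry (cell and
#' syringe concentrations, cell volume, temperature) is supplied by the
#' caller since the TSV carries only the injection series.
#'
#' @param path file path.
#' @param ... passed to [itcExperiment()] (concentrations, volume,
#'   temperature).
#' @return an [ITCExperiment-class] with heats.
#' @export
readITCTSV <- function(path, ...) {
    .checkFile(path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("index", "volume_ul", "heat_ucal")
    if (!all(need %in% names(d)))
        stop("ITC TSV must have columns: ", paste(need, collapse = ", "))
    d <- d[order(d$index), ]
    itcExperiment(..., injectionVolumes = d$volume_ul, heats = d$heat_ucal)
}

#' @rdname readITCTSV
#' @param object an [ITCExperiment-class] with heats to write.
#' @export
writeITCTSV <- function(object, path) {
    stopifnot(length(object@heats) > 0)
    utils::write.table(
        data.frame(index = seq_along(object@injectionVolumes),
                   volume_ul = object@injectionVolumes,
                   heat_ucal = object@heats),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
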