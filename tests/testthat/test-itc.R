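test_that("degenerate parameters give pure-baseline heats", {
    des <- itcExperiment()
    h0 <- simulateIsotherm(des, list(n = 1, ka = 1e7, dh = 0, qOffset = 0.3))
    expect_equal(h0, rep(0.3, 25), tolerance = 1e-12)
    des2 <- itcExperiment(syringeConc = 0)
    h1 <- simulateIsotherm(des2, list(n = 1, ka = 1e7, dh = -10,
                                      qOffset = -0.2))
    expect_equal(h1, rep(-0.2, 25), tolerance = 1e-12)
    expect_error(simulateIsotherm(des, list(n = 1, ka = -5, dh = -10)),
                 "positive")
})

test_that("at very high c the isotherm is a stoichiometric step at molar ratio n", {
    des <- itcExperiment()           # 300 uM into 2 ml of 30 uM
    molesPerInj <- 300e-6 * 20e-6    # mol ligand per injection
    fullHeat <- -10 * molesPerInj * 1e9   # ucal if all of it binds
    for (n in c(0.7, 1.0)) {
        h <- simulateIsotherm(des, list(n = n, ka = 1e12, dh = -10))
        ratio <- cumsum(rep(molesPerInj, 25)) / (30e-6 * 2e-3)
        pre <- which(ratio < 0.9 * n)
        post <- which(ratio > 1.1 * n)
        # pre-step injections release the full molar heat, independent of n
        expect_equal(h[pre], rep(fullHeat, length(pre)),
                     tolerance = 5e-3 * abs(fullHeat))
        expect_true(all(abs(h[post]) < 0.01 * abs(fullHeat)))
    }
})

test_that("simulated cumulative heat approaches the total-enthalpy limit at saturation", {
    # strong syringe excess: essentially no unbound macromolecule is
    # displaced before the equivalence point, so the displaced-volume
    # corrected cumulative heat must conserve n*M0*V0*dH
    M0 <- 30e-6
    expect_total <- 1 * M0 * 2e-3 * (-10) * 1e9
    for (cval in c(5, 50, 500)) {
        des <- itcExperiment(cellConc = 30, syringeConc = 30000,
                             nInjections = 100, injectionVolume = 10)
        h <- simulateIsotherm(des, list(n = 1, ka = cval / M0, dh = -10))
        expect_lt(abs(sum(h) / expect_total - 1), 0.005)
    }
})

test_that("derived thermodynamics follow dG = -RT ln Ka and TdS = dH - dG", {
    expect_equal(thermodynamics(1, -10)$dg, 0)
    th0 <- thermodynamics(2e5, dh = -7.1)
    expect_equal(th0$tds, -7.1 - th0$dg)
    # Kd = 52.1 nM at 293.15 K
    th <- thermodynamics(1 / 52.1e-9, dh = -10, temperature = 293.15)
    expect_equal(th$dg, -1.9872e-3 * 293.15 * log(1 / 52.1e-9),
                 tolerance = 1e-12)
    expect_equal(th$dg, -9.8, tolerance = 0.05)
    expect_error(thermodynamics(-1, 0), "positive")
})

test_that("noiseless simulate-then-fit recovers parameters across a c-value grid", {
    M0 <- 30e-6
    for (cval in c(5, 50, 500)) {
        ka <- cval / M0
        des <- itcExperiment()
        heats(des) <- simulateIsotherm(des, list(n = 1, ka = ka, dh = -10,
                                                 qOffset = 0.15))
        fit <- fitSingleSite(des)
        expect_true(fit$converged)
        expect_lt(abs(fit$params$ka / ka - 1), 1e-3)
        expect_lt(abs(fit$params$n - 1), 1e-3)
        expect_lt(abs(fit$params$dh / -10 - 1), 1e-3)
        expect_lt(abs(fit$params$qOffset - 0.15), 1e-3)
        expect_equal(fit$kd, 1e9 / fit$params$ka)
    }
})

test_that("fits against noisy synthetic isotherms bracket the generating Kd", {
    kdTrue <- 52.1
    kds <- vapply(1:12, function(s) {
        run <- makeITC(params = bindingParams(1, 1e9 / kdTrue, -10),
                       seed = s)
        suppressWarnings(fitSingleSite(run))$kd
    }, numeric(1))
    expect_gt(max(kds), kdTrue)
    expect_lt(min(kds), kdTrue)
    expect_lt(abs(mean(kds) - kdTrue), 13.5)   # the reported uncertainty
})

test_that("flat heats are flagged as unidentifiable rather than fitted", {
    des <- itcExperiment()
    heats(des) <- rep(0, 25)
    expect_warning(fitSingleSite(des), "unidentifiable")
    fit <- suppressWarnings(fitSingleSite(des))
    expect_false(fit$converged)
    expect_equal(fit$params$dh, 0)
    expect_true(is.na(fit$kd))
})

test_that("a c-value outside the identifiable window triggers a warning", {
    des <- itcExperiment()
    heats(des) <- simulateIsotherm(des, list(n = 1, ka = 1e9 / 1.2,
                                             dh = -10))
    expect_warning(fitSingleSite(des), "c-value")
})

test_that("synthetic ITC runs are seeded and exact at zero noise", {
    p <- bindingParams(1, 1e9 / 100, -8)
    a <- makeITC(params = p, seed = 3)
    b <- makeITC(params = p, seed = 3)
    expect_identical(heats(a), heats(b))
    c0 <- makeITC(params = p, noiseSigma = 0, seed = 3)
    expect_equal(heats(c0), simulateIsotherm(itcExperiment(), p),
                 tolerance = 1e-12)
})

test_that("injection heats round-trip through the TSV format", {
    run <- makeITC(params = bindingParams(1, 1e9 / 60, -9), seed = 8)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeITCTSV(run, f)
    back <- readITCTSV(f, cellConc = 30, syringeConc = 300, cellVolume = 2)
    expect_equal(heats(back), heats(run), tolerance = 1e-9)
    fit1 <- suppressWarnings(fitSingleSite(run))
    fit2 <- suppressWarnings(fitSingleSite(back))
    expect_equal(fit1$kd, fit2$kd, tolerance = 1e-6)
})
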