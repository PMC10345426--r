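test_that("superposing a structure onto itself gives zero RMSD and identity", {
    set.seed(1)
    a <- randomPoints(8)
    k <- kabsch(a, a)
    expect_equal(k$rmsd, 0, tolerance = 1e-10)
    expect_equal(k$rotation, diag(3), tolerance = 1e-9)
})

test_that("a rigid motion is recovered exactly", {
    set.seed(2)
    a <- randomPoints(10)
    th <- pi / 2
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    b <- a %*% R + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
    k <- kabsch(a, b)
    expect_equal(k$rmsd, 0, tolerance = 1e-9)
    expect_equal(a %*% k$rotation +
                 matrix(k$translation, 10, 3, byrow = TRUE), b,
                 tolerance = 1e-9)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    expect_equal(t(k$rotation) %*% k$rotation, diag(3), tolerance = 1e-9)
})

test_that("the displaced-corner toy square matches the quaternion oracle", {
    a <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
    b <- a; b[3, ] <- b[3, ] + c(0, 0, 0.5)
    expect_equal(kabsch(a, b)$rmsd, quaternionRMSD(a, b), tolerance = 1e-9)
})

test_that("kabsch agrees with the quaternion oracle on random instances", {
    set.seed(42)
    for (i in 1:200) {
        n <- sample(4:10, 1)
        a <- randomPoints(n)
        b <- randomPoints(n)
        expect_equal(kabsch(a, b)$rmsd, quaternionRMSD(a, b),
                     tolerance = 1e-7)
    }
})

test_that("RMSD is invariant under a common rigid transform of both inputs", {
    set.seed(3)
    a <- randomPoints(9); b <- randomPoints(9)
    base <- kabsch(a, b)$rmsd
    for (i in 1:20) {
        q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
        R <- matrix(c(
            1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
            2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
            2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)),
            3, 3, byrow = TRUE)
        t3 <- matrix(stats::rnorm(3, sd = 10), 9, 3, byrow = TRUE)
        expect_equal(kabsch(a %*% R + t3, b %*% R + t3)$rmsd, base,
                     tolerance = 1e-7)
    }
})

test_that("degenerate and mismatched inputs are rejected", {
    set.seed(4)
    a <- randomPoints(5)
    expect_error(kabsch(a, a[1:4, ]), "shape")
    expect_error(kabsch(a[1:2, ], a[1:2, ]), "at least 3")
    line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
    expect_error(kabsch(line, line), "collinear")
})

test_that("region RMSD of a structure against itself is zero and the measure is symmetric", {
    ensA <- makeEnsemble(nResidues = 20, nModels = 5, sigma = 0.3, seed = 6)
    ensB <- makeEnsemble(nResidues = 20, nModels = 5, sigma = 0.3, seed = 7)
    corr <- data.frame(resA = 3:18, resB = 3:18)
    expect_equal(regionRMSD(ensA, ensA, corr), 0, tolerance = 1e-9)
    ab <- regionRMSD(ensA, ensB, corr)
    ba <- regionRMSD(ensB, ensA, corr[, 2:1])
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_gt(ab, 0)
})

test_that("cross-structure RMSD of jittered copies matches the closed-form expectation", {
    # two independent jitters of one template: squared atom distance is a
    # sum of 3 coordinate differences each with variance 2*sigma^2, so
    # RMSD -> sigma*sqrt(6) for many atoms (superposition shrinks it a bit)
    sigma <- 0.5
    rmsds <- vapply(1:40, function(s) {
        a <- makeEnsemble(nResidues = 40, nModels = 1, sigma = sigma,
                          seed = 2 * s)
        b <- makeEnsemble(nResidues = 40, nModels = 1, sigma = sigma,
                          seed = 2 * s + 1)
        regionRMSD(a, b, data.frame(1:40, 1:40), representative = 1)
    }, numeric(1))
    expect_lt(abs(mean(rmsds) - sigma * sqrt(6)), 0.1 * sigma * sqrt(6))
})

test_that("missing residues in a correspondence raise a coverage error", {
    ensA <- makeEnsemble(nResidues = 10, nModels = 2, sigma = 0.2, seed = 8)
    ensB <- makeEnsemble(nResidues = 8, nModels = 2, sigma = 0.2, seed = 9)
    expect_error(
        regionRMSD(ensA, ensB, data.frame(resA = 1:10, resB = c(1:8, 9, 10))),
        "B:9")
})

test_that("ensemble precision is zero for identical or rigidly rotated models", {
    ens <- makeEnsemble(nResidues = 10, nModels = 1, sigma = 0, seed = 1)
    base <- ens@coords[, , 1]
    th <- 1.1
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    coords <- array(NA_real_, c(nrow(base), 3, 2))
    coords[, , 1] <- base
    coords[, , 2] <- base %*% R + matrix(c(3, -1, 2), nrow(base), 3,
                                         byrow = TRUE)
    two <- new("StructureEnsemble", atoms = atomData(ens), coords = coords)
    p <- ensemblePrecision(two)
    expect_equal(p$mean, 0, tolerance = 1e-7)
    expect_equal(p$sd, 0, tolerance = 1e-7)
})

test_that("ensemble precision matches a direct Monte-Carlo expectation and is order-independent", {
    sigma <- 0.5
    ens <- makeEnsemble(nResidues = 30, nModels = 20, sigma = sigma,
                        seed = 10)
    p <- ensemblePrecision(ens)
    # direct expectation: per-atom distance to the mean of m jittered
    # copies has E[d^2] = 3*sigma^2*(m-1)/m before superposition shrinkage
    expected <- sigma * sqrt(3 * 19 / 20)
    expect_lt(abs(p$mean - expected) / expected, 0.1)
    expect_equal(p$mean, mean(p$perModel))
    expect_equal(p$sd, stats::sd(p$perModel))
    # shuffling model order must not change the converged result
    perm <- c(7, 1, 20, 3:6, 2, 8:19)
    shuf <- new("StructureEnsemble", atoms = atomData(ens),
                coords = ens@coords[, , perm])
    p2 <- ensemblePrecision(shuf)
    expect_equal(p2$mean, p$mean, tolerance = 1e-7)
})

test_that("precision is refused for single-model ensembles", {
    ens <- makeEnsemble(nResidues = 10, nModels = 1, sigma = 0.2, seed = 1)
    expect_error(ensemblePrecision(ens), "single-model")
})
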