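test_that("a single-model file reads as one model with its atoms intact", {
    m <- data.frame(name = c("N", "CA", "C"), resno = 1,
                    x = c(0, 1.458, 2.1), y = c(0, 0, 1.4), z = 0)
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(pdbText(list(m)), f)
    ens <- readEnsemble(f)
    expect_equal(nModels(ens), 1L)
    expect_equal(nrow(atomData(ens)), 3L)
    expect_equal(ens@coords[2, 1, 1], 1.458)
    expect_equal(atomData(ens)$atom, c("N", "CA", "C"))
})

test_that("generator ensembles survive a write/read round trip exactly at PDB precision", {
    ens <- makeEnsemble(nResidues = 12, nModels = 20, sigma = 0.4, seed = 5)
    f <- withr::local_tempfile(fileext = ".pdb")
    writeEnsemble(ens, f)
    back <- readEnsemble(f)
    expect_equal(nModels(back), 20L)
    expect_equal(atomData(back), atomData(ens))
    expect_equal(back@coords, round(ens@coords, 3), tolerance = 1e-12)
    # second round trip is bit-stable
    f2 <- withr::local_tempfile(fileext = ".pdb")
    writeEnsemble(back, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("inconsistent rosters across models are rejected with the offending atom named", {
    m1 <- data.frame(name = c("N", "CA", "C"), resno = 1,
                     x = 1:3, y = 0, z = 0)
    m2 <- m1[-2, ]
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(pdbText(list(m1, m2)), f)
    expect_error(readEnsemble(f), "roster.*CA", ignore.case = TRUE)
})

test_that("malformed ATOM records raise a parse error naming the line", {
    m <- data.frame(name = c("N", "CA", "C"), resno = 1, x = 1:3, y = 0, z = 0)
    txt <- pdbText(list(m))
    txt[2] <- paste0(substr(txt[2], 1, 30), "   BADNUM", substr(txt[2], 40, 80))
    f <- withr::local_tempfile(fileext = ".pdb")
    writeLines(txt, f)
    expect_error(readEnsemble(f), "line 2")
    expect_error(readEnsemble(tempfile()), "not found")
})

test_that("coordinate extraction is deterministic and permutation-stable", {
    ens <- makeEnsemble(nResidues = 7, nModels = 2, sigma = 0.1, seed = 2)
    sel <- atomSelection(resno = 5:7, atoms = "backbone")
    x <- extractCoordinates(ens, sel, model = 1)
    expect_equal(dim(x), c(12L, 3L))   # 4 backbone atoms x 3 residues
    expect_equal(rownames(x)[1:4], c("A:5:N", "A:5:CA", "A:5:C", "A:5:O"))
    # shuffle the atom records in the file: extraction must not change
    f <- withr::local_tempfile(fileext = ".pdb")
    writeEnsemble(ens, f)
    lines <- readLines(f)
    isAtom <- startsWith(lines, "ATOM")
    blocks <- split(which(isAtom), cumsum(!isAtom)[isAtom])
    set.seed(99)
    perm <- sample(seq_along(blocks[[1]]))  # same reordering in every model
    for (b in blocks) lines[b] <- lines[b[perm]]
    f2 <- withr::local_tempfile(fileext = ".pdb")
    writeLines(lines, f2)
    shuffled <- readEnsemble(f2)
    expect_equal(extractCoordinates(shuffled, sel, model = 1),
                 round(x, 3), tolerance = 1e-12)
})

test_that("the mean structure averages models and cancels symmetric displacements", {
    ens <- makeEnsemble(nResidues = 5, nModels = 1, sigma = 0, seed = 1)
    base <- ens@coords[, , 1]
    t3 <- matrix(c(1, -2, 0.5), nrow(base), 3, byrow = TRUE)
    coords <- array(NA_real_, c(nrow(base), 3, 2))
    coords[, , 1] <- base + t3
    coords[, , 2] <- base - t3
    two <- new("StructureEnsemble", atoms = atomData(ens), coords = coords)
    m <- extractCoordinates(two, atomSelection(), model = "mean")
    expect_equal(unname(m), unname(base), tolerance = 1e-12)
})

test_that("averaging many jittered models shrinks the deviation like sigma/sqrt(m)", {
    sigma <- 0.5; m <- 20
    ens <- makeEnsemble(nResidues = 30, nModels = m, sigma = sigma, seed = 11)
    tpl <- attr(ens, "template")
    avg <- apply(ens@coords, c(1, 2), mean)
    rmsPerCoord <- sqrt(mean((avg - tpl)^2))
    # independent expectation: sd of a mean of m iid normals
    expect_lt(abs(rmsPerCoord - sigma / sqrt(m)), 0.35 * sigma / sqrt(m))
})

test_that("selection errors are informative", {
    ens <- makeEnsemble(nResidues = 5, nModels = 2, sigma = 0.1, seed = 3)
    expect_error(extractCoordinates(ens, atomSelection(resno = 99)),
                 "no atoms")
    expect_error(extractCoordinates(ens, atomSelection(atoms = "ZZ")),
                 "unknown atom name")
    expect_error(extractCoordinates(ens, atomSelection(resno = 1,
                                                       atoms = "N")),
                 "at least 3")
})

test_that("the roster sequence exports as FASTA", {
    ens <- makeEnsemble(nResidues = 6, nModels = 1, sigma = 0, seed = 1)
    f <- withr::local_tempfile(fileext = ".fasta")
    writeRosterFASTA(ens, f, id = "chainA")
    seqs <- readFASTA(f)
    expect_equal(names(seqs), "chainA")
    expect_equal(unname(seqs), "AAAAAA")  # poly-alanine template
})
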