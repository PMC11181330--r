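# Synthetic toy systems, score fields and harmonic sampling.

test_that("toy chains are deterministic, virtually bonded at 3.8 A,
           and labelled by architecture", {
  t1 <- makeToyModel(30, "two_domain_linker", seed = 7)
  t2 <- makeToyModel(30, "two_domain_linker", seed = 7)
  expect_identical(caCoords(t1@model), caCoords(t2@model))
  expect_identical(paeValues(t1), paeValues(t2))

  x <- caCoords(t1@model)
  consec <- sqrt(rowSums((x[-1, ] - x[-30, ])^2))
  expect_true(all(abs(consec - 0.38) < 0.001))
  # self-avoidance
  d <- as.matrix(dist(x)); diag(d) <- Inf
  expect_gt(min(d), 0.035 * 10 / 10)  # 0.35 nm

  cls <- toyTruth(t1)$flexClass
  expect_setequal(unique(cls), c("rigid", "flexible"))
  # central linker flexible, domains rigid
  expect_true(all(cls[c(1:5, 26:30)] == "rigid"))
  expect_true(any(cls[13:18] == "flexible"))

  single <- makeToyModel(14, "single_domain", seed = 3)
  expect_true(all(toyTruth(single)$flexClass == "rigid"))
  expect_error(makeToyModel(4), "at least 6")
})

test_that("toy score fields are consistent with the ground truth", {
  toy <- makeToyModel(34, "two_domain_linker", seed = 10)
  tr <- toyTruth(toy)
  pl <- plddt(toy)
  expect_true(all(pl[tr$flexClass == "rigid"] > 90))
  expect_true(all(pl[tr$flexClass == "flexible"] < 90))
  # physical PAE channel: scaffold contacts carry their sigma
  sf <- tr$scaffold
  expect_equal(paeValues(toy)[cbind(sf$i, sf$j)], sf$sigma)
  expect_true(all(sf$sigma > 0.2 & sf$sigma < 1.85))
  # ground-truth network is rigid and exactly isostatic
  expect_equal(nrow(bonds(tr$network)), 3L * 34L - 6L)
})

test_that("regression-channel scores follow the generative relations
           with clipping", {
  sc <- makeSyntheticScores(1.0, matrix(0, 2, 2), noiseSd = 0)
  expect_equal(sc$plddt, 92.3)
  expect_equal(paeValues(sc$pae)[1, 2], 2.4)
  # clipping at the score bounds
  big <- makeSyntheticScores(c(20, 0), matrix(60, 2, 2), noiseSd = 0)
  expect_equal(big$plddt, c(0, 100))
  expect_true(all(paeValues(big$pae) <= 31.75))
  # determinism under seed
  a <- makeSyntheticScores(1:5, matrix(1, 5, 5), noiseSd = 2, seed = 9)
  b <- makeSyntheticScores(1:5, matrix(1, 5, 5), noiseSd = 2, seed = 9)
  expect_identical(a, b)
})

test_that("two-particle harmonic sampling reproduces the 1D oscillator
           statistics and closes the PAE/force-constant loop", {
  m <- proteinModel(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  k <- 400
  net <- afenm:::.newNetwork(data.frame(i = 1L, j = 2L, r0 = 0.5, k = k),
                             buildParams(), 2L)
  ens <- sampleHarmonicEnsemble(net, m, temperatureK = 310,
                                nFrames = 40000, seed = 2)
  s <- distanceStdMatrix(ens)[1, 2]
  pred <- sqrt(kBoltz * 310 / k) * 10
  mcse <- pred / sqrt(2 * 40000)
  expect_lt(abs(s - pred), 3 * mcse + 0.02 * pred)
  # feeding the measured std back as a PAE recovers k
  expect_equal(forceConstant(s, 310), k, tolerance = 0.05)

  # zero temperature: all frames at the reference structure
  cold <- sampleHarmonicEnsemble(net, m, temperatureK = 0,
                                 nFrames = 5, seed = 1)
  for (f in 1:5)
    expect_equal(cold@coords[f, , ], caCoords(m), tolerance = 1e-12)

  # determinism
  e1 <- sampleHarmonicEnsemble(net, m, nFrames = 10, seed = 3)
  e2 <- sampleHarmonicEnsemble(net, m, nFrames = 10, seed = 3)
  expect_identical(caCoords(e1), caCoords(e2))
})

test_that("floppy networks are refused with their disconnected parts
           named", {
  m <- proteinModel(matrix(rnorm(12), 4))
  net <- afenm:::.newNetwork(data.frame(i = 1L, j = 2L, r0 = 0.5, k = 100),
                             buildParams(), 4L)
  expect_error(sampleHarmonicEnsemble(net, m, nFrames = 2), "floppy")
  expect_error(sampleHarmonicEnsemble(net, m, nFrames = 2), "near-zero")
})

test_that("chain springs and containment supplement without duplicating
           bonds", {
  toy <- makeToyModel(28, "two_domain_linker", seed = 5)
  net <- buildAfEnm(toy@model, toy@pae)
  aug <- addChainSprings(net, toy@model)
  b <- bonds(aug)
  expect_false(any(duplicated(b[c("i", "j")])))
  # every consecutive pair present
  expect_true(all(paste(1:27, 2:28) %in% paste(b$i, b$j)))
  full <- addContainment(aug, toy@model)
  expect_equal(nrow(bonds(full)), 28 * 27 / 2)
  expect_false(any(duplicated(bonds(full)[c("i", "j")])))
})

test_that("network components split a multi-domain network into rigid,
           sampleable pieces", {
  toy <- makeToyModel(40, "two_domain_linker", seed = 2)
  net <- buildAfEnm(toy@model, toy@pae)
  comps <- networkComponents(net)
  expect_equal(length(comps), 2L)
  sizes <- sapply(comps, function(cm) length(cm$indices))
  expect_equal(sum(sizes), 34L)   # all but the 6 linker residues
  for (cm in comps) {
    expect_equal(nrow(bonds(cm$network)), 3L * length(cm$indices) - 6L)
    sub <- subsetModel(toy@model, cm$indices)
    ens <- sampleHarmonicEnsemble(cm$network, sub, nFrames = 5, seed = 1)
    expect_equal(nFrames(ens), 5L)
  }
})

test_that("a pLDDT-90 threshold on noisy regression-channel scores
           separates rigid from flexible residues", {
  for (s in 1:3) {
    toy <- makeToyModel(40, "two_domain_linker", seed = 60 + s)
    tr <- toyTruth(toy)
    sc <- makeSyntheticScores(tr$sigmaDn, tr$sigmaPair, noiseSd = 2,
                              seed = 70 + s)
    rigid <- tr$flexClass == "rigid"
    sens <- mean(sc$plddt[rigid] > 90)
    spec <- mean(sc$plddt[!rigid] <= 90)
    expect_gt(sens, 0.8)
    expect_gt(spec, 0.8)
    # the flexibility truth itself separates at the 2 A line
    expect_true(all(tr$sigmaDn[!rigid] > 2))
    expect_true(all(tr$sigmaDn[rigid] < 2))
  }
})

test_that("toy fixtures written to disk read back like AlphaFold
           output", {
  toy <- makeToyModel(20, "single_domain", seed = 12)
  dir <- tempfile()
  paths <- writeToyFixtures(toy, dir, nFrames = 10)
  m <- readStructure(paths["model"])
  expect_equal(nResidues(m), 20L)
  expect_equal(plddt(m), plddt(toy), tolerance = 0.01)
  pae <- readPae(paths["pae"])
  expect_equal(paeValues(pae), paeValues(toy), tolerance = 1e-6)
  ens <- readEnsemble(paths["ensemble"])
  expect_equal(nFrames(ens), 10L)
  expect_equal(nResidues(ens), 20L)
})
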