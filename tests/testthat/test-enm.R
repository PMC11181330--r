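# Force-constant map and elastic network construction.

test_that("force constant follows kB*T/PAE^2 with its printed anchor
           values", {
  # 1.85 Angstrom at 310 K sits exactly at the published 75 threshold
  expect_equal(forceConstant(1.85, 310), 75.31, tolerance = 1e-3)
  expect_equal(round(forceConstant(1.85, 310)), 75)
  # hand evaluation at 1 Angstrom: 0.0083145*310 / 0.1^2
  expect_equal(forceConstant(1.0, 310), 257.7495, tolerance = 1e-6)
  # inverse-square scaling
  expect_equal(forceConstant(2, 310), forceConstant(1, 310) / 4)
  expect_error(forceConstant(0), "positive")
})

test_that("paeFromForceConstant is the exact inverse and is monotone", {
  expect_equal(paeFromForceConstant(75.31, 310), 1.85, tolerance = 1e-3)
  set.seed(1)
  p <- runif(100, 0.1, 30)
  expect_equal(paeFromForceConstant(forceConstant(p, 310), 310), p)
  k <- sort(runif(50, 1, 1e5))
  expect_true(all(diff(paeFromForceConstant(k, 310)) < 0))
  expect_error(paeFromForceConstant(-1), "positive")
})

test_that("standard ENM matches a brute-force all-pairs enumeration", {
  two <- proteinModel(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  net <- buildStandardEnm(two, minSeqSep = 1)
  expect_equal(nrow(bonds(net)), 1L)
  expect_equal(bonds(net)$r0, 0.5)
  expect_equal(bonds(net)$k, 500)
  expect_equal(nrow(bonds(buildStandardEnm(two, cutoffNm = 0.4,
                                           minSeqSep = 1))), 0L)

  set.seed(11)
  xyz <- matrix(rnorm(60, sd = 0.5), 20)
  m <- proteinModel(xyz)
  net <- buildStandardEnm(m)
  # independent O(N^2) oracle
  want <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= 0.9 && j - i >= 3)
      want <- rbind(want, data.frame(i = i, j = j, r0 = d, k = 500))
  }
  rownames(want) <- NULL
  expect_equal(bonds(net), want)
})

test_that("AF-ENM selection rules reproduce the hand-enumerated square
           fixture", {
  # all pLDDT 95, PAE(1,4) = 1.0: exactly one bond with k = kB*T/0.1^2
  net <- buildAfEnm(squareModel(), squarePae(1.0))
  b <- bonds(net)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$i, b$j), c(1L, 4L))
  expect_equal(b$r0, 0.5)
  expect_equal(b$k, 257.7495, tolerance = 1e-6)

  # strict pLDDT gate: 90 is not > 90
  net90 <- buildAfEnm(squareModel(plddt = c(95, 95, 95, 90)),
                      squarePae(1.0))
  expect_equal(nrow(bonds(net90)), 0L)
  # pLDDT 91 passes
  net91 <- buildAfEnm(squareModel(plddt = c(95, 95, 95, 91)),
                      squarePae(1.0))
  expect_equal(nrow(bonds(net91)), 1L)

  # strict k gate at the PAE threshold: 2.0 A -> k = 64.4 <= 75
  expect_equal(nrow(bonds(buildAfEnm(squareModel(), squarePae(2.0)))), 0L)
  # 1.84 A -> k = 76.1 > 75; 1.85 A -> 75.31 > 75 passes too
  expect_equal(nrow(bonds(buildAfEnm(squareModel(), squarePae(1.84)))), 1L)
  expect_equal(nrow(bonds(buildAfEnm(squareModel(), squarePae(1.85)))), 1L)
  # but 1.86 A -> 74.5 <= 75 fails
  expect_equal(nrow(bonds(buildAfEnm(squareModel(), squarePae(1.86)))), 0L)

  # af_const keeps the membership but assigns the generic constant
  netc <- buildAfEnm(squareModel(), squarePae(1.0),
                     buildParams(mode = "af_const"))
  expect_equal(bonds(netc)$k, 500)
  expect_equal(bonds(netc)[c("i", "j")], bonds(net)[c("i", "j")])

  expect_error(buildAfEnm(squareModel(), asymPae(5)), "4 residues")
})

test_that("bond count is monotone in the gates and af_scaled equals
           af_const membership at kMin = 0", {
  toy <- makeToyModel(30, "single_domain", seed = 5)
  count <- function(...) nrow(bonds(buildAfEnm(toy@model, toy@pae,
                                               buildParams(...))))
  expect_true(count(plddtMin = 80) >= count(plddtMin = 90))
  expect_true(count(kMin = 10) >= count(kMin = 75))
  expect_true(count(cutoffNm = 1.2) >= count(cutoffNm = 0.9))

  a <- bonds(buildAfEnm(toy@model, toy@pae,
                        buildParams(mode = "af_scaled", kMin = 1e-12)))
  b <- bonds(buildAfEnm(toy@model, toy@pae,
                        buildParams(mode = "af_const", kMin = 1e-12)))
  expect_equal(a[c("i", "j")], b[c("i", "j")])
})

test_that("the k > kMin filter is exactly the symmetrized-PAE threshold", {
  toy <- makeToyModel(20, "single_domain", seed = 9)
  pae <- asymPae(20, seed = 4)
  net <- buildAfEnm(toy@model, pae)
  thr <- paeFromForceConstant(75, 310)
  sym <- paeValues(symmetrizePae(pae))
  b <- bonds(net)
  # every selected bond is below the threshold...
  expect_true(all(sym[cbind(b$i, b$j)] < thr))
  # ...and relaxing only the k gate adds exactly the above-threshold pairs
  all_ <- bonds(buildAfEnm(toy@model, pae, buildParams(kMin = 1e-12)))
  dropped <- setdiff(paste(all_$i, all_$j), paste(b$i, b$j))
  if (length(dropped)) {
    ij <- do.call(rbind, lapply(strsplit(dropped, " "), as.integer))
    expect_true(all(sym[ij] >= thr))
  }
})

test_that("the network is invariant under rigid motion of the input", {
  toy <- makeToyModel(25, "single_domain", seed = 13)
  rot <- randomRotation(2)
  moved <- proteinModel(caCoords(toy@model) %*% t(rot) +
                          matrix(c(3, -1, 2), 25, 3, byrow = TRUE),
                        plddt = plddt(toy@model))
  n1 <- buildAfEnm(toy@model, toy@pae)
  n2 <- buildAfEnm(moved, toy@pae)
  expect_identical(bonds(n1)[c("i", "j")], bonds(n2)[c("i", "j")])
  expect_equal(bonds(n1)$r0, bonds(n2)$r0, tolerance = 1e-9)
})

test_that("inter-chain pairs are exempt from the separation rule", {
  xyz <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.1, 0.4, 0), c(0.48, 0.4, 0))
  m <- proteinModel(xyz, plddt = rep(95, 4), chain = c("A", "A", "B", "B"))
  v <- matrix(8, 4, 4); diag(v) <- 0
  v[1, 3] <- v[3, 1] <- 1.0   # |i-j| = 2 but across chains
  net <- buildAfEnm(m, paeMatrix(v))
  expect_equal(nrow(bonds(net)), 1L)
  expect_equal(c(bonds(net)$i, bonds(net)$j), c(1L, 3L))
})
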