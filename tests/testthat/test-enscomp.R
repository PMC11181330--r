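# PCA projection and Gaussian KL ensemble comparison.

# Ensemble varying along one known internal 3N direction (orthogonal
# to the rigid-body subspace, so superposition leaves it untouched).
axisEnsemble <- function(f = 60, n = 5, seed = 4) {
  set.seed(seed)
  base <- matrix(rnorm(n * 3), n)
  p <- sweep(base, 2, colMeans(base))
  rot <- cbind(as.vector(t(cbind(0, -p[, 3], p[, 2]))),
               as.vector(t(cbind(p[, 3], 0, -p[, 1]))),
               as.vector(t(cbind(-p[, 2], p[, 1], 0))))
  rigid <- cbind(kronecker(rep(1, n), diag(3)), rot)
  w <- rnorm(3 * n)
  w <- w - rigid %*% solve(crossprod(rigid), crossprod(rigid, w))
  w <- w / sqrt(sum(w^2))
  coords <- array(NA_real_, c(f, n, 3))
  amp <- rnorm(f, sd = 0.3)
  for (k in seq_len(f))
    coords[k, , ] <- base + matrix(w, n, 3, byrow = TRUE) * amp[k]
  list(ens = ensemble(coords), axis = as.vector(w))
}

test_that("PC1 aligns with a single known axis of variation", {
  ax <- axisEnsemble()
  basis <- fitPca(ax$ens)
  # coordinates flatten row-wise (x1 y1 z1 x2 ...): same as the axis
  expect_gt(abs(sum(basis@components[, 1] * ax$axis)), 0.999)
  expect_true(all(diff(basis@explainedVariance) <= 0))
})

test_that("eigen identities: projecting the reference reproduces the
           explained variances; mean projects to the origin", {
  ens <- randomEnsemble(f = 40, n = 5, spread = 0.1, seed = 6)
  basis <- fitPca(ens)
  cloud <- projectEnsemble(ens, basis)
  # population variance of scores equals the eigenvalue
  v1 <- mean(cloud[, 1]^2) - mean(cloud[, 1])^2
  v2 <- mean(cloud[, 2]^2) - mean(cloud[, 2])^2
  expect_equal(v1, basis@explainedVariance[1], tolerance = 1e-6)
  expect_equal(v2, basis@explainedVariance[2], tolerance = 1e-6)

  mens <- ensemble(array(basis@meanStructure,
                         c(1, nrow(basis@meanStructure), 3)))
  expect_equal(as.numeric(projectEnsemble(mens, basis)), c(0, 0),
               tolerance = 1e-9)
})

test_that("PCA equals a dense covariance eigendecomposition oracle", {
  ens <- randomEnsemble(f = 30, n = 5, spread = 0.08, seed = 9)
  basis <- fitPca(ens)
  # oracle: align with the same helper, then eigen() of the covariance
  al <- afenm:::alignToMean(ens)
  x <- t(sapply(1:30, function(k) as.vector(t(al$coords[k, , ]))))
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / 30, symmetric = TRUE)
  expect_equal(basis@explainedVariance, ev$values[1:2], tolerance = 1e-9)
  for (k in 1:2)
    expect_equal(abs(sum(basis@components[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-6)
})

test_that("projection is invariant under rigid motion of the candidate
           ensemble", {
  ens <- randomEnsemble(f = 25, n = 6, spread = 0.06, seed = 11)
  basis <- fitPca(ens)
  moved <- transformEnsemble(ens, randomRotation(5))
  c1 <- projectEnsemble(ens, basis)
  c2 <- projectEnsemble(moved, basis)
  expect_equal(c1, c2, tolerance = 1e-6)
})

test_that("Gaussian KL: zero on itself, exact on shifted unit
           Gaussians, asymmetric for unequal covariances,
           non-negative", {
  set.seed(13)
  p <- cbind(rnorm(2000), rnorm(2000))
  expect_equal(klGaussian(p, p), 0, tolerance = 1e-12)

  # exact shift of the same samples: identical fitted covariances S,
  # so KL reduces to the Mahalanobis term d' S^-1 d / 2 (about 0.5
  # for a unit shift of a standard-normal sample)
  q <- sweep(p, 2, c(1, 0), "+")
  S <- cov(p) * (nrow(p) - 1) / nrow(p)
  want <- 0.5 * drop(c(1, 0) %*% solve(S, c(1, 0)))
  expect_equal(klGaussian(p, q), want, tolerance = 1e-6)
  expect_equal(klGaussian(p, q), 0.5, tolerance = 0.05)

  w <- cbind(rnorm(1500, sd = 2), rnorm(1500, sd = 0.5))
  expect_gt(abs(klGaussian(p, w) - klGaussian(w, p)), 0.1)
  for (pair in list(list(p, w), list(w, p), list(q, w)))
    expect_gte(klGaussian(pair[[1]], pair[[2]]), 0)
})

test_that("closed-form KL agrees with numerical integration of the
           fitted densities", {
  set.seed(17)
  p <- cbind(rnorm(400, 1, 1.3), rnorm(400, -0.5, 0.8))
  q <- cbind(rnorm(400, 0, 1.0), rnorm(400, 0, 1.5))
  kl <- klGaussian(p, q)
  # integrate p*log(p/q) for the two moment-matched Gaussians on a grid
  mom <- function(m) list(mu = colMeans(m), s = cov(m) * (nrow(m) - 1) / nrow(m))
  mp <- mom(p); mq <- mom(q)
  dens <- function(x, y, mm) {
    si <- solve(mm$s)
    dx <- cbind(x - mm$mu[1], y - mm$mu[2])
    exp(-0.5 * rowSums((dx %*% si) * dx)) / (2 * pi * sqrt(det(mm$s)))
  }
  g <- seq(-8, 10, length.out = 220)
  gr <- expand.grid(x = g, y = g)
  fp <- dens(gr$x, gr$y, mp)
  fq <- dens(gr$x, gr$y, mq)
  h <- diff(g)[1]^2
  num <- sum(ifelse(fp > 0, fp * log(fp / fq), 0)) * h
  expect_equal(kl, num, tolerance = 1e-3)
})

test_that("compareEnsembles reports both directions and a near-zero
           divergence for statistically identical ensembles", {
  toy <- makeToyModel(16, "single_domain", seed = 4)
  tr <- toyTruth(toy)
  e1 <- sampleHarmonicEnsemble(tr$network, toy@model, nFrames = 800,
                               seed = 1)
  e2 <- sampleHarmonicEnsemble(tr$network, toy@model, nFrames = 800,
                               seed = 2)
  cmp <- compareEnsembles(e1, e2)
  expect_lt(cmp$kl, 0.05)
  expect_lt(cmp$klReverse, 0.05)
  expect_equal(dim(cmp$candidateCloud), c(800L, 2L))
})
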