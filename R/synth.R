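#' @include enm.R dynmetrics.R
NULL

## ---- toy chain geometry ----------------------------------------------

## Grow a compact self-avoiding C-alpha trace of `n` residues with
## 0.38 nm virtual bonds around `center`, starting from `start` moving
## along `dir0`. Directions blend chain persistence, attraction toward
## the center, and seeded noise; steps closer than 0.36 nm to any
## previous residue are rejected and redrawn. Returns an n x 3 matrix
## or NULL if growth stalls (caller retries with a fresh sub-seed).
.growGlobule <- function(n, center, start, dir0, prev = NULL,
                         attract = 1.8) {
  bond <- 0.38
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- start
  dir <- dir0 / sqrt(sum(dir0^2))
  for (i in seq_len(n - 1L)) {
    placed <- FALSE
    for (try in 1:300) {
      pull <- center - xyz[i, ]
      np <- sqrt(sum(pull^2))
      pull <- if (np > 1e-9) pull / np else c(0, 0, 0)
      cand <- 0.3 * dir + attract * min(np, 1) * pull +
        stats::rnorm(3, sd = 0.4)
      cand <- cand / sqrt(sum(cand^2))
      pos <- xyz[i, ] + bond * cand
      others <- rbind(xyz[seq_len(max(i - 1L, 0L)), , drop = FALSE], prev)
      ok <- is.null(others) || !nrow(others) ||
        min(sqrt(rowSums(sweep(others, 2, pos)^2))) >= 0.36
      if (ok) {
        xyz[i + 1L, ] <- pos
        dir <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  xyz
}

## Grow a zigzag linker of `n` residues from `start` toward `goal`.
## Every step bends sharply relative to the previous bond (cosine in
## [-0.3, 0.55]): a straight chain segment would leave the torsion
## about its axis unrestrained by any distance spring, producing a
## quasi-mechanism that harmonic sampling cannot handle.
.growLinker <- function(n, start, goal, prev, prevDir) {
  bond <- 0.38
  xyz <- matrix(NA_real_, n, 3)
  pos <- start
  dir <- prevDir / sqrt(sum(prevDir^2))
  for (i in seq_len(n)) {
    for (try in 1:500) {
      pull <- goal - pos
      pull <- pull / sqrt(sum(pull^2))
      cand <- pull + stats::rnorm(3, sd = 0.9)
      cand <- cand / sqrt(sum(cand^2))
      bend <- sum(cand * dir)
      p2 <- pos + bond * cand
      others <- rbind(prev, xyz[seq_len(max(i - 1L, 0L)), , drop = FALSE])
      if (bend <= 0.55 && bend >= -0.3 &&
          min(sqrt(rowSums(sweep(others, 2, p2)^2))) >= 0.36) {
        xyz[i, ] <- p2
        pos <- p2
        dir <- cand
        break
      }
      if (try == 500L) return(NULL)
    }
  }
  xyz
}

## ---- isostatic contact scaffold --------------------------------------

## Henneberg type-I construction over the vertex subset `verts`
## (global indices): seed the largest-area eligible triangle, then
## attach every remaining vertex by 3 bonds to already-placed
## vertices, each step choosing the vertex/anchor-triple whose tripod
## is best conditioned (largest |det| of the three unit directions —
## near-coplanar tripods create soft modes that leave the harmonic
## regime). All pairs respect |i - j| >= minSep and distance <=
## maxDist. Returns data.frame(i, j) with 3*|verts| - 6 rows, or NULL
## if the geometry does not admit the construction.
.hennebergScaffold <- function(verts, dmat, xyz, minSep = 3L,
                               maxDist = 0.88) {
  ok <- function(a, b) abs(a - b) >= minSep && dmat[a, b] <= maxDist
  if (length(verts) < 4L) return(NULL)
  tri <- NULL; bestArea <- -1
  for (a in verts) for (b in verts[verts > a]) {
    if (!ok(a, b)) next
    for (cc in verts[verts > b]) {
      if (!ok(a, cc) || !ok(b, cc)) next
      v1 <- xyz[b, ] - xyz[a, ]; v2 <- xyz[cc, ] - xyz[a, ]
      cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      ar <- sqrt(sum(cr^2))
      if (ar > bestArea) { bestArea <- ar; tri <- c(a, b, cc) }
    }
  }
  if (is.null(tri)) return(NULL)
  placed <- tri
  todo <- setdiff(verts, tri)
  edges <- data.frame(i = c(tri[1], tri[1], tri[2]),
                      j = c(tri[2], tri[3], tri[3]))
  tripodQ <- function(v, anch) {
    u <- vapply(anch, function(a) {
      d <- xyz[a, ] - xyz[v, ]; d / sqrt(sum(d^2))
    }, numeric(3))
    abs(det(u))
  }
  while (length(todo)) {
    bestv <- NULL; bestq <- -1; bestanch <- NULL
    for (v in todo) {
      anch <- placed[vapply(placed, function(p) ok(v, p), logical(1))]
      if (length(anch) < 3L) next
      combs <- utils::combn(anch, 3L)
      qs <- apply(combs, 2, function(a) tripodQ(v, a))
      qi <- which.max(qs)
      if (qs[qi] > bestq) { bestq <- qs[qi]; bestv <- v
                            bestanch <- combs[, qi] }
    }
    if (is.null(bestv)) return(NULL)
    edges <- rbind(edges, data.frame(i = pmin(bestv, bestanch),
                                     j = pmax(bestv, bestanch)))
    placed <- c(placed, bestv)
    todo <- setdiff(todo, bestv)
  }
  edges
}

## Smallest internal (non-rigid-body) eigenvalue of the unit-k
## scaffold Hessian — the conditioning score used to select among
## candidate domain geometries.
.scaffoldCondition <- function(xyz, edges) {
  d <- pairDistances(xyz)
  net <- .newNetwork(data.frame(i = edges$i, j = edges$j,
                                r0 = d[cbind(edges$i, edges$j)], k = 1),
                     buildParams(), nrow(xyz))
  ev <- eigen(.enmHessian(net, proteinModel(xyz)), symmetric = TRUE,
              only.values = TRUE)$values
  nz <- ev[ev > 1e-8 * max(ev)]
  if (length(ev) - length(nz) != 6L) return(-Inf)
  min(nz)
}

## Grow a domain globule several times and keep the realization whose
## isostatic scaffold is best conditioned (well-spread tripods give a
## stiff, near-harmonic network). Returns list(xyz, edges) with edges
## in local 1..n indices, or NULL.
.growDomain <- function(n, center, start, dir0, prev = NULL,
                        tries = 8L, dropFirst = FALSE, minCond = 0) {
  best <- NULL; bestl <- -Inf
  for (t in seq_len(tries)) {
    xyz <- .growGlobule(n + dropFirst, center, start, dir0, prev = prev)
    if (is.null(xyz)) next
    if (dropFirst) xyz <- xyz[-1L, , drop = FALSE]
    edges <- .hennebergScaffold(seq_len(n), pairDistances(xyz), xyz)
    if (is.null(edges)) next
    l <- .scaffoldCondition(xyz, edges)
    if (l > bestl) { bestl <- l; best <- list(xyz = xyz, edges = edges) }
  }
  if (bestl < minCond) return(NULL)
  best
}

## Six generically independent "hinge" bonds tying vertex block B to
## the rest (both already internally rigid): shortest eligible cross
## pairs with anchor diversity (each vertex used at most twice).
.hingeBonds <- function(blockB, others, dmat, minSep = 3L) {
  pairs <- expand.grid(a = others, b = blockB)
  pairs <- pairs[abs(pairs$a - pairs$b) >= minSep, ]
  if (nrow(pairs) < 6L) return(NULL)
  pairs$d <- dmat[cbind(pairs$a, pairs$b)]
  pairs <- pairs[order(pairs$d), ]
  used <- integer(0)
  sel <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    if (sum(used == a) < 2L && sum(used == b) < 2L) {
      sel[[length(sel) + 1L]] <- c(a, b)
      used <- c(used, a, b)
      if (length(sel) == 6L) break
    }
  }
  if (length(sel) < 6L) return(NULL)
  m <- do.call(rbind, sel)
  data.frame(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]))
}

## ---- ToySystem generator ---------------------------------------------

#' Generate a synthetic toy system with known ground truth
#'
#' Builds a self-avoiding C-alpha trace (0.38 nm virtual bonds) as
#' either one compact domain or two compact domains joined by a short
#' extended linker, and equips it with a fully known ground truth:
#'
#' * a "confident-contact scaffold" — an isostatic (Henneberg) set of
#'   3m - 6 contacts per m-residue domain, each assigned a
#'   ground-truth distance-fluctuation sigma (uniform 0.3-0.6
#'   Angstrom for rigid pairs, 2.5-3.5 for pairs touching the
#'   flexible linker or crossing domains). Isostatic scaffolds have no
#'   redundant constraints, so a harmonic ensemble generated from them
#'   reproduces each designated sigma exactly in the linear-response
#'   regime — redundant networks would shrink per-bond fluctuations
#'   below their nominal sqrt(kB*T/k). Among several growth
#'   realizations the best-conditioned scaffold (largest smallest
#'   internal Hessian eigenvalue) is kept, avoiding near-coplanar
#'   tripods whose soft modes leave the harmonic regime;
#' * a per-pair sigma_d matrix (scaffold sigmas; 0.6-1.2 Angstrom for
#'   other intra-domain pairs; 3-6 for linker/cross-domain pairs);
#' * per-residue flexibility classes (linker "flexible", domains
#'   "rigid");
#' * synthetic confidence scores consistent with the truth: pLDDT
#'   93-98 for rigid, 69-75 for flexible residues, and a physical
#'   PAE channel that equals the ground-truth sigma for scaffold
#'   contacts (the Gaussian distance-distribution semantics of the
#'   force-constant map) and is large (>= 5 Angstrom) everywhere else;
#' * the generating "truth network": domain scaffolds plus soft
#'   linker attachments and six hinge bonds, an isostatic, rigid,
#'   connected elastic network whose normal-mode ensemble realizes
#'   the ground truth.
#'
#' Everything is deterministic under `seed`.
#'
#' @param nResidues chain length (>= 6; >= 28 for the two-domain
#'   architecture).
#' @param architecture "single_domain" or "two_domain_linker".
#' @param seed integer seed.
#' @return a [ToySystem-class].
#' @export
makeToyModel <- function(nResidues,
                         architecture = c("single_domain",
                                          "two_domain_linker"),
                         seed = 1L) {
  architecture <- match.arg(architecture)
  if (nResidues < 6L) stop("need at least 6 residues")
  if (architecture == "two_domain_linker" && nResidues < 28L)
    stop("two_domain_linker needs at least 28 residues")
  for (attempt in 0:24) {
    toy <- withSeed(as.integer(seed) + 7919L * attempt,
                    .tryToy(nResidues, architecture, seed))
    if (!is.null(toy)) return(toy)
  }
  stop("could not realize a rigid toy geometry for this size/seed")
}

.tryToy <- function(n, architecture, seed) {
  if (architecture == "single_domain") {
    doms <- list(seq_len(n))
    linker <- integer(0)
    g <- .growDomain(n, center = c(0, 0, 0), start = c(0.5, 0, 0),
                     dir0 = c(0, 1, 0))
    if (is.null(g)) return(NULL)
    xyz <- g$xyz
    scaffold <- g$edges
  } else {
    nl <- if (n >= 36L) 6L else 4L
    n1 <- (n - nl) %/% 2L
    n2 <- n - nl - n1
    doms <- list(seq_len(n1), seq_len(n2) + n1 + nl)
    linker <- seq_len(nl) + n1
    c1 <- c(0, 0, 0)
    ## the two-domain toy is the substrate of quantitative harmonic
    ## recovery analyses: require well-conditioned domain scaffolds.
    ## Domains below ~15 residues rarely admit such scaffolds (few
    ## eligible contacts); there only rigidity is enforced.
    minCond1 <- if (n1 >= 15L) 0.025 else 5e-4
    minCond2 <- if (n2 >= 15L) 0.025 else 5e-4
    g1 <- .growDomain(n1, center = c1, start = c(0.5, 0, 0),
                      dir0 = c(0, 1, 0), minCond = minCond1)
    if (is.null(g1)) return(NULL)
    x1 <- g1$xyz
    ## second domain center ~1.4 nm away: surfaces touch, so the toy
    ## has genuine inter-domain contacts for a standard ENM to pin
    c2 <- c1 + c(1.4, 0.35, 0)
    xl <- .growLinker(nl, start = x1[n1, ], goal = c2 + c(0, 0.9, 0),
                      prev = x1, prevDir = x1[n1, ] - x1[n1 - 1L, ])
    if (is.null(xl)) return(NULL)
    ## grow one extra position seeded at the linker end, then drop it,
    ## so every consecutive pair keeps the 0.38 nm virtual bond
    g2 <- .growDomain(n2, center = c2, start = xl[nl, ],
                      dir0 = c(1, -0.3, 0),
                      prev = rbind(x1, xl[-nl, , drop = FALSE]),
                      dropFirst = TRUE, minCond = minCond2)
    if (is.null(g2)) return(NULL)
    xyz <- rbind(x1, xl, g2$xyz)
    off <- n1 + nl
    scaffold <- rbind(g1$edges,
                      data.frame(i = g2$edges$i + off,
                                 j = g2$edges$j + off))
  }
  dmat <- pairDistances(xyz)

  ## truth network: scaffold + linker attachments + hinge bonds
  extra <- NULL
  if (length(linker)) {
    placed <- doms[[1]]
    for (v in linker) {
      anch <- placed[abs(placed - v) >= 3L]
      if (length(anch) < 3L) return(NULL)
      anch <- anch[order(dmat[v, anch])][1:3]
      extra <- rbind(extra, data.frame(i = pmin(v, anch),
                                       j = pmax(v, anch)))
      placed <- c(placed, v)
    }
    hinge <- .hingeBonds(doms[[2]], c(doms[[1]], linker), dmat)
    if (is.null(hinge)) return(NULL)
    extra <- rbind(extra, hinge)
  }

  flexClass <- rep("rigid", n)
  flexClass[linker] <- "flexible"

  touchesFlex <- function(b)
    flexClass[b$i] == "flexible" | flexClass[b$j] == "flexible"
  crossDomain <- function(b) {
    dom <- integer(n)
    for (k in seq_along(doms)) dom[doms[[k]]] <- k
    dom[linker] <- 0L
    dom[b$i] != dom[b$j] | dom[b$i] == 0L | dom[b$j] == 0L
  }

  scaffold$sigma <- stats::runif(nrow(scaffold), 0.3, 0.6)
  allTruth <- scaffold
  if (!is.null(extra)) {
    extra$sigma <- stats::runif(nrow(extra), 2.5, 3.5)
    allTruth <- rbind(scaffold, extra)
  }

  ## per-pair ground-truth sigma_d (Angstrom)
  sigmaPair <- matrix(0, n, n)
  up <- which(upper.tri(sigmaPair), arr.ind = TRUE)
  soft <- flexClass[up[, 1]] == "flexible" | flexClass[up[, 2]] == "flexible" |
    crossDomain(data.frame(i = up[, 1], j = up[, 2]))
  vals <- ifelse(soft, stats::runif(nrow(up), 3, 6),
                 stats::runif(nrow(up), 0.6, 1.2))
  sigmaPair[up] <- vals
  sigmaPair[cbind(allTruth$i, allTruth$j)] <- allTruth$sigma
  sigmaPair <- sigmaPair + t(sigmaPair)

  ## physical PAE channel: scaffold contacts carry their sigma, the
  ## rest is uncertain (large PAE) so only designated contacts bond
  pae <- matrix(0, n, n)
  pvals <- ifelse(soft, stats::runif(nrow(up), 8, 20),
                  stats::runif(nrow(up), 5, 9))
  pae[up] <- pvals
  pae[cbind(scaffold$i, scaffold$j)] <- scaffold$sigma
  pae <- pae + t(pae)

  ## per-residue flexibility truth, consistent with the class labels
  ## (rigid cores fluctuate a few tenths of an Angstrom against their
  ## neighbourhood; disordered linkers several Angstrom)
  sigmaDn <- ifelse(flexClass == "rigid", stats::runif(n, 0.4, 0.9),
                    stats::runif(n, 2.8, 4.5))

  pl <- ifelse(flexClass == "rigid", stats::runif(n, 93, 98),
               stats::runif(n, 69, 75))

  model <- proteinModel(xyz, plddt = pl)
  net <- .newNetwork(
    data.frame(i = allTruth$i, j = allTruth$j,
               r0 = dmat[cbind(allTruth$i, allTruth$j)],
               k = forceConstant(allTruth$sigma)),
    buildParams(), n)

  ## rigidity check: exactly 6 near-zero modes required
  ev <- eigen(.enmHessian(net, model), symmetric = TRUE,
              only.values = TRUE)$values
  if (sum(ev < 1e-8 * max(ev)) != 6L) return(NULL)

  new("ToySystem", model = model,
      pae = paeMatrix(pae, maxPae = max(31.75, max(pae))),
      truth = list(sigmaPair = sigmaPair, sigmaDn = sigmaDn,
                   flexClass = flexClass, scaffold = scaffold,
                   network = net, seed = as.integer(seed)))
}

## ---- synthetic score fields ------------------------------------------

#' Generate confidence scores from ground-truth fluctuations
#'
#' The regression channel of the generator: applies the pooled
#' score-dynamics relations with optional Gaussian noise,
#'
#'   pLDDT = clip(101.3 - 9 * sigma_d20 + e, 0, 100)
#'   PAE   = clip(2.4 + 0.7 * sigma_d + e', 0.01, 31.75)
#'
#' (slope -9 per Angstrom with median intercept 101.3 for pLDDT;
#' slope 0.7 with median intercept 2.4 Angstrom for PAE). Noise is
#' drawn independently per entry, so the generated PAE matrix is
#' non-symmetric for noiseSd > 0, like real output.
#'
#' @param sigmaDn per-residue sigma_d,20 truth in Angstrom.
#' @param sigmaD N x N per-pair sigma_d truth in Angstrom.
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param seed integer seed (NULL leaves the RNG stream alone).
#' @return list with `plddt` (numeric vector) and `pae`
#'   ([PaeMatrix-class]).
#' @export
makeSyntheticScores <- function(sigmaDn, sigmaD, noiseSd = 0, seed = NULL) {
  stopifnot(noiseSd >= 0)
  sigmaD <- as.matrix(sigmaD)
  withSeed(seed, {
    pl <- pmin(pmax(101.3 - 9 * sigmaDn +
                      stats::rnorm(length(sigmaDn), sd = noiseSd), 0), 100)
    pae <- pmin(pmax(2.4 + 0.7 * sigmaD +
                       matrix(stats::rnorm(length(sigmaD), sd = noiseSd),
                              nrow(sigmaD)), 0.01), 31.75)
    diag(pae) <- pmin(pmax(diag(sigmaD), 0.01), 31.75)
    list(plddt = pl, pae = paeMatrix(pae))
  })
}

## ---- harmonic (normal-mode) ensemble sampling ------------------------

## ANM-style 3N x 3N Hessian of an elastic network: per bond k along
## the unit vector of the reference geometry.
.enmHessian <- function(network, model) {
  xyz <- caCoords(model)
  n <- nrow(xyz)
  h <- matrix(0, 3L * n, 3L * n)
  b <- bonds(network)
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    u <- xyz[j, ] - xyz[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- b$k[r] * tcrossprod(u)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    h[ii, ii] <- h[ii, ii] + blk
    h[jj, jj] <- h[jj, jj] + blk
    h[ii, jj] <- h[ii, jj] - blk
    h[jj, ii] <- h[jj, ii] - blk
  }
  h
}

## Connected components of the bond graph (for error messages and for
## sampling multi-domain networks piecewise).
.componentsOf <- function(network) {
  n <- nResidues(network)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  b <- bonds(network)
  for (r in seq_len(nrow(b))) {
    pa <- find(b$i[r]); pb <- find(b$j[r])
    if (pa != pb) parent[max(pa, pb)] <- min(pa, pb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

#' Sample a harmonic ensemble from an elastic network
#'
#' Builds the 3N x 3N Hessian of the network (per-bond stiffness along
#' the reference bond direction), removes the six near-zero
#' rigid-body modes (eigenvalues below 1e-8 of the largest), and draws
#' frames from the Boltzmann Gaussian: independent mode amplitudes
#' with variance kB*T / lambda. This targets the exact equilibrium
#' distribution of the harmonic model — no integrator, fast, and
#' deterministic under `seed`.
#'
#' The network must hold all residues in one rigid body; a floppy or
#' disconnected network (more than 6 near-zero modes) is an error —
#' split it with [networkComponents()] and sample each rigid component,
#' or supplement it with [addChainSprings()] first.
#'
#' @param network an [ElasticNetwork-class].
#' @param model the [ProteinModel-class] providing the reference
#'   geometry (bond r0 values are taken from this geometry).
#' @param temperatureK temperature in K (default 310).
#' @param nFrames number of frames to draw.
#' @param seed integer seed.
#' @return an [Ensemble-class] of nFrames frames.
#' @export
sampleHarmonicEnsemble <- function(network, model, temperatureK = 310,
                                   nFrames = 1000L, seed = 1L) {
  stopifnot(is(network, "ElasticNetwork"), is(model, "ProteinModel"))
  if (nResidues(network) != nResidues(model))
    stop("network and model disagree on residue count")
  n <- nResidues(model)
  h <- .enmHessian(network, model)
  eig <- eigen(h, symmetric = TRUE)
  tol <- 1e-8 * max(eig$values, 0)
  zero <- eig$values < tol
  ## a single collinear pair has only 5 rigid modes; allow <= 6
  if (sum(zero) > 6L) {
    comp <- .componentsOf(network)
    stop(sprintf(paste0("floppy network: %d near-zero modes (> 6); ",
                        "connected parts: %s"),
                 sum(zero),
                 paste(vapply(comp, function(v)
                   sprintf("[%d..%d]x%d", min(v), max(v), length(v)),
                   character(1)), collapse = " ")))
  }
  keep <- which(!zero)
  lam <- eig$values[keep]
  v <- eig$vectors[, keep, drop = FALSE]
  amp <- sqrt(.kB * temperatureK / lam)
  x0 <- as.vector(t(caCoords(model)))
  withSeed(seed, {
    z <- matrix(stats::rnorm(nFrames * length(lam)), nFrames)
    disp <- z %*% (t(v) * amp)  # frames x 3N
    coords <- array(NA_real_, c(nFrames, n, 3))
    for (f in seq_len(nFrames))
      coords[f, , ] <- matrix(x0 + disp[f, ], ncol = 3, byrow = TRUE)
    ensemble(coords)
  })
}

#' Supplement a network with backbone chain springs
#'
#' Adds stiff i,i+1 bonds and softer i,i+2 bonds along each chain
#' (skipping pairs the network already has), standing in for the
#' bonded and angle terms of a coarse-grained force field — the terms
#' the AF-ENM deliberately leaves out by its sequence-separation rule.
#' Use before [sampleHarmonicEnsemble()] when the elastic network
#' alone does not hold the chain together (e.g. an AF-ENM whose
#' low-confidence linker carries no bonds).
#'
#' @param network an [ElasticNetwork-class].
#' @param model the matching [ProteinModel-class].
#' @param kBond force constant for i,i+1 springs (default 8000
#'   kJ/(mol nm^2), bonded-term stiffness scale).
#' @param kAngle force constant for i,i+2 springs (default 100,
#'   a soft angle-term proxy).
#' @param kDihedral force constant for i,i+3 springs (default 20, a
#'   very soft dihedral-term proxy that removes free torsions while
#'   barely restraining large-scale motion).
#' @return a new [ElasticNetwork-class] including the chain springs.
#' @export
addChainSprings <- function(network, model, kBond = 8000, kAngle = 100,
                            kDihedral = 20) {
  stopifnot(is(network, "ElasticNetwork"), is(model, "ProteinModel"))
  n <- nResidues(model)
  ch <- chainIds(model)
  d <- pairDistances(caCoords(model))
  b <- bonds(network)
  have <- paste(b$i, b$j)
  add <- list()
  for (sep in 1:3) {
    k <- c(kBond, kAngle, kDihedral)[sep]
    i <- seq_len(n - sep)
    j <- i + sep
    okc <- ch[i] == ch[j] & !(paste(i, j) %in% have)
    if (any(okc))
      add[[length(add) + 1L]] <- data.frame(i = i[okc], j = j[okc],
                                            r0 = d[cbind(i[okc], j[okc])],
                                            k = k)
  }
  .newNetwork(rbind(b, do.call(rbind, add)), network@params, n)
}

#' Supplement a network with a weak global containment field
#'
#' Adds a very soft harmonic spring between every residue pair not
#' already bonded, anchored at the reference-structure distances. This
#' stands in for the mean effect of excluded volume and solvent
#' caging, which harmonic networks lack: without it, a quasi-mechanism
#' (e.g. domains twisting about a flexible linker) has near-zero
#' stiffness and its Gaussian fluctuation diverges, whereas in a real
#' simulation sterics bound such motion at the protein's own length
#' scale. The default 2.5 kJ/(mol nm^2) is the stiffness whose thermal
#' fluctuation at 310 K is about 1 nm — protein-scale dimensions.
#' Used by the ensemble-comparison experiments; do not add it when
#' checking quantitative per-bond fluctuation recovery, where any
#' redundant spring biases the along-bond statistics.
#'
#' @param network an [ElasticNetwork-class].
#' @param model the matching [ProteinModel-class].
#' @param k containment force constant in kJ/(mol nm^2) (default 2.5).
#' @return a new [ElasticNetwork-class] including the containment
#'   springs.
#' @export
addContainment <- function(network, model, k = 2.5) {
  stopifnot(is(network, "ElasticNetwork"), is(model, "ProteinModel"))
  n <- nResidues(model)
  d <- pairDistances(caCoords(model))
  b <- bonds(network)
  have <- paste(b$i, b$j)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- !(paste(idx[, 1], idx[, 2]) %in% have)
  add <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                    r0 = d[idx][keep], k = k)
  .newNetwork(rbind(b, add), network@params, n)
}

#' Split a network into its connected components
#'
#' @param network an [ElasticNetwork-class].
#' @param minVertices drop components smaller than this (default 2).
#' @return list of components, each a list with `indices` (original
#'   residue indices) and `network` (the induced sub-network,
#'   reindexed 1..m).
#' @export
networkComponents <- function(network, minVertices = 2L) {
  comp <- .componentsOf(network)
  comp <- comp[lengths(comp) >= minVertices]
  b <- bonds(network)
  lapply(unname(comp), function(v) {
    sel <- b$i %in% v & b$j %in% v
    sub <- b[sel, , drop = FALSE]
    sub$i <- match(sub$i, v)
    sub$j <- match(sub$j, v)
    list(indices = v,
         network = .newNetwork(sub, network@params, length(v)))
  })
}

#' Subset a ProteinModel by residue indices
#'
#' @param model a [ProteinModel-class].
#' @param indices residue indices to keep (in order).
#' @return a [ProteinModel-class] over the selected residues.
#' @export
subsetModel <- function(model, indices) {
  stopifnot(is(model, "ProteinModel"))
  proteinModel(caCoords(model)[indices, , drop = FALSE],
               plddt = plddt(model)[indices],
               chain = chainIds(model)[indices],
               resno = model@resno[indices])
}

## ---- fixture writers --------------------------------------------------

#' Write a ProteinModel as a pLDDT-bearing PDB file
#'
#' C-alpha-only PDB with the pLDDT in the B-factor column, the
#' AlphaFold output convention, so [readStructure()] round-trips it.
#'
#' @param model a [ProteinModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeModelPdb <- function(model, path) {
  stopifnot(is(model, "ProteinModel"))
  n <- nResidues(model)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(caCoords(model))) * .ANG_PER_NM,
                   resno = model@resno, chain = model@chain,
                   resid = rep("ALA", n), elety = rep("CA", n),
                   b = round(plddt(model), 2))
  invisible(path)
}

#' Write an Ensemble as a multi-model PDB file
#'
#' @param ens an [Ensemble-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnsemblePdb <- function(ens, path) {
  stopifnot(is(ens, "Ensemble"))
  f <- nFrames(ens)
  n <- nResidues(ens)
  xyz <- t(vapply(seq_len(f),
                  function(k) as.vector(t(ens@coords[k, , ])) * .ANG_PER_NM,
                  numeric(3L * n)))
  bio3d::write.pdb(file = path, xyz = xyz, resno = seq_len(n),
                   chain = rep("A", n), resid = rep("ALA", n),
                   elety = rep("CA", n), b = rep(0, n))
  invisible(path)
}

#' Write a PaeMatrix as AlphaFold-style JSON
#'
#' @param pae a [PaeMatrix-class].
#' @param path output path.
#' @param dialect "afdb" (2D array) or "legacy" (flattened triples in
#'   a one-element list).
#' @return the path, invisibly.
#' @export
writePaeJson <- function(pae, path, dialect = c("afdb", "legacy")) {
  stopifnot(is(pae, "PaeMatrix"))
  dialect <- match.arg(dialect)
  v <- paeValues(pae)
  n <- nrow(v)
  obj <- if (dialect == "afdb")
    list(predicted_aligned_error = v,
         max_predicted_aligned_error = pae@maxPae)
  else
    list(list(residue1 = rep(seq_len(n), each = n),
              residue2 = rep(seq_len(n), times = n),
              distance = as.vector(t(v)),
              max_predicted_aligned_error = pae@maxPae))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a complete toy fixture set to a directory
#'
#' Emits the three files an AlphaFold run would produce for the toy —
#' `model.pdb` (pLDDT in B-factors), `pae.json` — plus a
#' `reference_ensemble.pdb` sampled from the ground-truth network, so
#' the whole pipeline can be exercised from disk like real output.
#'
#' @param toy a [ToySystem-class].
#' @param dir output directory (created if needed).
#' @param nFrames frames for the reference ensemble (default 200).
#' @param seed sampling seed (default: the toy's seed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeToyFixtures <- function(toy, dir, nFrames = 200L, seed = NULL) {
  stopifnot(is(toy, "ToySystem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- toy@truth$seed
  paths <- c(model = file.path(dir, "model.pdb"),
             pae = file.path(dir, "pae.json"),
             ensemble = file.path(dir, "reference_ensemble.pdb"))
  writeModelPdb(toy@model, paths["model"])
  writePaeJson(toy@pae, paths["pae"])
  ens <- sampleHarmonicEnsemble(toy@truth$network, toy@model,
                                nFrames = nFrames, seed = seed)
  writeEnsemblePdb(ens, paths["ensemble"])
  invisible(paths)
}
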