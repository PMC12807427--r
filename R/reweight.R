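#' Reweight boosted frames to canonical statistics
#'
#' Each frame of a boosted run is weighted so that averages over the weighted
#' ensemble recover the unboosted canonical ensemble. Two variants are
#' offered: exact exponential reweighting `w_i` proportional to
#' `exp(beta * deltaV_i)` (stabilized by subtracting the maximum exponent
#' before exponentiation), and the Maclaurin-series approximation
#' `w_i` proportional to `sum_{j=0}^{k} (beta * deltaV_i)^j / j!`, which is
#' less noise-amplifying when `beta * deltaV` is large. Weights are
#' normalized to sum to one.
#'
#' @param deltaV per-frame boost energies, kcal/mol, >= 0.
#' @param temperature Kelvin.
#' @param method `"exponential"` or `"maclaurin"`.
#' @param k Maclaurin truncation order (>= 1).
#' @return normalized weights summing to 1.
#' @export
reweightFrames <- function(deltaV, temperature = 300,
                           method = c("exponential", "maclaurin"), k = 10L) {
  method <- match.arg(method)
  if (any(deltaV < 0)) stop("deltaV must be non-negative")
  b <- thermoBeta(temperature) * deltaV
  if (method == "exponential") {
    w <- exp(b - max(b))
  } else {
    if (k < 1L) stop("Maclaurin order k must be >= 1")
    w <- rep(1, length(b))
    term <- rep(1, length(b))
    for (j in seq_len(k)) {
      term <- term * b / j
      w <- w + term
    }
  }
  w / sum(w)
}

.binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

.makeEdges <- function(x, breaks) {
  if (length(breaks) > 1L) return(sort(breaks))
  r <- range(x)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = breaks + 1L)
}

#' Free-energy surface from (weighted) samples
#'
#' Histograms 1D or 2D samples (toy positions or PCA projections) into
#' equal-width bins and converts the weighted occupancy to a free energy
#' `G = -kT ln(weight density)`, shifted so the occupied minimum is zero;
#' empty bins carry `Inf`. Samples falling outside explicit bin edges are
#' dropped with a warning.
#'
#' @param samples numeric vector (1D) or F x d matrix, d in 1:2.
#' @param weights per-frame weights (default uniform); normalized internally.
#' @param breaks per-dimension bin count, or a list of explicit edge vectors.
#' @param temperature Kelvin.
#' @return a [FreeEnergySurface-class].
#' @export
freeEnergySurface <- function(samples, weights = NULL, breaks = 50,
                              temperature = 300) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  d <- ncol(samples)
  if (!d %in% 1:2) stop("samples must be 1D or 2D")
  if (is.null(weights)) weights <- rep(1, nrow(samples))
  stopifnot(length(weights) == nrow(samples))
  weights <- weights / sum(weights)
  if (!is.list(breaks)) breaks <- rep(list(breaks), d)
  edges <- lapply(seq_len(d), function(j) {
    e <- .makeEdges(samples[, j], breaks[[j]])
    if (length(e) < 3L) stop("need at least 2 bins per dimension")
    e
  })
  idx <- vapply(seq_len(d), function(j) .binIndex(samples[, j], edges[[j]]),
                integer(nrow(samples)))
  idx <- matrix(idx, ncol = d)
  ok <- rowSums(is.na(idx)) == 0L
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) outside the bin edges were dropped")
    idx <- idx[ok, , drop = FALSE]
    weights <- weights[ok]
  }
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  flat <- idx[, 1]
  if (d == 2L) flat <- flat + (idx[, 2] - 1L) * nb[1]
  wsum <- array(0, dim = nb)
  cnt <- array(0L, dim = nb)
  ws <- vapply(split(weights, flat), sum, numeric(1))
  cs <- vapply(split(weights, flat), length, integer(1))
  pos <- as.integer(names(ws))
  wsum[pos] <- ws
  cnt[pos] <- cs
  occ <- wsum > 0
  if (sum(occ) < 2L)
    warning("degenerate free-energy surface: fewer than 2 occupied bins")
  G <- array(Inf, dim = nb)
  kT <- kBoltzmann * temperature
  G[occ] <- -kT * log(wsum[occ])
  G[occ] <- G[occ] - min(G[occ])
  new("FreeEnergySurface", edges = edges, G = G, counts = cnt,
      weightSums = wsum, temperature = temperature)
}

#' Bin centers of a free-energy surface
#'
#' @param fes a [FreeEnergySurface-class].
#' @return list of per-dimension bin-center vectors.
#' @export
fesBinCenters <- function(fes) {
  lapply(fes@edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

.regionBins <- function(fes, region) {
  centers <- fesBinCenters(fes)
  d <- length(centers)
  if (!is.list(region)) region <- list(region)
  stopifnot(length(region) == d)
  inside <- lapply(seq_len(d), function(j)
    centers[[j]] >= region[[j]][1] & centers[[j]] <= region[[j]][2])
  mask <- array(TRUE, dim = dim(fes@G))
  if (d == 1L) mask[] <- inside[[1]]
  else mask[] <- outer(inside[[1]], inside[[2]], "&")
  which(mask & is.finite(fes@G), arr.ind = d > 1L)
}

# Lowest level at which two bins connect through G <= level, by binary search
# over the sorted finite levels with 4-neighbour flood fill (2D).
.saddleLevel2D <- function(G, from, to) {
  levels <- sort(unique(G[is.finite(G)]))
  connects <- function(level) {
    open <- G <= level
    if (!open[from[1], from[2]] || !open[to[1], to[2]]) return(FALSE)
    seen <- array(FALSE, dim = dim(G))
    queue <- list(from)
    seen[from[1], from[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (all(cur == to)) return(TRUE)
      for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb <- cur + step
        if (any(nb < 1L) || nb[1] > nrow(G) || nb[2] > ncol(G)) next
        if (open[nb[1], nb[2]] && !seen[nb[1], nb[2]]) {
          seen[nb[1], nb[2]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    FALSE
  }
  lo <- 1L; hi <- length(levels)
  if (!connects(levels[hi])) return(Inf)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connects(levels[mid])) hi <- mid else lo <- mid + 1L
  }
  levels[lo]
}

#' Basin free-energy difference and barrier on a binned surface
#'
#' `deltaG = Gmin(basinB) - Gmin(basinA)`; the barrier is the minimax level
#' of the path between the two basin minima (in 1D the interval of bins
#' between them, in 2D the lowest-saddle level found by threshold
#' connectivity over 4-neighbour bin adjacency), minus `Gmin(basinA)`.
#' Swapping the basins flips the sign of `deltaG` and measures the barrier
#' from the other minimum.
#'
#' @param fes a [FreeEnergySurface-class].
#' @param basinA,basinB coordinate regions: `c(lo, hi)` in 1D, or a list of
#'   two such ranges in 2D. Must be disjoint and contain occupied bins.
#' @return list with `deltaG` and `barrier`, kcal/mol.
#' @export
basinBarrier <- function(fes, basinA, basinB) {
  d <- length(fes@edges)
  binsA <- .regionBins(fes, basinA)
  binsB <- .regionBins(fes, basinB)
  if (!length(binsA) || !length(binsB))
    stop("basin region contains no occupied bins")
  if (d == 1L) {
    gA <- min(fes@G[binsA]); iA <- binsA[which.min(fes@G[binsA])]
    gB <- min(fes@G[binsB]); iB <- binsB[which.min(fes@G[binsB])]
    path <- seq(min(iA, iB), max(iA, iB))
    barrier <- max(fes@G[path]) - gA
  } else {
    binsA <- matrix(binsA, ncol = 2L); binsB <- matrix(binsB, ncol = 2L)
    gAv <- fes@G[binsA]; gBv <- fes@G[binsB]
    gA <- min(gAv); gB <- min(gBv)
    iA <- binsA[which.min(gAv), ]; iB <- binsB[which.min(gBv), ]
    barrier <- .saddleLevel2D(fes@G, iA, iB) - gA
  }
  list(deltaG = gB - gA, barrier = barrier)
}
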