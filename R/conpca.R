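#' Covariance of native-contact distances
#'
#' Population covariance of the per-frame contact distances,
#' `sigma_ij = <(D_i - <D_i>)(D_j - <D_j>)>`, on the raw distances -- no
#' standardization and no switching-function transform, so a contact's
#' variance contribution scales with the square of its distance fluctuation
#' (set `correlation = TRUE` for the normalized variant).
#'
#' @param series a [ContactDistanceSeries-class] with at least 2 frames.
#' @param correlation use the correlation matrix instead of covariance
#'   (off by default).
#' @return a [CovarianceModel-class] of kind `"contact"`.
#' @export
contactCovariance <- function(series, correlation = FALSE) {
  stopifnot(is(series, "ContactDistanceSeries"))
  D <- series@distances
  if (nrow(D) < 2L) stop("need at least 2 frames")
  mu <- colMeans(D)
  Dc <- sweep(D, 2, mu)
  C <- crossprod(Dc) / nrow(D)
  if (correlation) {
    s <- sqrt(diag(C))
    s[s == 0] <- 1
    C <- C / tcrossprod(s)
  }
  new("CovarianceModel", center = mu, matrix = C, kind = "contact",
      selection = new("AtomSelection", indices = integer(), label = "contacts"),
      nFrames = nrow(D),
      meta = list(contacts = series@contacts, correlation = correlation))
}

#' Contact-PCA modes
#'
#' Eigen-decomposition of a contact-distance covariance, sharing the
#' eigensolver and sign convention of the Cartesian PCA. Eigenvector
#' components index contact pairs and weight each contact's participation in
#' the collective contact dynamics.
#'
#' @param cov a contact-kind [CovarianceModel-class] from
#'   [contactCovariance()].
#' @return a [PCAResult-class] of kind `"contact"`.
#' @export
conpcaModes <- function(cov) {
  stopifnot(is(cov, "CovarianceModel"), cov@kind == "contact")
  eigenDecompose(cov)
}

#' Rank contact-PCA components by absolute weight
#'
#' Orders the eigenvector components of one mode in descending order of
#' their absolute values (the contacts' weights), ties broken by native
#' contact order; signs are preserved so that blocks of contacts that form
#' or break simultaneously can be recognized by shared sign.
#'
#' @param modes a contact-kind [PCAResult-class].
#' @param mode mode index (default 1).
#' @return data.frame: `rank`, `resno`, `resname`, `nucleotide`, `nucName`,
#'   `component`, `absComponent`.
#' @export
rankComponents <- function(modes, mode = 1L) {
  stopifnot(is(modes, "PCAResult"), modes@kind == "contact")
  if (mode < 1L || mode > ncol(modes@eigenvectors)) stop("mode out of range")
  comp <- modes@eigenvectors[, mode]
  pairs <- modes@meta$contacts@pairs
  ord <- order(-abs(comp), seq_along(comp))
  out <- data.frame(rank = seq_along(comp),
                    resno = pairs$resno[ord], resname = pairs$resname[ord],
                    nucleotide = pairs$nucleotide[ord],
                    nucName = pairs$nucName[ord],
                    component = comp[ord], absComponent = abs(comp[ord]))
  rownames(out) <- NULL
  out
}

#' Do the top-k components of a mode share one sign?
#'
#' Contacts that form or break simultaneously carry same-signed components
#' on the mode describing that collective event.
#'
#' @param modes a contact-kind [PCAResult-class].
#' @param mode mode index.
#' @param k how many top-ranked components to test.
#' @return logical.
#' @export
signCoherent <- function(modes, mode = 1L, k = 6L) {
  rc <- rankComponents(modes, mode)
  k <- min(k, nrow(rc))
  s <- sign(rc$component[seq_len(k)])
  all(s == s[1])
}

#' Frames at the projection extremes of a contact-PCA mode
#'
#' Projects the distance series onto one mode
#' (`(distances - center) . eigenvector`) and returns the frames with the
#' most negative and most positive projections -- the representative
#' conformations discriminated by that mode. Ties resolve to the lowest
#' frame index.
#'
#' @param series the [ContactDistanceSeries-class] the modes came from.
#' @param modes a contact-kind [PCAResult-class].
#' @param mode mode index.
#' @return named integer vector `c(min = , max = )`; attribute
#'   `projections` carries the per-frame projection values.
#' @export
representativeFrames <- function(series, modes, mode = 1L) {
  stopifnot(is(series, "ContactDistanceSeries"), is(modes, "PCAResult"),
            modes@kind == "contact")
  if (!nrow(series@distances)) stop("empty distance series")
  proj <- as.vector(sweep(series@distances, 2, modes@center) %*%
                      modes@eigenvectors[, mode])
  out <- c(min = which.min(proj), max = which.max(proj))
  attr(out, "projections") <- proj
  out
}
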