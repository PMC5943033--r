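#' @importFrom stats dnorm rnorm rpois runif rbinom setNames qnorm pnorm
#'   density cor t.test aov chisq.test sd var
#' @importFrom Matrix bandSparse rowSums Diagonal
NULL

# Deterministic seed mixing: combines a root seed with integer indices into a
# derived seed < 2^31, via a multiplicative hash over a Mersenne prime.
# Published so that per-islet / per-table streams are reproducible in docs.

#' Derive a sub-seed from a root seed and integer indices
#'
#' Deterministic mixing used for per-stage / per-islet / per-replicate random
#' streams: `h = ((h * 48271) + k) mod (2^31 - 1)` folded over the root seed
#' and each index in turn (value returned is `h + 1` to avoid 0).
#'
#' @param root integer root seed.
#' @param ... further non-negative integer indices (stage index, islet
#'   index, replicate index, ...).
#' @return a single integer in `[1, 2^31 - 1]`.
#' @examples
#' deriveSeed(1, 2, 3)
#' @export
deriveSeed <- function(root, ...) {
  ks <- c(as.numeric(root), as.numeric(unlist(list(...))))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (k in ks) h <- (h * 48271 + (abs(k) %% m)) %% m
  as.integer(h %% (m - 1)) + 1L
}

# Evaluate fn under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# Separable 3D Gaussian blur. One banded sparse convolution matrix per axis
# (edge-renormalized so flat fields stay flat); kernel radius = ceil(3 sigma).
blur3d <- function(vol, sigmaVox) {
  if (sigmaVox <= 0) return(vol)
  r <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  k <- dnorm(seq(-r, r), sd = sigmaVox)
  k <- k / sum(k)
  d <- dim(vol)
  convAxis <- function(a, axis) {
    n <- dim(a)[axis]
    if (n == 1L) return(a)
    off <- seq(-r, r)
    off <- off[abs(off) < n]
    kk <- k[abs(seq(-r, r)) < n]
    K <- Matrix::bandSparse(n, n, k = off,
      diagonals = lapply(seq_along(off),
                         function(i) rep(kk[i], n - abs(off[i]))))
    K <- Matrix::Diagonal(x = 1 / Matrix::rowSums(K)) %*% K
    K <- methods::as(K, "CsparseMatrix")
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1L])
    out <- as.matrix(K %*% m)
    dim(out) <- dp
    aperm(out, order(perm))
  }
  for (axis in 1:3) vol <- convAxis(vol, axis)
  vol
}

# Otsu threshold of a numeric vector (maximizes between-class variance over a
# 256-bin histogram). Used for marker positivity and the fallback segmenter.
otsuThreshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("Otsu threshold undefined on constant values; use a fixed threshold")
  br <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[nbins]
  bcv <- (muT * w1 - mu1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

# Normal draws truncated to (lo, hi) by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
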