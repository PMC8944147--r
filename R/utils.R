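#' @useDynLib neutroquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# physical length in um -> pixels (not rounded; callers round as needed)
umToPx <- function(um, pixelSize) um / pixelSize

#' Rasterise a disc structuring element
#'
#' Builds a flat disc of the given pixel radius using the pixel-centre
#' coverage convention: a pixel belongs to the disc iff its centre lies
#' within `radius + 0.5` of the origin. Radius 3 therefore gives a 37-pixel
#' disc. Radius 0 gives the 1x1 identity element.
#'
#' @param radiusPx disc radius in pixels (>= 0, need not be integer)
#' @return 0/1 numeric matrix with odd dimensions
#' @export
makeDisc <- function(radiusPx) {
  stopifnot(is.numeric(radiusPx), length(radiusPx) == 1L, radiusPx >= 0)
  r <- floor(radiusPx + 0.5)
  g <- expand.grid(x = -r:r, y = -r:r)
  m <- matrix(as.numeric(sqrt(g$x^2 + g$y^2) <= radiusPx + 0.5),
              2L * r + 1L, 2L * r + 1L)
  m
}

# evaluate code under a given RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a 32-bit hash of a serialised R object, as 8 hex digits.
# Used only as a config fingerprint for run manifests. Arithmetic is done
# in doubles with an explicit split multiply to stay exact mod 2^32.
fnvHash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    hi <- h %/% 65536
    h <- ((h %% 65536) * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# mean/max guard for empty vectors
meanOrNA <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
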