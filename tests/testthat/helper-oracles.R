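# Brute-force reference implementations used as independent oracles.
# Deliberately naive: plain loops over pixels, no shared code with the
# package internals they check.

# flat-disc structuring element by pixel-centre coverage
oracleDisc <- function(r) {
  rr <- floor(r + 0.5)
  g <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  g[sqrt(g$dx^2 + g$dy^2) <= r + 0.5, ]
}

# grayscale erosion/dilation/opening with a flat disc, by direct min/max
oracleErode <- function(img, r) {
  off <- oracleDisc(r)
  out <- img
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    xi <- i + off$dx; yj <- j + off$dy
    ok <- xi >= 1 & xi <= nr & yj >= 1 & yj <= nc
    out[i, j] <- min(img[cbind(xi[ok], yj[ok])])
  }
  out
}
oracleDilate <- function(img, r) -oracleErode(-img, r)
oracleOpening <- function(img, r) oracleDilate(oracleErode(img, r), r)

# connected components by breadth-first flood fill
oracleLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4) rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
         else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        q <- p + nbr[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# all-pairs minimum pixel distance scan between two labelled sets;
# returns the (a, b) pairs within `reach` (Chebyshev for 8-connectivity,
# Manhattan for 4)
oraclePairs <- function(labA, labB, reach = 1, connectivity = 8) {
  pairs <- NULL
  for (a in setdiff(unique(c(labA)), 0L)) {
    pa <- which(labA == a, arr.ind = TRUE)
    for (b in setdiff(unique(c(labB)), 0L)) {
      pb <- which(labB == b, arr.ind = TRUE)
      dmin <- Inf
      for (u in seq_len(nrow(pa))) {
        dx <- abs(pb[, 1] - pa[u, 1]); dy <- abs(pb[, 2] - pa[u, 2])
        d <- if (connectivity == 8) pmax(dx, dy) else dx + dy
        dmin <- min(dmin, d)
      }
      if (dmin <= reach) pairs <- rbind(pairs, c(a, b))
    }
  }
  pairs
}

# moment width of one labelled object, straight from its pixel list
oracleWidths <- function(lab, id) {
  p <- which(lab == id, arr.ind = TRUE)
  cv <- stats::cov(p) * (nrow(p) - 1) / nrow(p)  # population covariance
  ev <- sort(eigen(cv, symmetric = TRUE)$values)
  sqrt(12 * (pmax(ev, 0) + 1 / 12))
}

# classical two-way ANOVA sums of squares, written out longhand
oracleAnovaSS <- function(y, fA, fB) {
  fA <- as.factor(fA); fB <- as.factor(fB)
  gm <- mean(y)
  mA <- tapply(y, fA, mean); mB <- tapply(y, fB, mean)
  mAB <- tapply(y, interaction(fA, fB), mean)
  nA <- table(fA); nB <- table(fB); nAB <- table(interaction(fA, fB))
  ssA <- sum(nA * (mA - gm)^2)
  ssB <- sum(nB * (mB - gm)^2)
  cellOf <- interaction(fA, fB)
  ssW <- sum((y - mAB[cellOf])^2)
  ssT <- sum((y - gm)^2)
  ssAB <- ssT - ssA - ssB - ssW
  c(A = ssA, B = ssB, AB = ssAB, resid = ssW, total = ssT)
}
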