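# Small programmatic fixtures shared across the suite.

# a bare multi-channel image with constant channels
flatImage <- function(markers = c("MPO", "S100A8"), shape = c(64, 64),
                      value = 0, pixelSize = 1) {
  chans <- lapply(markers, function(m) matrix(value, shape[1], shape[2]))
  names(chans) <- markers
  MultiChannelImage(chans, pixelSize = pixelSize)
}

# paint a hard-edged disc into a channel of an existing image
paintDisc <- function(image, marker, centre, radiusPx, value) {
  ch <- getChannel(image, marker)
  d2 <- outer((seq_len(nrow(ch)) - centre[1])^2,
              (seq_len(ncol(ch)) - centre[2])^2, "+")
  ch[d2 <= radiusPx^2] <- value
  chans <- lapply(channelNames(image), function(m)
    if (m == marker) ch else getChannel(image, m))
  names(chans) <- channelNames(image)
  MultiChannelImage(chans, pixelSize = pixelSize(image))
}

# LabeledObjects built directly from a logical matrix
labelsFrom <- function(mask, connectivity = 8, pixelSize = 1) {
  labelObjects(BinaryMask(mask, pixelSize = pixelSize),
               connectivity = connectivity)
}

# a noiseless scene spec (crisp signal, zero background) for geometry tests
noiselessScene <- function(..., seed = 1) {
  sceneSpec(..., noise = list(gaussianSd = 0, poissonScale = 0,
                              background = 0), seed = seed)
}

# horizontal tube spec of given diameter centred at row y0
hTube <- function(y0, d, x0 = 15, x1 = 115, lectinFactor = 1) {
  vesselSpec(rbind(c(x0, y0), c(x1, y0)), diameter = d,
             lectinFactor = lectinFactor)
}

# random logical mask with approximately the given foreground fraction
randomMask <- function(nr, nc, frac = 0.3) {
  matrix(stats::runif(nr * nc) < frac, nr, nc)
}
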