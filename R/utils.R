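# Small shared numerical helpers (circular track geometry, smoothing).

# circular three-point boxcar (weights 1/3) along a vector
boxcar3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  (x + x[c(n, seq_len(n - 1L))] + x[c(2:n, 1L)]) / 3
}

# apply boxcar3 to each row of a matrix
boxcar3Rows <- function(m) {
  n <- ncol(m)
  if (n < 3L) return(m)
  (m + m[, c(n, seq_len(n - 1L)), drop = FALSE] +
     m[, c(2:n, 1L), drop = FALSE]) / 3
}

# signed circular difference a - b on a track of length L, result in (-L/2, L/2]
circDiff <- function(a, b, L) {
  d <- (a - b) %% L
  d[d > L / 2] <- d[d > L / 2] - L
  d
}

# circular (wrap-aware) distance between positions on a track of length L
circDist <- function(a, b, L) abs(circDiff(a, b, L))

# 1-based spatial bin index of a position (half-open bins [k*w, (k+1)*w)).
# A 1e-9 cm guard absorbs accumulated floating-point error when frame
# positions fall exactly on bin boundaries (commensurate speeds).
positionToBin <- function(pos, beltLength = 180, nBins = 50L) {
  b <- floor((pos + 1e-9) / (beltLength / nBins)) + 1L
  pmin(pmax(b, 1L), nBins)
}

# rotate a vector so that element `from` lands at index `to` (circular)
rotateToBin <- function(x, from, to) {
  n <- length(x)
  shift <- (to - from) %% n
  if (shift == 0) return(x)
  x[((seq_len(n) - 1L - shift) %% n) + 1L]
}

# shift applied by rotateToBin, to translate raw bins into aligned bins
alignShiftFor <- function(from, to, nBins = 50L) as.integer((to - from) %% nBins)

applyBinShift <- function(bin, shift, nBins = 50L) {
  as.integer(((bin - 1L + shift) %% nBins) + 1L)
}

# fill NA entries of a circular vector by linear interpolation from the
# nearest non-NA circular neighbours
fillCircularNA <- function(x) {
  n <- length(x)
  idx <- which(is.na(x))
  if (!length(idx)) return(x)
  good <- which(!is.na(x))
  if (!length(good)) return(rep(0, n))
  for (i in idx) {
    dl <- (i - good) %% n   # distance to previous good point
    dr <- (good - i) %% n   # distance to next good point
    l <- good[which.min(dl)]
    r <- good[which.min(dr)]
    wl <- min(dl); wr <- min(dr)
    x[i] <- if (wl + wr == 0) x[l] else (wr * x[l] + wl * x[r]) / (wl + wr)
  }
  x
}

# adjusted Rand index between two partitions (integer label vectors)
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expn <- ai * bj / n2
  maxn <- (ai + bj) / 2
  if (maxn == expn) return(1)
  (nij - expn) / (maxn - expn)
}

# contiguous runs of TRUE in a logical vector: matrix with columns start, end
trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
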