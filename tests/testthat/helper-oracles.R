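# Scalar-loop brute-force oracles for the three losses. Deliberately
# unvectorized and independent of the package implementation.
bfKernel <- function(dy, sigma) exp(-dy^2 / (2 * sigma^2))

bfYaware <- function(f, ages, sigma) {
  f <- f / sqrt(rowSums(f^2))
  s <- tcrossprod(f); n <- nrow(f); v <- 0
  for (i in 1:n) for (k in 1:n) if (k != i) {
    den <- 0
    for (t in 1:n) if (t != i && t != k) den <- den + exp(s[i, t])
    v <- v - bfKernel(ages[i] - ages[k], sigma) * (s[i, k] - log(den))
  }
  v
}

bfExponential <- function(f, ages, sigma) {
  f <- f / sqrt(rowSums(f^2))
  s <- tcrossprod(f); n <- nrow(f); v <- 0
  for (i in 1:n) for (k in 1:n) if (k != i) {
    den <- 0
    for (t in 1:n) if (t != i && t != k)
      den <- den + exp(s[i, t] * (1 - bfKernel(ages[i] - ages[t], sigma)))
    v <- v - bfKernel(ages[i] - ages[k], sigma) * (s[i, k] - log(den))
  }
  v
}

# weightScale checks the ratio-invariance of the per-anchor normalization
bfAdaptive <- function(f, ages, sigma, nnSets, weightScale = 1) {
  f <- f / sqrt(rowSums(f^2))
  s <- tcrossprod(f); n <- nrow(f); v <- 0
  for (i in 1:n) {
    wsum <- 0
    for (t in 1:n) if (t != i)
      wsum <- wsum + weightScale * bfKernel(ages[i] - ages[t], sigma)
    for (k in 1:n) if (k != i) {
      tset <- setdiff(nnSets[[i]], c(i, k))
      if (length(tset) == 0) next
      den <- 0
      for (t in tset)
        den <- den + exp(s[i, t] * (1 - bfKernel(ages[i] - ages[t], sigma)))
      w <- weightScale * bfKernel(ages[i] - ages[k], sigma)
      v <- v - (w / wsum) * (s[i, k] - log(den))
    }
  }
  v
}
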