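# independent brute-force Kapur criterion: direct entropy loop over the
# 256-bin histogram, sharing no code with the package implementation
kapur_bruteforce <- function(img) {
  bins <- pmin(floor(unclass(img) * 256), 255)
  h <- tabulate(as.vector(bins) + 1L, nbins = 256)
  p <- h / sum(h)
  best_t <- NA; best_psi <- -Inf
  for (t in 0:254) {
    P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    H0 <- 0; H1 <- 0
    for (i in 0:255) {
      if (p[i + 1] == 0) next
      if (i <= t) H0 <- H0 - (p[i + 1] / P0) * log(p[i + 1] / P0)
      else H1 <- H1 - (p[i + 1] / P1) * log(p[i + 1] / P1)
    }
    if (H0 + H1 > best_psi) { best_psi <- H0 + H1; best_t <- t }
  }
  best_t
}
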