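# shared helpers: small random rasters built in code

rand_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

rand_image <- function(h, w, max_val = 255) {
  array(sample(0:max_val, h * w * 3, replace = TRUE), c(h, w, 3))
}

# exhaustive-search Otsu oracle: independent of the implementation's
# cumulative-sum formulation
otsu_brute <- function(channel) {
  q <- as.integer(floor(channel * 255 + 0.5))
  n <- length(q)
  best_t <- 0L; best_v <- -Inf
  for (t in 0:254) {
    n0 <- sum(q <= t); n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- mean(q[q <= t]); mu1 <- mean(q[q > t])
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# tiny smear set reused by training tests
tiny_smears <- function(n, size = 32, seed0 = 100) {
  lapply(seq_len(n), function(i)
    make_smear(smear_params(image_size = size, n_rbc = 3,
                            nucleus_radius_range = c(6, 9),
                            seed = seed0 + i)))
}
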