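# Shared fixtures and independent oracles used across test files.

options(nmrflex.verbose = FALSE)

# the acquisition field-strength grid without repeats (Hz)
nu_grid12 <- c(33.3, 66.7, 100.0, 133.3, 166.7, 200.0, 266.7, 333.3, 466.7,
               600.0, 733.3, 933.3)

# brute-force optimal-superposition RMSD, independent of the Kabsch path:
# multi-start optimisation over Euler angles of the centred coordinates
brute_superpose_rmsd <- function(a, b, n_starts = 150) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  obj <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((ac %*% (rz %*% ry %*% rx) - bc)^2)))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    o <- optim(runif(3, -pi, pi), obj)
    best <- min(best, o$value)
  }
  best
}

# a random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# noiseless dispersion profile tibble for a parameter set
make_profile <- function(params, nus = nu_grid12, t_relax = 0.030,
                         sigma = 0.05) {
  tibble::tibble(
    nu_cpmg_hz = nus,
    r2eff = simulate_r2eff_exact(params, nus, t_relax),
    sigma = sigma
  )
}
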