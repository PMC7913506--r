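# Independent single-purpose Monte Carlo oracle, written against the same
# physics but with a different algorithmic formulation (vectorized over
# photons, R RNG, boundary handling by memoryless step resampling) so it
# shares no code path with the package's transport engine. Semi-infinite
# homogeneous medium, pencil beam, Henyey-Greenstein scattering, mismatched
# refractive boundary, Russian roulette. Returns total diffuse reflectance.

oracle_fresnel <- function(n_i, n_t, ca1) {
  r_normal <- ((n_i - n_t) / (n_i + n_t))^2
  sa1 <- sqrt(pmax(0, 1 - ca1^2))
  sa2 <- n_i * sa1 / n_t
  tir <- sa2 >= 1
  sa2 <- pmin(sa2, 1)
  ca2 <- sqrt(pmax(0, 1 - sa2^2))
  cap <- ca1 * ca2 - sa1 * sa2
  cam <- ca1 * ca2 + sa1 * sa2
  sap <- sa1 * ca2 + ca1 * sa2
  sam <- sa1 * ca2 - ca1 * sa2
  R <- 0.5 * sam^2 * (cap^2 + cam^2) / (sap^2 * cam^2)
  R[tir] <- 1
  R[ca1 > 1 - 1e-9] <- r_normal
  pmin(pmax(R, 0), 1)
}

oracle_rd_semiinf <- function(mu_a, mu_s, g, n_rel, n_photons, seed,
                              w_threshold = 1e-4, p_survive = 0.1) {
  set.seed(seed)
  n <- as.integer(n_photons)
  rsp <- ((1 - n_rel) / (1 + n_rel))^2
  mu_t <- mu_a + mu_s
  albedo <- mu_s / mu_t
  z <- numeric(n)
  ux <- numeric(n); uy <- numeric(n); uz <- rep(1, n)
  w <- rep(1 - rsp, n)
  alive <- rep(TRUE, n)
  rd <- 0
  while (any(alive)) {
    i <- which(alive)
    s <- -log(runif(length(i))) / mu_t
    zn <- z[i] + uz[i] * s
    hit <- zn < 0
    if (any(hit)) {
      hi <- i[hit]
      R <- oracle_fresnel(n_rel, 1, abs(uz[hi]))
      refl <- runif(length(hi)) < R
      esc <- hi[!refl]
      rd <- rd + sum(w[esc])
      alive[esc] <- FALSE
      # internally reflected packets restart from the surface; the
      # exponential step is memoryless, so a fresh step next round is
      # statistically identical to continuing the interrupted one
      rb <- hi[refl]
      z[rb] <- 0
      uz[rb] <- -uz[rb]
    }
    j <- i[!hit]
    if (length(j) > 0) {
      z[j] <- zn[!hit]
      w[j] <- w[j] * albedo
      # roulette
      low <- j[w[j] < w_threshold]
      if (length(low) > 0) {
        die <- low[runif(length(low)) >= p_survive]
        alive[die] <- FALSE
        surv <- setdiff(low, die)
        w[surv] <- w[surv] / p_survive
      }
      j <- j[alive[j]]
      if (length(j) > 0) {
        # Henyey-Greenstein deflection
        u <- runif(length(j))
        if (g == 0) {
          ct <- 2 * u - 1
        } else {
          tt <- (1 - g^2) / (1 - g + 2 * g * u)
          ct <- pmin(pmax((1 + g^2 - tt^2) / (2 * g), -1), 1)
        }
        st <- sqrt(1 - ct^2)
        phi <- 2 * pi * runif(length(j))
        cp <- cos(phi); sp <- sin(phi)
        uzj <- uz[j]; uxj <- ux[j]; uyj <- uy[j]
        straight <- abs(uzj) > 0.99999
        tmp <- sqrt(pmax(1e-300, 1 - uzj^2))
        nx <- ifelse(straight, st * cp,
                     st * (uxj * uzj * cp - uyj * sp) / tmp + uxj * ct)
        ny <- ifelse(straight, st * sp,
                     st * (uyj * uzj * cp + uxj * sp) / tmp + uyj * ct)
        nz <- ifelse(straight, ct * sign(uzj), -st * cp * tmp + uzj * ct)
        ux[j] <- nx; uy[j] <- ny; uz[j] <- nz
      }
    }
  }
  rd / n
}
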