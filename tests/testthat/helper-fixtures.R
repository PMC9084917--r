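# shared fixture builders; everything is generated in code, seeded

# small feature matrix with a known linear map y = X beta + intercept + noise
toy_feature_matrix <- function(n, coefs, intercept = 0, noise_sd = 0, seed = 1,
                               x_scale = 1) {
  p <- length(coefs)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p) * x_scale
    y <- as.numeric(X %*% coefs) + intercept + rnorm(n, sd = noise_sd)
  })
  cols <- paste0("p", rep(1:9, length.out = p), "_t",
                 sprintf("%02d", seq_len(p)))
  tbl <- tibble::tibble(decoy_id = sprintf("d%04d", seq_len(n)),
                        target_ha_rmsd = y)
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(`colnames<-`(X, cols)))
  decoyrank:::new_feature_matrix(tbl)
}

# long score table for n positions x given terms, constant-free values
toy_score_long <- function(decoy_id, terms = c("atr", "rep", "sol"), seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      decoy_id = decoy_id,
      position = rep(1:9, each = length(terms)),
      term = rep(terms, 9),
      value = rnorm(9 * length(terms))
    )
  })
}

# brute-force RMSD between paired coordinate matrices
brute_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# independent exact Wilcoxon signed-rank p by full enumeration of the 2^n
# sign patterns of the observed (mid-)ranks
enumerate_signrank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# analytic accessible area of two intersecting probe-expanded spheres
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  cap_h <- function(ra, rb) ra - (d^2 + ra^2 - rb^2) / (2 * d)
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * cap_h(r1, r2)
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * cap_h(r2, r1)
  a1 + a2
}

# two-structure fixture: reference complex plus a decoy with one residue's
# peptide atoms displaced by a fixed vector
displace_residue <- function(st, resno, delta) {
  out <- st
  sel <- out$atoms$chain == out$peptide_chain & out$atoms$resno == resno
  out$atoms$x[sel] <- out$atoms$x[sel] + delta[1]
  out$atoms$y[sel] <- out$atoms$y[sel] + delta[2]
  out$atoms$z[sel] <- out$atoms$z[sel] + delta[3]
  out
}

rigid_motion <- function(st, angle = 0.7, axis = c(0, 0, 1), shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  out <- st
  xyz <- as.matrix(out$atoms[, c("x", "y", "z")]) %*% t(R)
  out$atoms$x <- xyz[, 1] + shift[1]
  out$atoms$y <- xyz[, 2] + shift[2]
  out$atoms$z <- xyz[, 3] + shift[3]
  out
}
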