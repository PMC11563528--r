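# Shared fixtures: small phantom grids and hand-built symmetric subjects.

asl_grid <- function(shape = c(16, 16, 8)) {
  volume_grid(shape, c(3, 3, 5.5), lr_axis = 1L, slice_gap_mm = 0.55)
}

# A tiny hand-built subject on an 8x6x4 grid: left-side infarct box with a
# known CBF, mirrored positions carrying the contralateral value, GM = 1
# everywhere. Returns volumes plus masks ready for percent_cbf_difference.
tiny_subject <- function(cbf_infarct = 20, cbf_contra = 25, background = 40) {
  g <- volume_grid(c(8, 6, 4), c(2, 2, 2))
  cbf <- array(background, g$shape)
  inf <- array(0, g$shape)
  inf[2:3, 2:5, 2:3] <- 1                  # 2*4*2 = 16 voxels, left half
  cbf[2:3, 2:5, 2:3] <- cbf_infarct
  cbf[6:7, 2:5, 2:3] <- cbf_contra         # mirror of indices 2:3 on extent 8
  list(grid = g,
       cbf = cbf,
       infarct = mask_volume(inf, g, "infarct"),
       hematoma = mask_volume(array(0, g$shape), g, "hematoma"),
       gm = mask_volume(array(1, g$shape), g, "gm"))
}

# Brute-force Mann-Whitney oracle: enumerate every assignment of nx labels
# to the pooled sample, two-sided p = 2 * min tail of the rank-sum, capped.
mw_enumeration_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(pooled), nx)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  eps <- 1e-9
  p_lo <- mean(ws <= w_obs + eps)
  p_hi <- mean(ws >= w_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

# Hypergeometric enumeration oracle for the two-sided Fisher test
# (probability-ordering rule), written from the definition with choose().
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  ps <- vapply(xs, prob, numeric(1))
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}
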