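# internal geometry / misc helpers

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalised", call. = FALSE)
  v / n
}

# largest-eigenvalue axis of the gyration tensor, sign fixed deterministically
# (first component of largest magnitude made positive)
principal_axis <- function(xyz) {
  if (nrow(xyz) < 3) stop("need >= 3 points for a principal axis", call. = FALSE)
  cc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1e-10) stop("degenerate (zero-length) principal axis", call. = FALSE)
  ax <- ev$vectors[, 1]
  k <- which.max(abs(ax))
  if (ax[k] < 0) ax <- -ax
  ax
}

# angle between two directions in degrees; axis semantics folds to [0, 90]
angle_deg <- function(a, b, fold = TRUE) {
  a <- unit_vec(a); b <- unit_vec(b)
  ct <- max(-1, min(1, sum(a * b)))
  ang <- acos(ct) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

# deterministic sub-seed derivation; stays below 2^31
derive_seed <- function(base, i) {
  ((as.numeric(base) %% 100000) * 20011 + as.numeric(i) * 7919) %% 2147483647
}
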