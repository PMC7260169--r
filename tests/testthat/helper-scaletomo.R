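# Shared fixture builders; everything is generated in code, seeded.

# small synthetic scale: truth + rendered greyscale
make_scale <- function(shape = c(48, 48, 160), seed = 1, ...) {
  cfg <- synthetic_scale_config(shape = shape, seed = seed, ...)
  truth <- generate_truth(cfg)
  list(cfg = cfg, truth = truth, grey = render_greyscale(truth, cfg))
}

# embed a rendered scale centrally in a constant-air box (the real scale
# sits in air inside the reconstructed cylinder)
embed_in_air <- function(grey, box_shape, air = 180L) {
  d <- dim(grey)
  at <- (box_shape - d) %/% 2L
  box <- array(air, box_shape)
  box[at[1] + seq_len(d[1]), at[2] + seq_len(d[2]), at[3] + seq_len(d[3])] <-
    grey$data
  grey_volume(box)
}

# smooth seeded volume on the 0-254 scale (continuous content, no sharp edges)
smooth_volume <- function(shape = c(48, 48, 96), seed = 8, sigma = 2) {
  set.seed(seed)
  f <- array(stats::rnorm(prod(shape)), shape)
  sm <- scaletomo:::gaussian_smooth_cpp(f, as.integer(shape), sigma, 4)
  sm <- (sm - min(sm)) / (max(sm) - min(sm)) * 254
  grey_volume(array(as.integer(round(sm)), shape))
}

# add independent rounded Gaussian noise to every scan of a scan_set,
# emulating separate acquisitions of the same object
perturb_scans <- function(ss, sd, seed = 99) {
  set.seed(seed)
  for (k in seq_along(ss$scans)) {
    dd <- ss$scans[[k]]$data
    dd <- array(as.integer(round(pmin(pmax(
      dd + stats::rnorm(length(dd), 0, sd), 0), 254))), dim(dd))
    ss$scans[[k]] <- grey_volume(dd)
  }
  ss
}

# reflect an index vector into 1..n (half-sample symmetric, multi-fold)
reflect1 <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  j <- (i - 1) %% (2 * n)
  j <- ifelse(j < 0, j + 2 * n, j)
  as.integer(ifelse(j < n, j, 2 * n - 1 - j) + 1)
}

# brute-force Gaussian-weighted local mean (explicit 3-D kernel sum,
# reflecting boundaries) -- independent oracle for the adaptive threshold
oracle_gaussian_mean <- function(v, sigma, voxels = NULL) {
  d <- dim(v)
  r <- as.integer(ceiling(4 * sigma))
  k1 <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k1 <- k1 / sum(k1)
  w3 <- outer(outer(k1, k1), k1)
  if (is.null(voxels))
    voxels <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  out <- numeric(nrow(voxels))
  for (i in seq_len(nrow(voxels))) {
    p <- voxels[i, ]
    xs <- reflect1(p[1] + (-r:r), d[1])
    ys <- reflect1(p[2] + (-r:r), d[2])
    zs <- reflect1(p[3] + (-r:r), d[3])
    out[i] <- sum(w3 * v[xs, ys, zs])
  }
  out
}

# literal non-local means (double precision, exact exp) on a tiny volume
oracle_nlm <- function(v, patch_radius, patch_distance, h, sigma) {
  d <- dim(v)
  pr <- patch_radius; pd <- patch_distance
  m <- pr + pd
  px <- reflect1(seq(1 - m, d[1] + m), d[1])
  py <- reflect1(seq(1 - m, d[2] + m), d[2])
  pz <- reflect1(seq(1 - m, d[3] + m), d[3])
  pad <- v[px, py, pz]
  np <- (2 * pr + 1)^3
  out <- array(0, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    p <- c(x, y, z) + m
    acc <- pad[p[1], p[2], p[3]]; wsum <- 1
    for (tz in -pd:pd) for (ty in -pd:pd) for (tx in -pd:pd) {
      if (tx == 0 && ty == 0 && tz == 0) next
      q <- p + c(tx, ty, tz)
      d2 <- sum((pad[(p[1]-pr):(p[1]+pr), (p[2]-pr):(p[2]+pr),
                     (p[3]-pr):(p[3]+pr)] -
                 pad[(q[1]-pr):(q[1]+pr), (q[2]-pr):(q[2]+pr),
                     (q[3]-pr):(q[3]+pr)])^2) / np
      e <- max(d2 - 2 * sigma^2, 0) / h^2
      w <- if (e > 25) 0 else exp(-e)
      acc <- acc + w * pad[q[1], q[2], q[3]]
      wsum <- wsum + w
    }
    out[x, y, z] <- acc / wsum
  }
  out
}
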