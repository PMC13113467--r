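# Shared fixtures and independent oracles used across the test files.

default_schema <- label_schema()

# Brute-force even-odd point-in-polygon test at pixel centres; independent
# of the scanline rasterizer.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(poly, H, W) {
  m <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      m[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, poly)
    }
  }
  m
}

# Dense convolution by explicit loops (the naive oracle for conv2d).
oracle_conv <- function(x, w, stride = 1, dil = 1) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  dw <- dim(w); Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  ph <- dil * (kh - 1) %/% 2; pw <- dil * (kw - 1) %/% 2
  Ho <- (H + 2 * ph - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pw - dil * (kw - 1) - 1) %/% stride + 1
  out <- array(0, c(Cout, Ho, Wo))
  for (co in seq_len(Cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    s <- 0
    for (ci in seq_len(C)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      hi <- (ho - 1) * stride + (ki - 1) * dil + 1 - ph
      wi <- (wo - 1) * stride + (kj - 1) * dil + 1 - pw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        s <- s + w[co, ci, ki, kj] * x[ci, hi, wi]
      }
    }
    out[co, ho, wo] <- s
  }
  out
}

# Side length of the bounding box of nonzero responses to a centred impulse.
impulse_support <- function(forward_fun, size) {
  x <- array(0, c(1L, size, size))
  x[1, size %/% 2, size %/% 2] <- 1
  y <- forward_fun(x)
  nz <- which(abs(y[1, , ]) > 1e-12, arr.ind = TRUE)
  max(diff(range(nz[, 1])), diff(range(nz[, 2]))) + 1L
}

# Dense softmax attention oracle on explicit neighbour lists.
oracle_masked_attention <- function(Q, K, V, neighbours, scale) {
  n <- nrow(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    js <- neighbours[[i]]
    lg <- as.numeric(Q[i, ] %*% t(K[js, , drop = FALSE])) * scale
    p <- exp(lg - max(lg)); p <- p / sum(p)
    out[i, ] <- as.numeric(p %*% V[js, , drop = FALSE])
  }
  out
}

# A tiny single-image training index written to disk, reused by pipeline
# tests.
make_phantom_index <- function(dir, n_patients, planes = "ACS", seed = 1,
                               images_per_patient = c(1, 1), size = 128) {
  generate_dataset(dir, n_patients = n_patients,
                   images_per_patient = images_per_patient,
                   planes = planes, seed = seed, size = size)
}
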