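# Independent oracles: literal, slow transcriptions of the method's formulas,
# kept free of the package's compiled path.

# scalar bilinear lookup, 1-based (x, y); NA outside the grid
bilerp <- function(A, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- if (fx > 1e-12) x0 + 1 else x0
  y1 <- if (fy > 1e-12) y0 + 1 else y0
  if (x0 < 1 || y0 < 1 || x1 > ncol(A) || y1 > nrow(A)) return(NA_real_)
  (1 - fy) * ((1 - fx) * A[y0, x0] + fx * A[y0, x1]) +
       fy  * ((1 - fx) * A[y1, x0] + fx * A[y1, x1])
}

# term-by-term weighted ZNCC over the whole image as calculation window:
# weights w(p + d) on both sides, means of the weighted values over
# contributing pixels, standard ZNCC quotient
zncc_oracle <- function(dr, drr, d, ic, sigma = Inf, valid = NULL,
                        min_valid = 16) {
  H <- nrow(dr); W <- ncol(dr)
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  ap <- c(); bp <- c()
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      if (!valid[y, x]) next
      a <- bilerp(drr, x + d[1], y + d[2])
      if (is.na(a)) next
      w <- if (is.finite(sigma)) {
        exp(-((ic[1] - x - d[1])^2 + (ic[2] - y - d[2])^2) / (2 * sigma^2))
      } else 1
      ap <- c(ap, a * w)
      bp <- c(bp, dr[y, x] * w)
    }
  }
  n <- length(ap)
  if (n < min_valid) return(NA_real_)
  am <- mean(ap); bm <- mean(bp)
  num <- sum((ap - am) * (bp - bm))
  den <- sqrt(sum((ap - am)^2) * sum((bp - bm)^2))
  if (den <= 1e-6) return(NA_real_)
  num / den
}

# exhaustive fractional-grid maximization of the oracle correlation
brute_best_match <- function(dr, drr, M, step, ic, sigma = Inf,
                             valid = NULL) {
  offs <- seq(-M, M, by = step)
  best <- NULL
  for (dy in offs) {
    for (dx in offs) {
      r <- zncc_oracle(dr, drr, c(dx, dy), ic, sigma, valid)
      if (is.na(r)) next
      better <- is.null(best) || r > best$R + 1e-12 ||
        (abs(r - best$R) <= 1e-12 &&
           dx^2 + dy^2 < best$dx^2 + best$dy^2 - 1e-12)
      if (better) best <- list(dx = dx, dy = dy, R = r)
    }
  }
  best
}

# literal couch-error equations: errors from view displacements in px
eq7_oracle <- function(m, dF, dL, dF_ref, dL_ref, sp) {
  e_lat  <- m[1] - (dF_ref[1] - dF[1]) * sp
  e_vert <- m[2] - (dL_ref[1] - dL[1]) * sp
  e_long <- m[3] - ((dF_ref[2] - dF[2]) + (dL_ref[2] - dL[2])) / 2 * sp
  c(e_lat, e_vert, e_long)
}

# translate image content by +v (bilinear, edge-replicated): B(p) = A(p - v)
shift_image <- function(A, vx, vy) {
  H <- nrow(A); W <- ncol(A)
  B <- matrix(NA_real_, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      sx <- min(max(x - vx, 1), W)
      sy <- min(max(y - vy, 1), H)
      B[y, x] <- bilerp(A, sx, sy)
    }
  }
  B
}

# small deterministic textured image with smooth blobs (good correlation peak)
blob_image <- function(S = 32, seed = 42) {
  set.seed(seed)
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  img <- 10000 + 2000 * y / S
  for (i in 1:4) {
    cx <- runif(1, 0.25, 0.75) * S; cy <- runif(1, 0.25, 0.75) * S
    r2 <- (runif(1, 0.08, 0.2) * S)^2
    img <- img + runif(1, 4000, 12000) * exp(-((x - cx)^2 + (y - cy)^2) / (2 * r2))
  }
  img
}

# a compact spec/config pair used across pipeline tests
tiny_spec <- function(...) {
  phantom_spec(size_px = 128, noise_sd = 200,
               collimation_px = c(12, 12, 8, 8), seed = 11, ...)
}

tiny_cfg <- function(...) {
  match_config(s = 128, M = 10, subpixel_step_px = 0.05, ...)
}
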