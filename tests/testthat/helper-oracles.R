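# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# Otsu by exhaustive search: 256-bin histogram, try every split, compute the
# weighted intra-class variance directly from the binned values.
oracle_otsu <- function(vals) {
  if (max(vals) == min(vals)) return(vals[1])
  bins <- pmin(floor(vals * 256), 255)
  centers <- (bins + 0.5) / 256
  best_obj <- Inf
  best_k <- NA
  for (k in 1:255) {
    lo <- centers[bins < k]
    hi <- centers[bins >= k]
    obj <- 0
    if (length(lo) > 0) obj <- obj + length(lo) / length(vals) * mean((lo - mean(lo))^2)
    if (length(hi) > 0) obj <- obj + length(hi) / length(vals) * mean((hi - mean(hi))^2)
    if (obj < best_obj) {  # strict improvement => ties keep the lowest k
      best_obj <- obj
      best_k <- k
    }
  }
  best_k / 256
}

# Flood-fill labeling: scan pixels in raster (row-major) order, BFS from each
# unlabeled foreground pixel.
oracle_flood_fill <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (r in 1:H) for (cc in 1:W) {
    if (mask[r, cc] && lab[r, cc] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, cc))
      lab[r, cc] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in nb) {
          rr <- p[1] + d[1]; ccc <- p[2] + d[2]
          if (rr >= 1 && rr <= H && ccc >= 1 && ccc <= W &&
              mask[rr, ccc] && lab[rr, ccc] == 0L) {
            lab[rr, ccc] <- nxt
            queue <- c(queue, list(c(rr, ccc)))
          }
        }
      }
    }
  }
  attr(lab, "n_objects") <- nxt
  lab
}

# Even-odd point-in-polygon, scalar.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Dense direct Gaussian convolution (full validity), zero padding with
# renormalization, for small frames.
oracle_gaussian <- function(img, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        wgt <- exp(-(di^2) / (2 * sigma^2)) * exp(-(dj^2) / (2 * sigma^2))
        num <- num + wgt * img[ii, jj]
        den <- den + wgt
      }
    }
    out[i, j] <- num / den
  }
  out
}

# Random unit-norm non-negative stain vector with at least two active channels
random_stain <- function(name) {
  repeat {
    v <- stats::runif(3)
    if (sum(v > 0.05) >= 2) return(stain_vector(name, v))
  }
}

random_noncollinear_pair <- function() {
  repeat {
    v1 <- random_stain("s1"); v2 <- random_stain("s2")
    if (abs(sum(v1$absorbance * v2$absorbance)) < 0.995) return(list(v1, v2))
  }
}

# A filled disk mask of given diameter centred at (cx, cy), pixel-center rule
disk_mask <- function(H, W, cx, cy, diameter) {
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  y <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  (x - cx)^2 + (y - cy)^2 <= (diameter / 2)^2
}
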