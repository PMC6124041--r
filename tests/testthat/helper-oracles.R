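# Independent oracles used by the tests. These deliberately avoid the
# package's C++ distance kernel and search code: pure-R brute force and
# closed-form geometry only.

# Closed-form collision-terminated angle for a sphere pair: rotating sphere B
# (radius r, pivot at mid-gap) contacts sphere A at
# phi* = acos(2 r^2 / (r + g/2)^2 - 1).
sphere_phi_star <- function(r, g) {
  acos(pmin(1, 2 * r^2 / (r + g / 2)^2 - 1)) * 180 / pi
}

# Brute-force sweep oracle on ideal (continuous) spheres: step the rotation
# of B's centre about the pivot and report the last angle before the
# centre-centre distance drops to 2 r. Independent of the closed form above.
sphere_sweep_oracle <- function(r, g, step_deg = 0.01) {
  pivot <- c(-(r + g / 2), 0, 0)
  cA <- c(0, 0, 0)
  cB <- c(-(2 * r + g), 0, 0)
  ang <- 0
  repeat {
    a <- (ang + step_deg) * pi / 180
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    p <- drop(R %*% (cB - pivot)) + pivot
    if (sqrt(sum((p - cA)^2)) <= 2 * r) return(ang)
    ang <- ang + step_deg
    if (ang > 180) return(NA_real_)
  }
}

# Vectorised point-to-triangle distances: all points in P (n x 3) against one
# triangle (a, b, c).
points_tri_dist <- function(P, a, b, c) {
  seg_d2 <- function(P, p, q) {
    d <- q - p
    len2 <- sum(d^2)
    t <- if (len2 > 0) pmin(1, pmax(0, ((P[, 1] - p[1]) * d[1] +
                                          (P[, 2] - p[2]) * d[2] +
                                          (P[, 3] - p[3]) * d[3]) / len2)) else 0
    dx <- P[, 1] - (p[1] + t * d[1])
    dy <- P[, 2] - (p[2] + t * d[2])
    dz <- P[, 3] - (p[3] + t * d[3])
    dx^2 + dy^2 + dz^2
  }
  ab <- b - a; ac <- c - a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  nn2 <- sum(n^2)
  dn <- (P[, 1] - a[1]) * n[1] + (P[, 2] - a[2]) * n[2] + (P[, 3] - a[3]) * n[3]
  # barycentric coordinates of the in-plane projection
  d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
  px <- P[, 1] - a[1] - dn * n[1] / nn2
  py <- P[, 2] - a[2] - dn * n[2] / nn2
  pz <- P[, 3] - a[3] - dn * n[3] / nn2
  d20 <- px * ab[1] + py * ab[2] + pz * ab[3]
  d21 <- px * ac[1] + py * ac[2] + pz * ac[3]
  denom <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / denom
  w <- (d00 * d21 - d01 * d20) / denom
  inside <- v >= 0 & w >= 0 & (v + w) <= 1
  d2 <- pmin(seg_d2(P, a, b), seg_d2(P, b, c), seg_d2(P, c, a))
  d2[inside] <- (dn[inside]^2) / nn2
  d2
}

# Exhaustive vertex-to-surface scan between two meshes (both directions).
# Upper-bounds the true surface distance; exact when the closest features
# include a vertex.
brute_mesh_dist <- function(ma, mb) {
  one_way <- function(P, m) {
    best <- rep(Inf, nrow(P))
    for (i in seq_len(nrow(m$faces))) {
      f <- m$faces[i, ]
      best <- pmin(best, points_tri_dist(P, m$vertices[f[1], ],
                                         m$vertices[f[2], ], m$vertices[f[3], ]))
    }
    min(best)
  }
  sqrt(min(one_way(ma$vertices, mb), one_way(mb$vertices, ma)))
}

merge_vertebra <- function(v) {
  neckROM:::merge_meshes(v$parts)
}

# Hand-computed Watson-Williams F via the explicit resultant formula,
# written out independently of the package implementation.
ww_hand <- function(deg_a, deg_b) {
  a <- deg_a * pi / 180; b <- deg_b * pi / 180
  Rlen <- function(x) sqrt(sum(cos(x))^2 + sum(sin(x))^2)
  Ra <- Rlen(a); Rb <- Rlen(b); Rp <- Rlen(c(a, b))
  N <- length(a) + length(b)
  rbar <- (Ra + Rb) / N
  kap <- if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6 else
    if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar) else
      1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  K <- 1 + 3 / (8 * kap)
  F <- K * (N - 2) * (Ra + Rb - Rp) / ((N - (Ra + Rb)))
  list(F = F, p = stats::pf(F, 1, N - 2, lower.tail = FALSE))
}

# Permutation oracle: null distribution of the absolute circular
# mean-direction difference under label exchange.
perm_mean_dir_p <- function(deg_a, deg_b, B = 2000L) {
  circ_mean <- function(deg) {
    r <- deg * pi / 180
    atan2(sum(sin(r)), sum(cos(r)))
  }
  ang_diff <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    min(d, 2 * pi - d)
  }
  obs <- ang_diff(circ_mean(deg_a), circ_mean(deg_b))
  pool <- c(deg_a, deg_b)
  na <- length(deg_a)
  hits <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(length(pool), na)
    d <- ang_diff(circ_mean(pool[idx]), circ_mean(pool[-idx]))
    if (d >= obs) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}
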