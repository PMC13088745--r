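# Independent oracles used across tests; deliberately naive.

# Exhaustive Otsu: try every cut of an 8-bit histogram, maximize
# between-class variance directly from class weights and means.
brute_force_otsu_8bit <- function(counts) {
  stopifnot(length(counts) == 256)
  levels <- 0:255
  n <- sum(counts)
  best <- -Inf
  best_cut <- NA_integer_
  for (t in 1:255) {                     # classes: levels < t vs >= t
    w0 <- sum(counts[1:t]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(levels[1:t] * counts[1:t]) / sum(counts[1:t])
    m1 <- sum(levels[(t + 1):256] * counts[(t + 1):256]) /
      sum(counts[(t + 1):256])
    sb2 <- w0 * w1 * (m0 - m1)^2
    if (sb2 > best) {
      best <- sb2
      best_cut <- t
    }
  }
  best_cut                               # threshold index: bins 1..t below
}

# Max pairwise distance over all boundary corner points of one label,
# by full enumeration (no hull).
brute_force_feret <- function(lab, id, pixel_size = 1) {
  px <- which(lab == id, arr.ind = TRUE)
  nr <- nrow(lab); nc <- ncol(lab)
  on_boundary <- apply(px, 1, function(rc) {
    r <- rc[1]; c <- rc[2]
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    any(nb[, 1] < 1 | nb[, 1] > nr | nb[, 2] < 1 | nb[, 2] > nc |
          lab[pmin(pmax(nb[, 1], 1), nr) +
                (pmin(pmax(nb[, 2], 1), nc) - 1) * nr] != id)
  })
  bp <- px[on_boundary, , drop = FALSE]
  pts <- unique(rbind(
    cbind(bp[, 2] - 0.5, -(bp[, 1] - 0.5)),
    cbind(bp[, 2] + 0.5, -(bp[, 1] - 0.5)),
    cbind(bp[, 2] - 0.5, -(bp[, 1] + 0.5)),
    cbind(bp[, 2] + 0.5, -(bp[, 1] + 0.5))))
  max(dist(pts)) * pixel_size
}

# Chebyshev gap between two labels, by exhaustive pixel-pair scan.
min_label_gap <- function(lab, id1, id2) {
  p1 <- which(lab == id1, arr.ind = TRUE)
  p2 <- which(lab == id2, arr.ind = TRUE)
  best <- Inf
  for (i in seq_len(nrow(p1))) {
    d <- pmax(abs(p2[, 1] - p1[i, 1]), abs(p2[, 2] - p1[i, 2]))
    best <- min(best, min(d))
  }
  best - 1                               # background pixels between them
}

# Hand KW H statistic from rank sums, with tie correction.
hand_kruskal_H <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  rk <- rank(v)
  N <- length(v)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(v)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# A small noise-free scene + measurement, shared by several tests.
tiny_scene <- function(width_um = 500, noise_sd = 0, blur_sigma = 0,
                       seed = 1, height = 300, ...) {
  generate_lumen_scene(scene_config(
    image_height_px = height, image_width_px = 320,
    pixel_size = 3.25, wall_left_x = 41, wall_right_x = 281,
    lumen_width_um = width_um, noise_sd = noise_sd,
    blur_sigma = blur_sigma, seed = seed, ...))
}
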