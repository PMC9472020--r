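# Independent oracles used across tests. These deliberately re-derive results
# by the most literal route available (loops, direct convolution, explicit
# running sums) and never call the code paths they check.

# Literal walk-down-the-list running sum for the enrichment score.
brute_force_es <- function(pi_sorted, is_hit, p = 1) {
  N <- length(pi_sorted)
  nh <- sum(is_hit)
  if (nh == 0 || nh == N) return(0)
  w <- abs(pi_sorted)^p
  nr <- sum(w[is_hit])
  if (nr == 0) { w <- rep(1, N); nr <- nh }
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (is_hit[i]) w[i] / nr else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Direct spatial convolution with a truncated Gaussian kernel (zero padding);
# valid away from the borders.
direct_gaussian_blur <- function(img, sigma, radius = ceiling(3 * sigma)) {
  off <- -radius:radius
  k <- outer(exp(-off^2 / (2 * sigma^2)), exp(-off^2 / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    da <- off[a]; db <- off[b]
    rs <- max(1, 1 - da):min(nr, nr - da)
    cs <- max(1, 1 - db):min(nc, nc - db)
    out[rs, cs] <- out[rs, cs] + k[a, b] * img[rs + da, cs + db]
  }
  out
}

# Brute-force nearest-centroid analysis regions: every pixel within Euclidean
# distance d of some nucleus pixel is assigned to the candidate nucleus
# (one whose own pixels are within d) with the nearest centroid, ties to the
# lower id. O(pixels x nuclei pixels); fine for tiny instances.
brute_force_regions <- function(lab, d) {
  nr <- nrow(lab); nc <- ncol(lab)
  n <- max(lab)
  pix <- lapply(seq_len(n), function(i) which(lab == i, arr.ind = TRUE))
  cen <- t(vapply(pix, colMeans, numeric(2)))
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (lab[r, cc] > 0L) { out[r, cc] <- lab[r, cc]; next }
    cand <- which(vapply(pix, function(p)
      min((p[, 1] - r)^2 + (p[, 2] - cc)^2) <= d^2, logical(1)))
    if (!length(cand)) next
    d2 <- (cen[cand, 1] - r)^2 + (cen[cand, 2] - cc)^2
    out[r, cc] <- cand[order(d2, cand)][1]
  }
  out
}

# A two-marker tissue-like scene used by the coexpression tests.
coexpr_scene <- function(noise_sd, seed, n_cells = 150) {
  tr <- random_image_truth(n_cells, radius_range = c(6, 9), min_gap = 7,
                           markers = list(GFP = 0.5, TxRed = 0.45),
                           noise_sd = noise_sd, seed = seed)
  generate_image_set(tr, seed = seed)
}

# Pooled per-cell double-positive confusion counts: planted cells are matched
# to segmented cells through their center pixel.
dp_confusion <- function(img, res) {
  lab <- res$seg$label_image
  centers <- round(img$truth$centers)
  seg_id <- lab[cbind(centers[, 1], centers[, 2])]
  truth_dp <- img$cells$GFP_positive & img$cells$TxRed_positive
  called_dp <- rep(FALSE, res$seg$n_cells)
  called_dp[res$calls$cell_id] <- res$calls$double_positive
  matched <- seg_id > 0L
  tp <- sum(truth_dp[matched] & called_dp[seg_id[matched]])
  c(tp = tp,
    truth_pos = sum(truth_dp),
    called_pos = sum(called_dp))
}
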