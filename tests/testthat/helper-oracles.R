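# shared fixtures and independent oracles

# render isolated Gaussian spots onto a pixel grid (amplitude 1)
render_spots <- function(xy_um, size_px, pixel_scale, sigma_um) {
  m <- matrix(0, size_px, size_px)
  sig <- sigma_um / pixel_scale
  for (i in seq_len(nrow(xy_um))) {
    cx <- xy_um[i, 1] / pixel_scale + 0.5
    cy <- xy_um[i, 2] / pixel_scale + 0.5
    gx <- exp(-((1:size_px) - cx)^2 / (2 * sig^2))
    gy <- exp(-((1:size_px) - cy)^2 / (2 * sig^2))
    m <- m + outer(gy, gx)
  }
  m
}

# greedy one-to-one matching of detections to ground truth within a radius
match_points <- function(gt, det, radius) {
  if (nrow(det) == 0 || nrow(gt) == 0)
    return(list(recall = 0, precision = 0))
  D <- outer(gt[, 1], det[, 1], "-")^2 + outer(gt[, 2], det[, 2], "-")^2
  used <- rep(FALSE, nrow(det))
  matched <- 0
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] < radius^2) {
      matched <- matched + 1
      used[j] <- TRUE
    }
  }
  list(recall = matched / nrow(gt), precision = matched / nrow(det))
}

# trapezoid rule written as an explicit loop, independent of aulcsf()
trapz_loop <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

# exhaustive expected-posterior-entropy stimulus selection, independent of
# the batched linear-algebra path in psi_select()
brute_select <- function(state) {
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  best <- Inf; best_c <- NA_real_
  for (cc in state$candidates) {
    p <- psychometric(cc, 10^state$grid$lt, state$grid$slope,
                      state$guess, state$lapse)
    pc <- sum(state$posterior * p)
    eh <- pc * ent(state$posterior * p / pc) +
      (1 - pc) * ent(state$posterior * (1 - p) / (1 - pc))
    if (eh < best - 1e-12) { best <- eh; best_c <- cc }
  }
  best_c
}
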