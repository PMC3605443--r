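# Independent brute-force oracles used to pin down expected values.

# AUC by exhaustive pair counting (ties count one half)
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# best cutoff by exhaustive enumeration of every midpoint; positivity is
# score > cutoff; ties resolved toward the lowest cutoff
brute_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)])
  best <- NULL
  for (ct in cand) {
    sens <- sum(scores > ct & labels) / sum(labels)
    spec <- sum(scores <= ct & !labels) / sum(!labels)
    if (is.null(best) || sens + spec > best$youden + 1e-12) {
      best <- list(cutoff = ct, sens = sens, spec = spec,
                   youden = sens + spec)
    }
  }
  best
}

# digital disk raster (pixel-centre inclusion)
disk_matrix <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- matrix(0, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- 255
  m
}

# a minimal flat-field RGB image
uniform_rgb <- function(h, w, rgb) {
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# noiseless signal parameters with no T1 weighting (flip 90, TR >> T1)
no_t1_params <- function(t2star = 20, ...) {
  mri_signal_params(flip_angle = 90, tr = 1e9, t2star = t2star, ...)
}
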