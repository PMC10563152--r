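# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# pixel-counting IoU
oracle_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1L
    if (a[i] || b[i]) uni <- uni + 1L
  }
  inter / uni
}

# covariance-form Pearson correlation
oracle_pcc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive-search Otsu: try every distinct level below the max as the
# threshold, classify by strict >, maximize between-class variance
oracle_otsu <- function(img) {
  v <- as.numeric(img)
  lev <- sort(unique(v))
  best_t <- NA_real_; best_bcv <- -Inf
  for (t in lev[-length(lev)]) {
    bg <- v[v <= t]; fg <- v[v > t]
    w0 <- length(bg) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  best_t
}

# window-scanning onset detector: first index (0-based) whose next
# min_run labels are all positive
oracle_onset <- function(labels, min_run = 3L) {
  n <- length(labels)
  for (i in seq_len(n - min_run + 1L)) {
    if (all(labels[i:(i + min_run - 1L)] == 1L))
      return(list(is_event = TRUE, onset_frame = i - 1L))
  }
  list(is_event = FALSE, onset_frame = NULL)
}

# dense scale-space LoG response at one pixel, by direct convolution sums
oracle_log_response <- function(img, r0, c0, sigma) {
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(4 * sigma)
  acc <- 0
  for (dr in -rad:rad) for (dc in -rad:rad) {
    rr <- min(max(r0 + dr, 1), h); cc <- min(max(c0 + dc, 1), w)
    r2 <- dr^2 + dc^2
    lognorm <- (r2 / sigma^2 - 2) / (2 * pi * sigma^4) *
      exp(-r2 / (2 * sigma^2))
    acc <- acc + img[rr, cc] * lognorm
  }
  sigma^2 * acc
}

# small random logical mask
random_mask <- function(h, w, p = 0.3) {
  matrix(stats::runif(h * w) < p, h, w)
}

# a disk painted on a flat background
disk_image <- function(h, w, center, r, bg = 50, fg = 200) {
  img <- matrix(bg, h, w)
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+")
  img[d2 <= r^2] <- fg
  img
}
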