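# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-pixel loops, recursive flood fill) so they cannot
# share a defect with the vectorised implementations they check.

rand_mask <- function(h = 16, w = 16, p = 0.3) {
  binary_mask(matrix(stats::runif(h * w) < p, h, w))
}

# random annotation with disjoint green/red sets
rand_annotation <- function(h = 16, w = 16, p_green = 0.15, p_red = 0.15) {
  u <- matrix(stats::runif(h * w), h, w)
  annotation_mask(u < p_green, u >= p_green & u < p_green + p_red)
}

mask_content_equal <- function(a, b) {
  isTRUE(all(dim(a) == dim(b))) && all(as.vector(a) == as.vector(b))
}

disk_mask <- function(r, cx = NULL, cy = NULL, pad = 5) {
  n <- 2 * ceiling(r) + 2 * pad + 1
  if (is.null(cx)) cx <- ceiling(r) + pad + 1
  if (is.null(cy)) cy <- cx
  binary_mask(outer(seq_len(n), seq_len(n),
                    function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2))
}

ellipse_mask <- function(a, b, theta = 0, pad = 6) {
  ext <- ceiling(max(a, b)) + pad
  n <- 2 * ext + 1
  c0 <- ext + 1
  binary_mask(outer(seq_len(n), seq_len(n), function(i, j) {
    dx <- j - c0; dy <- i - c0
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  }))
}

# per-pixel double-loop confusion oracle
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p && t) tp <- tp + 1
    else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# per-pixel corrective oracle: builds the corrected mask pixelwise, then counts
brute_corrective <- function(pred, ann) {
  h <- nrow(pred); w <- ncol(pred)
  corrected <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- pred[i, j]
    if (ann$green[i, j]) v <- FALSE
    if (ann$red[i, j]) v <- TRUE
    corrected[i, j] <- v
  }
  counts <- brute_confusion(pred, binary_mask(corrected))
  list(corrected = corrected, counts = counts,
       area_error = sum(pred) - sum(corrected))
}

brute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  prec <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  dce <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  acc <- (tp + tn) / (tp + fp + fn + tn)
  c(precision = prec, recall = rec, dice = dce, accuracy = acc)
}

# stack-based flood fill region counter (independent of the run-merging
# labelling algorithm)
flood_fill_labels <- function(mask, connectivity = 8) {
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  next_lab <- 0L
  for (sj in seq_len(nc)) for (si in seq_len(nr)) {
    if (!m[si, sj] || lab[si, sj] > 0L) next
    next_lab <- next_lab + 1L
    stack <- list(c(si, sj))
    lab[si, sj] <- next_lab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- next_lab
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  list(labels = lab, n = next_lab)
}

naive_rolling_mean <- function(x, n) {
  if (length(x) < n) return(numeric(0))
  vapply(n:length(x), function(i) sum(x[(i - n + 1):i]) / n, numeric(1))
}
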