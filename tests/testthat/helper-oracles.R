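# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# exhaustive minimum-description-length change-point search: enumerates all
# change-point sets up to max_cp (each segment its own level = segment
# mean) and minimizes RSS/(2*sigma^2) + ((n_states + n_cp)/2) * log(N),
# subject to the same minimum state separation the segmentation enforces
# (segment means closer than min_sep cannot be distinct states)
oracle_mdl_changepoints <- function(y, max_cp = 3, min_sep = 70) {
  n <- length(y)
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  sigma <- max(sigma, 1e-9 * max(1, diff(range(y))), 1e-12)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  seg_rss <- function(i, j) { # rss of y[i..j] around its mean
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  best <- list(mdl = Inf, cp = integer(0))
  for (k in 0:max_cp) {
    cps_sets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(n - 1, k), 2)
    for (cp in cps_sets) {
      cp <- as.integer(cp)
      bounds <- c(0L, cp, n)
      means <- vapply(seq_len(length(bounds) - 1), function(s) {
        mean(y[(bounds[s] + 1L):bounds[s + 1]])
      }, double(1))
      if (k > 0 && min(abs(diff(sort(means)))) < min_sep) next
      rss <- sum(vapply(seq_len(length(bounds) - 1), function(s) {
        seg_rss(bounds[s] + 1L, bounds[s + 1])
      }, double(1)))
      mdl <- rss / (2 * sigma^2) + ((k + 1) + k) / 2 * log(n)
      if (mdl < best$mdl) best <- list(mdl = mdl, cp = cp)
    }
  }
  best$cp  # 1-based index of last frame of each segment == 0-based start of next
}

# brute-force minimum-cost assignment by permutation enumeration
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 7)
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perm(v[-i]), function(p) c(v[i], p))
    }))
  }
  min(vapply(perm(seq_len(m)), function(p) {
    sum(cost[cbind(seq_len(n), p[seq_len(n)])])
  }, double(1)))
}

# textbook O(n^2) DBSCAN, no spatial index
oracle_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (length(nb[[i]]) < min_samples) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] != 0L) next
      labels[j] <- cl
      if (length(nb[[j]]) >= min_samples)
        queue <- c(queue, nb[[j]][is.na(labels[nb[[j]]]) | labels[nb[[j]]] == 0L])
    }
  }
  labels
}

# numeric integral of a function on [0, upper] (fine trapezoid)
oracle_integral <- function(f, upper, n = 20000) {
  x <- seq(0, upper, length.out = n)
  sum((f(x)[-1] + f(x)[-n]) / 2 * diff(x))
}

study_cfg <- function(seed, frame_count = 30, ...) {
  acq_config(frame_count = frame_count, rng_seed = seed, ...)
}
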