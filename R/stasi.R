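#' Change-point segmentation of an intensity trace (STaSI)
#'
#' Step transition and state identification for noisy piecewise-constant
#' photon traces, in two phases.
#'
#' *Splitting*: the trace is recursively divided at the point maximizing
#' the two-sample Student t statistic between the two halves, with the
#' noise amplitude estimated robustly from the median absolute first
#' difference (`sigma = median(|diff(y)|) / (sqrt(2) * 0.6745)`, a
#' Haar-type estimator insensitive to the steps themselves). Always the
#' segment with the largest |t| is split next (ties by earliest frame);
#' splitting stops when no segment's maximal |t| exceeds the critical value
#' for a false-positive probability of `fp_limit` (Bonferroni-corrected
#' over that segment's candidate split points).
#'
#' *State identification*: segment means are merged agglomeratively
#' (closest pair first, weighted means) and the number of states is chosen
#' by a minimum description length criterion,
#' `MDL = RSS/(2*sigma^2) + ((n_states + n_changepoints)/2) * log(N)`,
#' restricted to groupings whose state levels are separated by at least
#' `min_separation` photons (a single state is always admissible).
#'
#' @param photons Numeric photon trace (background-subtracted; values may
#'   be negative), length >= 2. A tibble with a `photons` column is also
#'   accepted.
#' @param fp_limit Limiting false-positive probability for the t-test
#'   splitting (default 0.02).
#' @param min_separation Minimum state separation in photons (default 70).
#'
#' @return A `"step_fit"` object: list with `changepoints` (0-based frames
#'   at which a new level starts, strictly increasing), `levels` (fitted
#'   level per dwell), `states` (distinct state levels), `fitted` (full
#'   fitted trace), `sigma` (noise estimate), `mdl`, `n`, and the
#'   parameters used.
#' @export
#' @examples
#' y <- c(rep(1000, 100), rep(0, 100))
#' fit <- stasi_segment(y)
#' fit$changepoints  # 100
stasi_segment <- function(photons, fp_limit = 0.02, min_separation = 70) {
  if (is.data.frame(photons)) photons <- photons$photons
  y <- as.numeric(photons)
  n <- length(y)
  if (n < 2) abort("trace must have length >= 2")

  sigma <- median(abs(diff(y))) / (sqrt(2) * 0.6745)
  sigma_eff <- max(sigma, 1e-9 * max(1, diff(range(y))), 1e-12)

  # --- phase 1: recursive splitting, largest |t| first -------------------
  best_split <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2) return(list(t = -Inf, at = NA_integer_))
    ys <- y[lo:hi]
    cs <- cumsum(ys)
    nl <- seq_len(m - 1)
    nr <- m - nl
    ml <- cs[nl] / nl
    mr <- (cs[m] - cs[nl]) / nr
    tt <- abs(ml - mr) / (sigma_eff * sqrt(1 / nl + 1 / nr))
    k <- which.max(tt)
    # critical t: two-sided fp_limit, Bonferroni over the m-1 candidates
    df <- max(m - 2, 1)
    tcrit <- qt(1 - fp_limit / 2 / (m - 1), df)
    list(t = tt[k], at = lo + k - 1L, tcrit = tcrit)
  }

  segs <- list(list(lo = 1L, hi = n))
  cand <- list(best_split(1L, n))
  repeat {
    scores <- purrr::map_dbl(seq_along(segs), function(i) {
      if (cand[[i]]$t > cand[[i]]$tcrit %||% Inf) cand[[i]]$t else -Inf
    })
    scores[!is.finite(scores)] <- -Inf
    if (all(scores == -Inf)) break
    i <- which.max(scores)  # ties: earliest segment (which.max picks first)
    sp <- cand[[i]]
    lo <- segs[[i]]$lo; hi <- segs[[i]]$hi
    left <- list(lo = lo, hi = sp$at)
    right <- list(lo = sp$at + 1L, hi = hi)
    segs[[i]] <- left
    segs <- append(segs, list(right), after = i)
    cand[[i]] <- best_split(left$lo, left$hi)
    cand <- append(cand, list(best_split(right$lo, right$hi)), after = i)
  }
  segs <- segs[order(purrr::map_int(segs, "lo"))]
  seg_lo <- purrr::map_int(segs, "lo")
  seg_hi <- purrr::map_int(segs, "hi")
  seg_n <- seg_hi - seg_lo + 1L
  seg_mean <- purrr::map_dbl(segs, function(s) mean(y[s$lo:s$hi]))

  # --- phase 2: agglomerative state grouping + MDL selection -------------
  grouping <- group_states_mdl(y, seg_lo, seg_hi, seg_mean, seg_n,
                               sigma_eff, min_separation)

  dwell_level <- grouping$state_of_segment
  # merge adjacent segments assigned to the same state
  lev <- grouping$state_levels[dwell_level]
  keep <- c(TRUE, diff(lev) != 0)
  cp <- seg_lo[which(!c(TRUE, lev[-1] == lev[-length(lev)]))] - 1L
  fitted <- rep(lev, seg_n)

  structure(list(
    changepoints = as.integer(cp),       # 0-based first frame of new level
    levels = lev[keep],
    states = sort(unique(grouping$state_levels[dwell_level])),
    fitted = fitted,
    sigma = sigma,
    mdl = grouping$mdl,
    n = n,
    fp_limit = fp_limit,
    min_separation = min_separation
  ), class = "step_fit")
}

# Agglomerative merging of segment means into states; MDL-selected count
# subject to a minimum level separation.
group_states_mdl <- function(y, seg_lo, seg_hi, seg_mean, seg_n,
                             sigma_eff, min_separation) {
  n <- length(y)
  k <- length(seg_mean)
  # path of groupings from k states down to 1
  assign <- seq_len(k)
  levels <- seg_mean
  weights <- seg_n
  path <- list(list(assign = assign, levels = levels))
  while (length(levels) > 1) {
    d <- abs(outer(levels, levels, `-`))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- min(ij); b <- max(ij)
    new_level <- (levels[a] * weights[a] + levels[b] * weights[b]) /
      (weights[a] + weights[b])
    levels[a] <- new_level
    weights[a] <- weights[a] + weights[b]
    levels <- levels[-b]; weights <- weights[-b]
    assign[assign == b] <- a
    assign[assign > b] <- assign[assign > b] - 1L
    path <- c(path, list(list(assign = assign, levels = levels)))
  }

  eval_one <- function(g) {
    lev_seg <- g$levels[g$assign]               # level of each segment
    fitted <- rep(lev_seg, seg_n)
    rss <- sum((y - fitted)^2)
    n_cp <- sum(lev_seg[-1] != lev_seg[-length(lev_seg)])
    m <- length(unique(g$assign))
    mdl <- rss / (2 * sigma_eff^2) + (m + n_cp) / 2 * log(n)
    sep_ok <- m == 1 ||
      min(abs(diff(sort(g$levels)))) >= min_separation
    list(mdl = mdl, ok = sep_ok)
  }
  evals <- purrr::map(path, eval_one)
  ok <- purrr::map_lgl(evals, "ok")
  mdls <- purrr::map_dbl(evals, "mdl")
  mdls[!ok] <- Inf
  best <- which.min(mdls)
  g <- path[[best]]
  list(state_of_segment = g$assign, state_levels = g$levels,
       mdl = mdls[best])
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d frames, %d change point(s), %d state(s), sigma = %.2f\n",
              x$n, length(x$changepoints), length(x$states), x$sigma))
  if (length(x$changepoints))
    cat("  change points at frames:", paste(x$changepoints, collapse = ", "), "\n")
  cat("  levels:", paste(signif(x$levels, 5), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
tidy.step_fit <- function(x, ...) {
  starts <- c(0L, x$changepoints)
  ends <- c(x$changepoints, x$n) - 1L
  tibble(dwell = seq_along(starts), start_frame = starts, end_frame = ends,
         level = x$levels)
}

#' @export
autoplot.step_fit <- function(object, photons = NULL, ...) {
  df <- tibble(frame = seq_len(object$n) - 1L, fitted = object$fitted)
  p <- ggplot(df, aes(.data$frame, .data$fitted))
  if (!is.null(photons))
    p <- p + geom_line(data = tibble(frame = df$frame, photons = photons),
                       aes(y = .data$photons), colour = "grey70")
  p + geom_line(colour = "red") +
    labs(x = "frame", y = "photons") + theme_minimal()
}

#' Count irreversible photobleaching steps in a segmented trace
#'
#' Post-processes a [stasi_segment()] fit into a molecule count:
#' (1) transient fluctuations -- dwells shorter than `min_dwell` frames
#' whose entering and leaving transitions have opposite sign (blinks,
#' diffusion spikes) -- are removed by merging them into the preceding
#' level; (2) successive downward steps closer than `max_lag` frames are
#' merged into a single bleaching event; (3) counting is restricted to the
#' strictly decaying part: it starts at the first dwell at the maximum
#' state and stops at the first upward transition.
#'
#' @param fit A `"step_fit"`.
#' @param min_dwell Minimum dwell length in frames for a fluctuation to be
#'   kept (default 50).
#' @param max_lag Maximum frame lag within which successive downward steps
#'   merge into one event (default 6).
#'
#' @return A one-row tibble: `n_steps` (accepted bleaching-step count),
#'   `n_down`, `n_removed_fluctuations`, `n_merged`; the filtered event
#'   log is attached as attribute `"events"`.
#' @export
count_bleach_steps <- function(fit, min_dwell = 50, max_lag = 6) {
  stopifnot(inherits(fit, "step_fit"))
  starts <- c(0L, fit$changepoints)
  lens <- diff(c(starts, fit$n))
  lev <- fit$levels
  n_removed <- 0L

  # (1) drop short reversal dwells (blink / spike), shortest first
  repeat {
    k <- length(lev)
    if (k < 3) break
    inner <- 2:(k - 1)
    enter <- sign(lev[inner] - lev[inner - 1])
    leave <- sign(lev[inner + 1] - lev[inner])
    bad <- inner[lens[inner] < min_dwell & enter != 0 & leave != 0 &
                   enter != leave]
    if (length(bad) == 0) break
    j <- bad[which.min(lens[bad])]
    # merge dwell j into the previous level
    lens[j - 1] <- lens[j - 1] + lens[j]
    lev <- lev[-j]; lens <- lens[-j]; starts <- starts[-j]
    n_removed <- n_removed + 1L
    # merge adjacent now-equal levels
    eq <- which(diff(lev) == 0)
    while (length(eq) > 0) {
      i <- eq[1]
      lens[i] <- lens[i] + lens[i + 1]
      lev <- lev[-(i + 1)]; lens <- lens[-(i + 1)]; starts <- starts[-(i + 1)]
      eq <- which(diff(lev) == 0)
    }
  }
  starts <- cumsum(c(0L, lens[-length(lens)]))

  events <- tibble(
    frame = starts[-1],
    from = lev[-length(lev)],
    to = lev[-1],
    direction = ifelse(lev[-1] < lev[-length(lev)], "down", "up")
  )

  # (3) strictly decaying part: from first dwell at the maximum level to
  # the first upward transition
  i_max <- which.max(lev)
  n_steps <- 0L
  n_down <- sum(events$direction == "down")
  n_merged <- 0L
  if (length(lev) > i_max) {
    down_frames <- integer(0)
    for (i in i_max:(length(lev) - 1)) {
      if (lev[i + 1] > lev[i]) break
      down_frames <- c(down_frames, starts[i + 1])
    }
    if (length(down_frames) > 0) {
      # (2) chain-merge downs closer than max_lag frames
      gaps <- diff(down_frames)
      n_merged <- sum(gaps <= max_lag)
      n_steps <- length(down_frames) - n_merged
    }
  }
  out <- tibble(n_steps = as.integer(n_steps), n_down = n_down,
                n_removed_fluctuations = n_removed, n_merged = n_merged)
  attr(out, "events") <- events
  out
}

#' Regression of first-frame intensity on bleaching-step count
#'
#' The robustness check for step counting: across spots, the first-frame
#' intensity should scale linearly with the number of detected bleaching
#' steps.
#'
#' @param traces Tibble (`trace_id`, `frame`, `photons`) of >= 10 spots.
#' @param fits Named list of `"step_fit"` objects, names = trace ids (or
#'   unnamed, in trace order). When NULL, traces are segmented with
#'   default parameters.
#' @param min_dwell,max_lag Passed to [count_bleach_steps()].
#' @return One-row tibble: `slope`, `intercept`, `r`, `n_spots`, `flag`
#'   (`"ok"` or `"degenerate"` when all counts are equal; `r` is NA then).
#'   The per-spot table is attached as attribute `"spots"`.
#' @export
steps_vs_intensity <- function(traces, fits = NULL, min_dwell = 50,
                               max_lag = 6) {
  ids <- unique(traces$trace_id)
  if (length(ids) < 10) abort("need >= 10 spots")
  if (is.null(fits)) {
    fits <- purrr::map(ids, function(id) {
      stasi_segment(traces$photons[traces$trace_id == id])
    })
    names(fits) <- as.character(ids)
  }
  if (is.null(names(fits))) names(fits) <- as.character(ids)
  spots <- purrr::map(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    cnt <- count_bleach_steps(fits[[as.character(id)]], min_dwell, max_lag)
    tibble(trace_id = id,
           first_intensity = tr$photons[which.min(tr$frame)],
           n_steps = cnt$n_steps)
  }) |> list_rbind()
  if (length(unique(spots$n_steps)) < 2) {
    out <- tibble(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                  n_spots = nrow(spots), flag = "degenerate")
  } else {
    fit <- lm(first_intensity ~ n_steps, data = spots)
    out <- tibble(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r = stats::cor(spots$first_intensity, spots$n_steps),
      n_spots = nrow(spots),
      flag = "ok"
    )
  }
  attr(out, "spots") <- spots
  out
}
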