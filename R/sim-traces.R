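#' Simulate photobleaching intensity traces
#'
#' Each trace starts with `n_fluorophores` active emitters; every emitter
#' bleaches irreversibly after an exponentially distributed lifetime (mean
#' `bleach_mean` frames). The trace level is the number of active emitters
#' times `cfg$photons_per_fluorophore`, plus additive Gaussian noise. The
#' ground truth records each trace's true fluorophore count and change-point
#' frames.
#'
#' @param n_fluorophores Integer vector, one entry per trace (each >= 1).
#' @param cfg An [acq_config()]; `frame_count` sets the trace length.
#' @param noise_sigma Gaussian noise s.d. in photons (default
#'   `0.1 * photons_per_fluorophore`).
#' @param bleach_mean Mean bleaching lifetime in frames (default 150, so
#'   that dwell-based filtering is exercised).
#'
#' @return Tibble with columns `trace_id`, `frame` (0-based), `photons`;
#'   ground truth (list-columns `changepoints`, `levels`) via [sim_truth()].
#' @export
#' @examples
#' tr <- sim_bleach_traces(c(1, 2, 3), acq_config(frame_count = 600, rng_seed = 2))
#' sim_truth(tr)$n_fluorophores
sim_bleach_traces <- function(n_fluorophores,
                              cfg = acq_config(frame_count = 1000),
                              noise_sigma = NULL,
                              bleach_mean = 150) {
  if (any(n_fluorophores < 1)) abort("`n_fluorophores` entries must be >= 1")
  seed_from_config(cfg)
  noise_sigma <- noise_sigma %||% (0.1 * cfg$photons_per_fluorophore)
  nf <- cfg$frame_count
  unit <- cfg$photons_per_fluorophore

  res <- purrr::imap(n_fluorophores, function(nk, id) {
    # bleach frame of each emitter (>= 1: every emitter is on in frame 0)
    bleach_at <- pmax(1L, ceiling(rexp(nk, 1 / bleach_mean)))
    alive <- vapply(seq_len(nf) - 1L, function(f) sum(bleach_at > f), integer(1))
    cps <- which(diff(alive) < 0)  # change point = first frame of the new level
    trace <- tibble(
      trace_id = id,
      frame = seq_len(nf) - 1L,
      photons = alive * unit + rnorm(nf, 0, noise_sigma)
    )
    truth <- tibble(
      trace_id = id,
      n_fluorophores = nk,
      noise_sigma = noise_sigma,
      changepoints = list(as.integer(cps)),          # 0-based frame of level change
      levels = list(unit * unique_levels(alive)),
      n_steps_observed = length(cps)
    )
    list(trace = trace, truth = truth)
  })
  with_truth(
    list_rbind(purrr::map(res, "trace")),
    list_rbind(purrr::map(res, "truth"))
  )
}

unique_levels <- function(alive) {
  alive[c(TRUE, diff(alive) != 0)]
}
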