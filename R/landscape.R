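# Global identifiability mapping: score the MSE of randomized scaling
# factor vectors against a fixed target, then summarize the per-parameter
# minimum-MSE envelope and its local minima.

#' Sample the MSE landscape
#'
#' Draws scaling-factor vectors log-uniformly over per-current ranges
#' (default 1/10 to 10 times baseline) and scores each against the target.
#' The exact centre point (all sampled currents at 1) is injected
#' deterministically as the first sample when `include_center` is TRUE.
#' Quiescent samples carry the penalty MSE and a flag.
#'
#' @param target Single-cycle target from [make_target()].
#' @param params A [cell_params()].
#' @param free Currents to randomize (others fixed at 1).
#' @param n_samples Number of random samples.
#' @param range Two-element range applied to every free current.
#' @param seed Integer seed.
#' @param cost Optional cost function overriding the model-based one
#'   (used for surrogate studies); called with a named sf vector.
#' @param spec An [objective_spec()].
#' @param include_center Inject the all-ones sample first.
#' @param progress Print a dot every 100 samples.
#' @return A `landscape` tibble: one row per sample with the free sf
#'   columns, `mse`, `log10_mse` and `quiescent`.
#' @export
sample_landscape <- function(target = NULL, params = cell_params(),
                             free = c("Kr", "bNSC"), n_samples = 1000,
                             range = c(0.1, 10), seed = 1, cost = NULL,
                             spec = objective_spec(),
                             include_center = TRUE, progress = FALSE) {
  stopifnot(n_samples >= 1, range[1] > 0, range[2] > range[1])
  if (is.null(cost)) {
    stopifnot(!is.null(target))
    cost <- make_cost(target, params, spec)
  }
  draws <- with_seed(seed, {
    m <- matrix(stats::runif(n_samples * length(free),
                             log(range[1]), log(range[2])),
                ncol = length(free))
    exp(m)
  })
  colnames(draws) <- free
  if (include_center) {
    draws <- rbind(stats::setNames(rep(1, length(free)), free), draws)
  }
  mse <- numeric(nrow(draws))
  for (i in seq_len(nrow(draws))) {
    mse[i] <- cost(draws[i, ])
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- tibble::as_tibble(as.data.frame(draws))
  out$mse <- mse
  out$log10_mse <- log10(pmax(mse, .Machine$double.xmin))
  out$quiescent <- mse >= spec$penalty_mse
  structure(out, class = c("landscape", class(out)),
            free = free, range = range, seed = seed)
}

#' Minimum-MSE envelope along one parameter axis
#'
#' Bins the samples along one scaling-factor axis (log-spaced bins over the
#' sampled range) and records the minimum MSE in each bin, marginalizing
#' over all other parameters.  Quiescent (penalty) samples are excluded.
#'
#' @param samples A `landscape` tibble from [sample_landscape()].
#' @param sf_name Current name (a free axis of the scan).
#' @param n_bins Number of bins.
#' @return Tibble: `bin`, `sf_lo`, `sf_hi`, `sf_mid` (geometric midpoint),
#'   `min_mse`, `n` (samples in bin; empty bins have `n = 0`, `min_mse` NA).
#' @export
mse_envelope <- function(samples, sf_name, n_bins = 50) {
  if (!sf_name %in% names(samples)) {
    stop("'", sf_name, "' is not a sampled axis", call. = FALSE)
  }
  ok <- !samples$quiescent
  if (!any(ok)) stop("no non-quiescent samples on axis", call. = FALSE)
  rng <- attr(samples, "range") %||% range(samples[[sf_name]])
  edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  x <- samples[[sf_name]]
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  bin[bin > n_bins] <- n_bins
  purrr::map_dfr(seq_len(n_bins), function(b) {
    i <- ok & bin == b
    tibble::tibble(bin = b, sf_lo = edges[b], sf_hi = edges[b + 1],
                   sf_mid = sqrt(edges[b] * edges[b + 1]),
                   min_mse = if (any(i)) min(samples$mse[i]) else NA_real_,
                   n = sum(i))
  })
}

#' Detect local minima of an envelope
#'
#' Scans the non-empty bins of a minimum-MSE envelope for interior strict
#' local minima (on the log10 MSE scale) with prominence above a
#' threshold.  For a baseline-model target the expected outcome is a
#' single minimum in the bin containing sf = 1.
#'
#' @param envelope Tibble from [mse_envelope()].
#' @param prominence Minimum prominence in log10-MSE units (default 0.2).
#' @return Tibble of detected minima: `bin`, `sf_mid`, `min_mse`,
#'   `prominence`.
#' @export
detect_local_minima <- function(envelope, prominence = 0.2) {
  e <- envelope[envelope$n > 0, ]
  if (nrow(e) < 5) {
    stop("need at least 5 non-empty bins", call. = FALSE)
  }
  y <- log10(e$min_mse)
  n <- length(y)
  out <- list()
  for (i in 2:(n - 1)) {
    if (!(y[i] < y[i - 1] && y[i] < y[i + 1])) next
    # barrier heights before reaching a strictly lower envelope value
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    lower_l <- which(rev(left) < y[i])
    lower_r <- which(right < y[i])
    barrier_l <- if (length(lower_l)) {
      max(rev(left)[seq_len(lower_l[1] - 1)])
    } else max(left)
    barrier_r <- if (length(lower_r)) {
      max(right[seq_len(lower_r[1] - 1)])
    } else max(right)
    prom <- min(barrier_l, barrier_r) - y[i]
    if (prom >= prominence) {
      out[[length(out) + 1]] <- tibble::tibble(
        bin = e$bin[i], sf_mid = e$sf_mid[i], min_mse = e$min_mse[i],
        prominence = prom)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(bin = integer(), sf_mid = numeric(),
                          min_mse = numeric(), prominence = numeric()))
  }
  dplyr::bind_rows(out)
}
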