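# Base-point / new-point Pattern Search over selected conductance scaling
# factors, and the multi-run driver with randomized initial parameter sets
# ("orp" protocol).  The exploratory move probes each selected coordinate
# at +/- the current step; an improved sweep renews the base point at the
# same step, otherwise the step shrinks by the reduction factor until it
# falls below the critical step.

#' Pattern Search configuration
#'
#' @param stp0 Initial step in sf units (dimensionless).
#' @param redFct Step reduction factor in (0, 1); default 1/4.
#' @param crtstp Critical (termination) step; default 5e-5, sensible range
#'   2e-5 to 1e-4.
#' @param sweep Coordinate sweep order (current names); default the roster
#'   order of the selected currents.
#' @param max_evals Evaluation budget.
#' @param short_circuit Skip the -step probe when the +step probe already
#'   improves (halves the evaluation cost of improving sweeps).
#' @return A `ps_config` object.
#' @export
ps_config <- function(stp0 = 0.04, redFct = 1 / 4, crtstp = 5e-5,
                      sweep = NULL, max_evals = 20000,
                      short_circuit = TRUE) {
  stopifnot(redFct > 0, redFct < 1, crtstp > 0, crtstp < stp0, max_evals >= 1)
  structure(list(stp0 = stp0, redFct = redFct, crtstp = crtstp,
                 sweep = sweep, max_evals = max_evals,
                 short_circuit = short_circuit),
            class = "ps_config")
}

#' Pattern Search optimization of a cost function
#'
#' Minimizes `cost` over the named components of `bp0`.  For each selected
#' coordinate in sweep order the candidate points base +/- step are
#' evaluated and the best of the three kept (ties prefer the + step); after
#' a full sweep, an improved candidate renews the base point at the same
#' step, otherwise the step is multiplied by `redFct`.  The run terminates
#' when the step falls below `crtstp`.
#'
#' @param cost Function mapping a named numeric vector to a scalar cost
#'   (total: quiescent candidates must return a finite penalty).
#' @param bp0 Named numeric start vector (positive).
#' @param config A [ps_config()].
#' @return A `ps_run` with the base-point history, evaluation log, final
#'   point and convergence flag.  Supports [tidy()] and [glance()].
#' @examples
#' cost <- function(x) sum((x - 1)^2)
#' run <- ps_optimize(cost, c(a = 1.1, b = 0.9))
#' glance(run)
#' @export
ps_optimize <- function(cost, bp0, config = ps_config()) {
  stopifnot(!is.null(names(bp0)), all(bp0 > 0))
  sweep <- config$sweep %||% names(bp0)
  stopifnot(all(sweep %in% names(bp0)))

  n_evals <- 0L
  eval_log <- vector("list", 256L)
  n_log <- 0L
  stp_now <- config$stp0
  ev <- function(x) {
    if (any(x <= 0)) return(Inf)   # conductances are non-negative
    n_evals <<- n_evals + 1L
    f <- cost(x)
    n_log <<- n_log + 1L
    if (n_log > length(eval_log)) length(eval_log) <<- 2L * length(eval_log)
    eval_log[[n_log]] <<- c(x, mse = f, stp = stp_now)
    f
  }

  bp <- bp0
  f_bp <- ev(bp)
  history <- list(c(bp, mse = f_bp, stp = stp_now))
  converged <- FALSE
  stp <- config$stp0
  dir_mem <- stats::setNames(rep(1, length(sweep)), sweep)
  repeat {
    if (stp < config$crtstp) {
      converged <- TRUE
      break
    }
    if (n_evals >= config$max_evals) break
    stp_now <- stp
    np <- bp
    f_np <- f_bp
    for (nm in sweep) {
      # probe the last successful direction for this coordinate first
      d1 <- if (isTRUE(config$short_circuit)) dir_mem[[nm]] else 1
      first <- np; first[nm] <- np[nm] + d1 * stp
      f_first <- ev(first)
      if (isTRUE(config$short_circuit) && f_first < f_np) {
        np <- first; f_np <- f_first
        dir_mem[[nm]] <- d1
      } else {
        second <- np; second[nm] <- np[nm] - d1 * stp
        f_second <- ev(second)
        # on exact ties the + step is preferred
        f_pl <- if (d1 > 0) f_first else f_second
        f_mi <- if (d1 > 0) f_second else f_first
        if (f_pl <= f_mi && f_pl < f_np) {
          np[nm] <- np[nm] + stp; f_np <- f_pl
          dir_mem[[nm]] <- 1
        } else if (f_mi < f_np) {
          np[nm] <- np[nm] - stp; f_np <- f_mi
          dir_mem[[nm]] <- -1
        }
      }
      if (n_evals >= config$max_evals) break
    }
    if (f_np < f_bp) {
      bp <- np
      f_bp <- f_np
      history[[length(history) + 1]] <- c(bp, mse = f_bp, stp = stp)
    } else {
      stp <- stp * config$redFct
    }
  }

  hist_mat <- do.call(rbind, history)
  log_mat <- do.call(rbind, eval_log[seq_len(n_log)])
  structure(list(
    bp_history = tibble::as_tibble(as.data.frame(hist_mat)),
    eval_log = tibble::as_tibble(as.data.frame(log_mat)),
    final_sf = bp,
    final_mse = f_bp,
    converged = converged,
    n_evals = n_evals,
    config = config
  ), class = "ps_run")
}

#' @export
print.ps_run <- function(x, ...) {
  cat("<ps_run>", nrow(x$bp_history), "base-point renewals,",
      x$n_evals, "evaluations\n")
  cat("  final MSE:", format(x$final_mse, digits = 6),
      if (x$converged) "(converged)" else "(budget exhausted)", "\n")
  print(round(x$final_sf, 5))
  invisible(x)
}

#' @export
tidy.ps_run <- function(x, ...) {
  h <- x$bp_history
  h$renewal <- seq_len(nrow(h)) - 1L
  h
}

#' @export
glance.ps_run <- function(x, ...) {
  tibble::tibble(final_mse = x$final_mse,
                 log10_mse = log10(x$final_mse),
                 n_renewals = nrow(x$bp_history) - 1L,
                 n_evals = x$n_evals,
                 converged = x$converged)
}

#' Multi-run optimization from randomized initial parameter sets
#'
#' Runs [ps_optimize()] `n_runs` times against one cell-specific target,
#' each run starting from an independent uniform randomization of the
#' ground-truth scaling factors (the "orp" protocol).  Pools all base
#' points into a common sf-MSE scatter and records the homeostasis
#' endpoints (intracellular Na+ and total cell Ca) of each run.
#'
#' @param target Single-cycle target from [make_target()] (carries
#'   `sf_true`).
#' @param params A [cell_params()].
#' @param selected Currents to optimize (4-6 typical, up to 9).
#' @param n_runs Number of optimization runs.
#' @param range_pct Randomization half-width (0.05-0.15 in the protocol).
#' @param config A [ps_config()].
#' @param seed Integer seed; run `i` derives seed `seed + i`.
#' @param frozen Named sf values held fixed (not optimized).
#' @param spec An [objective_spec()].
#' @param settle_cycles Settling horizon per cost evaluation, in target
#'   cycle lengths (see [make_cost()]).
#' @param progress Print one line per run.
#' @return An `orp_result`; supports [tidy()], [glance()],
#'   [top_k_stats()], [autoplot()].
#' @export
orp_test <- function(target, params = cell_params(),
                     selected = c("Kr", "CaL", "Na", "K1"),
                     n_runs = 30, range_pct = 0.1,
                     config = ps_config(), seed = 1, frozen = NULL,
                     spec = objective_spec(), settle_cycles = 3,
                     progress = FALSE) {
  stopifnot(n_runs >= 1)
  sf_true <- complete_sf(attr(target, "sf_true"))
  if (!is.null(frozen)) {
    overlap <- intersect(names(frozen), selected)
    if (length(overlap)) {
      stop("currents both frozen and selected: ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
  }
  runs <- vector("list", n_runs)
  finals <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    run_seed <- seed + i
    sf0 <- randomize_sf(sf_true, selected, range_pct, seed = run_seed)
    cost <- make_cost(target, params, spec, frozen = frozen,
                      settle_cycles = settle_cycles)
    bp0 <- stats::setNames(as.numeric(sf0[selected]), selected)
    res <- ps_optimize(cost, bp0, config)
    res$seed <- run_seed
    runs[[i]] <- res
    st <- cost_state_for(cost, res$final_sf)
    ep <- homeostasis_endpoints(params, complete_sf(frozen_with(res$final_sf,
                                                                frozen)),
                                st)
    row <- tibble::tibble(
      run = i, seed = run_seed,
      final_mse = res$final_mse, converged = res$converged,
      n_evals = res$n_evals,
      Na_i = ep[["Na_i"]],
      Ca_tot = ep[["Ca_tot"]]
    )
    for (nm in selected) row[[paste0("sf_", nm)]] <- res$final_sf[[nm]]
    finals[[i]] <- row
    if (progress) {
      cat(sprintf("run %3d: mse %.3e evals %d\n", i, res$final_mse,
                  res$n_evals))
    }
  }
  structure(list(
    runs = runs,
    finals = dplyr::bind_rows(finals),
    sf_true = sf_true,
    selected = selected,
    frozen = frozen,
    range_pct = range_pct,
    config = config,
    seed = seed
  ), class = "orp_result")
}

#' @export
print.orp_result <- function(x, ...) {
  cat("<orp_result>", length(x$runs), "runs over",
      paste(x$selected, collapse = ", "),
      sprintf("(+/-%g%% starts)\n", 100 * x$range_pct))
  cat("  final log10(MSE): median",
      round(stats::median(log10(x$finals$final_mse)), 2), "\n")
  invisible(x)
}

#' @export
tidy.orp_result <- function(x, ...) x$finals

#' @export
glance.orp_result <- function(x, ...) {
  tibble::tibble(n_runs = length(x$runs),
                 median_log10_mse = stats::median(log10(x$finals$final_mse)),
                 best_log10_mse = min(log10(x$finals$final_mse)),
                 prop_converged = mean(x$finals$converged))
}

#' Pooled base-point scatter of an orp test
#'
#' All base points of all runs in a common sf-MSE coordinate (long format),
#' for convergence plots.
#'
#' @param x An `orp_result`.
#' @return Tibble: `run`, `renewal`, `current`, `sf`, `mse`.
#' @export
orp_scatter <- function(x) {
  purrr::map_dfr(seq_along(x$runs), function(i) {
    h <- tidy(x$runs[[i]])
    h$run <- i
    tidyr::pivot_longer(h, dplyr::all_of(x$selected),
                        names_to = "current", values_to = "sf")
  })
}

#' Statistics of the top-K runs
#'
#' Mean and standard error of each optimized scaling factor over the `k`
#' runs with the smallest final MSE, together with the mean final
#' log10(MSE) and the mean homeostasis endpoints.
#'
#' @param x An `orp_result`.
#' @param k Number of best runs (default 20).
#' @return List with `per_sf` (tibble: current, mean, se), and scalars
#'   `mean_log10_mse`, `mean_Na_i`, `mean_Ca_tot`, `k`.
#' @export
top_k_stats <- function(x, k = 20) {
  fin <- x$finals[is.finite(x$finals$final_mse), ]
  if (nrow(fin) < k) {
    stop("only ", nrow(fin), " usable runs; need k = ", k, call. = FALSE)
  }
  top <- dplyr::slice_min(fin, .data$final_mse, n = k, with_ties = FALSE)
  per_sf <- purrr::map_dfr(x$selected, function(nm) {
    v <- top[[paste0("sf_", nm)]]
    tibble::tibble(current = nm, mean = mean(v),
                   se = stats::sd(v) / sqrt(k))
  })
  list(per_sf = per_sf,
       mean_log10_mse = mean(log10(top$final_mse)),
       mean_Na_i = mean(top$Na_i),
       mean_Ca_tot = mean(top$Ca_tot),
       k = k)
}

# full sf vector from optimized components plus frozen values
frozen_with <- function(final_sf, frozen) {
  full <- complete_sf(frozen)
  full[names(final_sf)] <- final_sf
  full
}

# steady-state Na_i and total Ca at the cycle boundary (the homeostasis
# sampling instant), from a short continuation of the final state
homeostasis_endpoints <- function(params, sf, init) {
  tr <- simulate_cell(params, sf, init = init, n_cycles = 2, output_dt = 1)
  ups <- attr(tr, "cycles")
  if (!length(ups)) {
    return(c(Na_i = init[["Na_i"]], Ca_tot = ca_total(init, params)))
  }
  ix <- which.min(abs(tr$time_ms - ups[length(ups)]))
  c(Na_i = tr$Na_i[ix], Ca_tot = tr$Ca_tot[ix])
}

#' Constrained orp test with frozen currents
#'
#' Identical to [orp_test()] with a subset of currents fixed at given
#' values and removed from the search vector, used to probe complementary
#' (degenerate) current combinations.
#'
#' @inheritParams orp_test
#' @param frozen Named numeric: currents to fix and their values.
#' @export
constrained_orp <- function(target, params = cell_params(), frozen,
                            selected = NULL, ...) {
  stopifnot(!is.null(names(frozen)))
  sf_true <- complete_sf(attr(target, "sf_true"))
  if (is.null(selected)) {
    selected <- setdiff(c("Kr", "CaL", "Na", "ha", "K1", "bNSC"),
                        names(frozen))
  }
  orp_test(target, params, selected = selected, frozen = frozen, ...)
}
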