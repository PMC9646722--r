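# Delimited-text I/O for traces, scan results and run manifests.  Traces
# are two-column CSV (`time_ms,vm_mV`) on a validated uniform grid;
# configurations and manifests are YAML/JSON.

#' Write / read a membrane-potential trace
#'
#' Traces are stored as CSV with header `time_ms,vm_mV`; the grid must be
#' strictly uniform.  Reading validates grid uniformity and finiteness and
#' reports the offending line on failure; both LF and CRLF files are
#' accepted.  Round-trip is lossless to the printed precision (9
#' significant digits).
#'
#' @param trace An `ap_trace` or tibble with `time_ms`, `vm_mV`.
#' @param path File path.
#' @return `read_trace` returns an `ap_trace` tibble.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("time_ms", "vm_mV") %in% names(trace)))
  lines <- c("time_ms,vm_mV",
             paste(formatC(trace$time_ms, format = "fg", digits = 9),
                   formatC(trace$vm_mV, format = "g", digits = 9),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  raw <- readLines(path)
  raw <- sub("\r$", "", raw)
  if (!length(raw) || tolower(raw[1]) != "time_ms,vm_mv") {
    stop("not a trace file (expected header 'time_ms,vm_mV'): ", path,
         call. = FALSE)
  }
  body <- raw[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_len <- which(lengths(parts) != 2)
  if (length(bad_len)) {
    stop("malformed row at line ", bad_len[1] + 1L, " of ", path,
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2, byrow = TRUE)
  nf <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))
  if (length(nf)) {
    stop("non-finite value at line ", nf[1] + 1L, " of ", path,
         call. = FALSE)
  }
  dt <- diff(m[, 1])
  if (any(dt <= 0)) {
    stop("non-increasing time at line ", which(dt <= 0)[1] + 2L, " of ",
         path, call. = FALSE)
  }
  if (length(dt) > 1) {
    bad <- which(abs(dt - dt[1]) > 1e-6 * max(1, dt[1]))
    if (length(bad)) {
      stop("non-uniform grid (", format(dt[bad[1]]), " ms step) at line ",
           bad[1] + 2L, " of ", path, call. = FALSE)
    }
  }
  out <- tibble::tibble(time_ms = m[, 1], vm_mV = m[, 2])
  structure(out, class = c("ap_trace", class(out)),
            output_dt = if (length(dt)) dt[1] else NA_real_)
}

#' Write / read a landscape scan
#'
#' One row per sample: the sampled sf columns, `mse`, `log10_mse`,
#' `quiescent`.  Serialization round-trips losslessly.
#'
#' @param samples A `landscape` tibble.
#' @param path File path.
#' @export
write_landscape <- function(samples, path) {
  df <- as.data.frame(samples)
  header <- sprintf("# pacefit landscape free=%s range=%s seed=%s",
                    paste(attr(samples, "free"), collapse = "|"),
                    paste(attr(samples, "range"), collapse = "|"),
                    attr(samples, "seed") %||% NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header,
                     regexec("free=(\\S+) range=(\\S+) seed=(\\S+)", header))[[1]]
  df <- utils::read.csv(path, skip = 1)
  out <- tibble::as_tibble(df)
  structure(out, class = c("landscape", class(out)),
            free = strsplit(meta[2], "|", fixed = TRUE)[[1]],
            range = as.numeric(strsplit(meta[3], "|", fixed = TRUE)[[1]]),
            seed = suppressWarnings(as.integer(meta[4])))
}

#' Run manifest
#'
#' A self-describing record of a computation: tool version, formulation
#' id, fully resolved configuration, seeds and input digests.  Re-running
#' a manifest's configuration reproduces the outputs of deterministic
#' stages bit-identically.
#'
#' @param config Named list: the fully resolved configuration.
#' @param seed Integer seed(s).
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config = list(), seed = NULL, inputs = character()) {
  digests <- if (length(inputs)) {
    found <- file.exists(inputs)
    d <- rep(NA_character_, length(inputs))
    d[found] <- unname(tools::md5sum(inputs[found]))
    stats::setNames(as.list(d), inputs)
  } else NULL
  structure(list(
    tool = "pacefit",
    version = as.character(utils::packageVersion("pacefit")),
    formulation_id = cell_params()$formulation_id,
    config = config,
    seed = seed,
    input_digests = digests
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path File path (JSON).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}

#' Write / read an orp-test summary
#'
#' Persists the per-run finals table and the defining configuration of an
#' [orp_test()] result as JSON; reading restores a summary object whose
#' finals table is bit-identical for a reproduced run.
#'
#' @param orp An `orp_result`.
#' @param path File path.
#' @export
write_orp <- function(orp, path) {
  payload <- list(
    selected = orp$selected,
    frozen = orp$frozen,
    range_pct = orp$range_pct,
    seed = orp$seed,
    sf_true = as.list(unclass(orp$sf_true)),
    config = unclass(orp$config),
    finals = orp$finals
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_orp
#' @export
read_orp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$finals <- tibble::as_tibble(p$finals)
  p
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @param config Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read model parameters (YAML)
#'
#' Serializes a [cell_params()] set as structured text with an explicit
#' `formulation_id`; reading validates the formulation id and restores the
#' full parameter object.
#'
#' @param params A [cell_params()].
#' @param path YAML file path.
#' @export
write_cell_params <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_cell_params
#' @export
read_cell_params <- function(path) {
  p <- yaml::read_yaml(path)
  if (is.null(p$formulation_id)) {
    stop("not a parameter file (missing formulation_id): ", path,
         call. = FALSE)
  }
  ref <- cell_params()
  if (!identical(p$formulation_id, ref$formulation_id)) {
    stop("parameter file targets formulation '", p$formulation_id,
         "' but this build implements '", ref$formulation_id, "'",
         call. = FALSE)
  }
  known <- setdiff(names(p), c("rtol", "atol", "formulation_id"))
  do.call(cell_params, c(p[known], list(rtol = p$rtol, atol = p$atol)))
}

#' Write / read a cell-state snapshot (YAML)
#'
#' Structured-text serialization of a full dynamical [cell_state()] for
#' warm restarts.
#'
#' @param state A [cell_state()].
#' @param path YAML file path.
#' @export
write_state <- function(state, path) {
  yaml::write_yaml(list(t = attr(state, "t") %||% 0,
                        state = as.list(unclass(state))), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  s <- yaml::read_yaml(path)
  as_cell_state(unlist(s$state), t = s$t %||% 0)
}
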