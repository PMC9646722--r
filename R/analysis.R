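# Post-hoc identifiability analytics on converged parameter ensembles:
# principal components computed by explicit variance-maximization with
# deflation, and complementary-relationship hyperplane fits.

#' Principal components of a parameter ensemble by deflation
#'
#' Computes principal components of an n x p matrix of final scaling
#' factors by the deflation scheme: the first loading maximizes the
#' Rayleigh quotient of the centered data; each subsequent loading
#' maximizes it on the data with the previous components subtracted.
#' Loadings are unit-norm with the sign fixed so the largest-magnitude
#' entry is positive.  Input columns are centered, not variance-scaled.
#'
#' @param x Matrix or data frame (n runs x p factors), n >= 2.
#' @return An `sf_pca` object: `loadings` (p x p), `scores` (n x p),
#'   `sdev`, `var_explained`, `center`, `x`.  Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' sf_pca(x)$var_explained
#' @export
sf_pca <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, ncol(x) >= 1)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (all(apply(xc, 2, stats::sd) < .Machine$double.eps^0.5)) {
    stop("degenerate input: all columns constant", call. = FALSE)
  }
  p <- ncol(xc)
  w <- matrix(0, p, p)
  xk <- xc
  for (k in seq_len(p)) {
    v <- dominant_direction(xk)
    if (k > 1) {
      # the deflated remainder can be numerically rank-deficient; keep the
      # loading exactly orthogonal to the components already extracted
      prev <- w[, seq_len(k - 1), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) {
        v <- qr.Q(qr(prev), complete = TRUE)[, k]
      } else {
        v <- v / nv
      }
    }
    w[, k] <- v
    xk <- xk - (xk %*% w[, k, drop = FALSE]) %*% t(w[, k, drop = FALSE])
  }
  # sign convention: largest-magnitude entry positive
  for (k in seq_len(p)) {
    j <- which.max(abs(w[, k]))
    if (w[j, k] < 0) w[, k] <- -w[, k]
  }
  scores <- xc %*% w
  sdev <- apply(scores, 2, stats::sd)
  rownames(w) <- colnames(x) %||% paste0("x", seq_len(p))
  colnames(w) <- paste0("PC", seq_len(p))
  colnames(scores) <- colnames(w)
  structure(list(loadings = w, scores = scores, sdev = sdev,
                 var_explained = sdev^2 / sum(sdev^2),
                 center = mu, x = x),
            class = "sf_pca")
}

# leading eigendirection of t(x) %*% x by deterministic power iteration
dominant_direction <- function(x, tol = 1e-14, maxit = 10000L) {
  p <- ncol(x)
  cp <- crossprod(x)
  # deterministic start: the coordinate axis with the largest variance,
  # blended with a fixed dense vector to avoid orthogonal stalls
  v0 <- rep(1, p) / sqrt(p)
  j <- which.max(diag(cp))
  v <- v0
  v[j] <- v[j] + 1
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(maxit)) {
    u <- cp %*% v
    nu <- sqrt(sum(u^2))
    if (nu < .Machine$double.eps) break   # fully deflated remainder
    u <- u / nu
    if (abs(nu - lam) <= tol * max(1, nu) && sum(abs(u - v)) < 1e-12) {
      v <- u
      break
    }
    lam <- nu
    v <- u
  }
  as.numeric(v)
}

#' @export
print.sf_pca <- function(x, ...) {
  cat("<sf_pca>", nrow(x$x), "observations,", ncol(x$x), "variables\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.sf_pca <- function(x, ...) {
  ld <- as.data.frame(x$loadings)
  ld$term <- rownames(x$loadings)
  tidyr::pivot_longer(tibble::as_tibble(ld), -"term",
                      names_to = "component", values_to = "loading")
}

#' @export
glance.sf_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$x), p = ncol(x$x),
                 var_pc1 = x$var_explained[1],
                 var_pc2 = if (length(x$var_explained) > 1) {
                   x$var_explained[2]
                 } else NA_real_)
}

#' Fit a hyperplane to a parameter ensemble
#'
#' Fits `a . sf = c` to the selected columns.  Two modes: `"tls"`
#' (orthogonal / total least squares: `a` is the smallest-variance
#' direction of the centered ensemble, reported with unit norm) and
#' `"ols"` (ordinary least squares with a designated response column,
#' coefficients renormalized to unit length for comparability).  The R^2
#' always refers to the OLS regression of the response on the remaining
#' columns (for `"tls"`, the response defaults to the column with the
#' largest normalized coefficient).
#'
#' @param points Matrix or data frame of sf values (columns named).
#' @param response Response column name for the OLS view (optional).
#' @param method `"tls"` (default) or `"ols"`.
#' @return A `plane_fit`: `coefficients` (named, unit norm), `constant`,
#'   `r_squared`, `response`, `method`, `n`, `points`.
#' @examples
#' pts <- data.frame(a = runif(20), b = runif(20))
#' pts$c <- 1 - 0.5 * pts$a - 0.3 * pts$b
#' fit_plane(pts)$r_squared  # 1: exact plane
#' @export
fit_plane <- function(points, response = NULL, method = c("tls", "ols")) {
  method <- match.arg(method)
  x <- as.matrix(points)
  stopifnot(!is.null(colnames(x)))
  p <- ncol(x)
  if (nrow(x) < p + 1) {
    stop("need at least ", p + 1, " points for ", p, " coefficients",
         call. = FALSE)
  }
  if (any(apply(x, 2, stats::sd) < .Machine$double.eps^0.5)) {
    bad <- colnames(x)[apply(x, 2, stats::sd) < .Machine$double.eps^0.5]
    stop("degenerate (zero-variance) column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)

  if (method == "tls") {
    ev <- eigen(crossprod(xc), symmetric = TRUE)
    a <- ev$vectors[, p]
  } else {
    if (is.null(response)) response <- colnames(x)[p]
    yi <- match(response, colnames(x))
    if (is.na(yi)) stop("unknown response column '", response, "'",
                        call. = FALSE)
    qr_x <- qr(cbind(1, x[, -yi, drop = FALSE]))
    if (qr_x$rank < p) {
      stop("rank-deficient regressors among: ",
           paste(colnames(x)[-yi], collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qr_x, x[, yi])
    a <- numeric(p)
    a[yi] <- -1
    a[-yi] <- beta[-1]
    a <- a / sqrt(sum(a^2))
  }
  names(a) <- colnames(x)
  # orient so the largest-magnitude coefficient is positive
  j <- which.max(abs(a))
  if (a[j] < 0) a <- -a
  const <- sum(a * mu)

  if (is.null(response)) response <- names(a)[which.max(abs(a))]
  yi <- match(response, colnames(x))
  fit <- stats::lm.fit(cbind(1, x[, -yi, drop = FALSE]), x[, yi])
  r2 <- 1 - sum(fit$residuals^2) / sum((x[, yi] - mean(x[, yi]))^2)

  structure(list(coefficients = a, constant = const, r_squared = r2,
                 response = response, method = method, n = nrow(x),
                 points = tibble::as_tibble(as.data.frame(x))),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  terms <- paste(sprintf("%+.3f*%s", x$coefficients,
                         names(x$coefficients)), collapse = " ")
  cat("<plane_fit>", terms, "=", format(x$constant, digits = 6), "\n")
  cat("  method:", x$method, " R^2 (", x$response, "on rest):",
      round(x$r_squared, 4), " n:", x$n, "\n")
  invisible(x)
}

#' @export
tidy.plane_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' @export
glance.plane_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, constant = x$constant,
                 n = x$n, method = x$method)
}

#' Complementarity analysis of an orp ensemble
#'
#' Fits a hyperplane to the top-K final scaling factors of the chosen
#' currents and reports, in addition, the 2-D composite replot: the
#' coefficient-weighted sum of same-sign ("inward") currents against the
#' opposite-sign ("outward") combination, with its regression R^2.  High
#' plane and replot R^2 indicate that the currents trade off along a
#' degenerate direction while producing nearly identical waveforms.
#'
#' @param orp An `orp_result`.
#' @param currents Currents to analyze (default the slow-depolarization
#'   trio `ha`, `K1`, `bNSC` intersected with the optimized set).
#' @param k Top-K runs to use (default 20).
#' @param method Plane fit method, see [fit_plane()].
#' @return List: `plane` (a `plane_fit`), `replot_r2`, `replot` tibble
#'   (`x`, `y`), `currents`, `k`.
#' @export
complementarity_report <- function(orp, currents = NULL, k = 20,
                                   method = "tls") {
  if (is.null(currents)) {
    currents <- intersect(c("ha", "K1", "bNSC"), orp$selected)
  }
  missing_cur <- setdiff(currents, orp$selected)
  if (length(missing_cur)) {
    stop("currents not optimized in this orp test: ",
         paste(missing_cur, collapse = ", "), call. = FALSE)
  }
  fin <- orp$finals[is.finite(orp$finals$final_mse), ]
  if (nrow(fin) < k) stop("need at least ", k, " usable runs", call. = FALSE)
  top <- dplyr::slice_min(fin, .data$final_mse, n = k, with_ties = FALSE)
  pts <- as.matrix(top[, paste0("sf_", currents)])
  colnames(pts) <- currents
  plane <- fit_plane(pts, method = method)

  a <- plane$coefficients
  pos <- names(a)[a >= 0]
  neg <- names(a)[a < 0]
  if (!length(pos) || !length(neg)) {
    replot_r2 <- NA_real_
    replot <- tibble::tibble(x = numeric(), y = numeric())
  } else {
    xs <- as.numeric(pts[, pos, drop = FALSE] %*% a[pos])
    ys <- as.numeric(pts[, neg, drop = FALSE] %*% (-a[neg]))
    fit <- stats::lm(ys ~ xs)
    replot_r2 <- summary(fit)$r.squared
    replot <- tibble::tibble(x = xs, y = ys)
  }
  list(plane = plane, replot_r2 = replot_r2, replot = replot,
       currents = currents, k = k)
}
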