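#' ICA backend configuration
#'
#' @param name backend algorithm: `"fastica"` (fixed-point, logcosh
#'   contrast), `"infomax"` (extended information-maximization), or `"jade"`
#'   (joint diagonalization of cumulant matrices).
#' @param max_iter maximum backend iterations.
#' @param tol convergence tolerance of the backend.
#' @param retries number of additional attempts with fresh random rotations
#'   after a non-converged fit.
#' @return An object of class `backend_spec`.
#' @examples
#' backend_spec("fastica")
#' @export
backend_spec <- function(name = c("fastica", "infomax", "jade"),
                         max_iter = 500L, tol = 1e-6, retries = 3L) {
  name <- match.arg(name)
  max_iter <- as.integer(max_iter)
  retries <- as.integer(retries)
  if (retries < 1L) stop("'retries' must be at least 1")
  if (tol <= 0) stop("'tol' must be positive")
  structure(list(name = name, max_iter = max_iter, tol = tol,
                 retries = retries), class = "backend_spec")
}

as_backend <- function(backend) {
  if (inherits(backend, "backend_spec")) return(backend)
  if (is.character(backend) && length(backend) == 1L) return(backend_spec(backend))
  stop("'backend' must be a backend_spec or a backend name")
}

# Center rows and project onto the q leading principal directions, rescaling
# every projected row to unit sample variance.  For q beyond the numerical
# rank of X the extra directions carry amplified numerical noise; rescaling
# them to unit variance (rather than dividing by a near-zero eigenvalue)
# keeps the backend input exactly full rank, which is what lets the
# split-half statistic collapse under over-decomposition.
whiten_q <- function(Xc, q) {
  n <- ncol(Xc)
  e <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
  Z <- t(e$vectors[, seq_len(q), drop = FALSE]) %*% Xc
  v <- rowSums(Z^2) / (n - 1)
  if (any(v == 0)) return(NULL) # exactly degenerate direction: no data there
  list(Z = Z / sqrt(v), basis = e$vectors[, seq_len(q), drop = FALSE],
       scale = sqrt(v))
}

run_backend <- function(Z, q, backend, rot) {
  zt <- t(Z)
  res <- switch(backend$name,
    fastica = ica::icafast(zt, nc = q, center = FALSE, maxit = backend$max_iter,
                           tol = backend$tol, Rmat = rot),
    infomax = ica::icaimax(zt, nc = q, center = FALSE, maxit = backend$max_iter,
                           tol = backend$tol, Rmat = rot),
    jade = ica::icajade(zt, nc = q, center = FALSE, maxit = backend$max_iter,
                        tol = backend$tol, Rmat = rot))
  res
}

#' Fit an ICA model with a requested number of components
#'
#' Centers the channels, whitens to exactly `q` principal directions, and
#' runs the requested backend.  Non-converged fits are retried with fresh
#' random rotation initializations on derived sub-seeds; only after all
#' retries fail is a result with `converged = FALSE` returned (callers
#' decide policy).  Component order and sign are backend-arbitrary and must
#' not be relied upon.
#'
#' @param X a [signal_matrix()] or numeric matrix (channels in rows).
#' @param q requested number of components, `2 <= q <= nrow(X)`.
#' @param backend a [backend_spec()] or backend name.
#' @param seed integer seed controlling the rotation initialization.
#' @return An object of class `ica_result`: `components` (`q x n`, unit
#'   variance rows), `mixing_estimate` (`p x q`), `unmixing` (`q x p`,
#'   applied to the centered data), `center` (row means), `method`,
#'   `requested_q`, `converged`, `iterations` and `seed`.
#' @examples
#' s <- simulate_sources(3, 256, seed = 1)
#' m <- mix_signals(s, p = 8, seed = 2)
#' fit <- fit_ica(m$signals, q = 3, seed = 3)
#' fit$converged
#' @export
fit_ica <- function(X, q, backend = backend_spec("fastica"), seed = 1) {
  backend <- as_backend(backend)
  m <- signal_data(X)
  p <- nrow(m)
  n <- ncol(m)
  q <- as.integer(q)
  if (q < 2L) stop("'q' must be at least 2")
  if (q > p) {
    stop("'q' = ", q, " exceeds the number of channels p = ", p,
         ": the underdetermined regime is not supported")
  }
  if (n <= q) stop("signal length n must exceed q")
  center <- rowMeans(m)
  Xc <- m - center
  wh <- whiten_q(Xc, q)

  result <- NULL
  converged <- FALSE
  used_seed <- seed
  if (!is.null(wh)) {
    for (attempt in 0:backend$retries) {
      used_seed <- seed + 1000L * attempt
      # JADE is a deterministic joint diagonalization: it takes no random
      # restart, and a non-identity start rotation survives into its output
      rot <- if (backend$name == "jade") diag(q) else
        with_seed(used_seed, qr.Q(qr(matrix(stats::rnorm(q * q), q, q))))
      result <- tryCatch(run_backend(wh$Z, q, backend, rot),
                         error = function(e) NULL)
      if (!is.null(result) && nrow(result$M) == q && isTRUE(result$converged)) {
        converged <- TRUE
        break
      }
    }
  }

  if (is.null(result) || nrow(result$M %||% matrix(nrow = 0, ncol = 0)) != q) {
    return(structure(list(components = NULL, mixing_estimate = NULL,
                          unmixing = NULL, center = center,
                          method = backend$name, requested_q = q,
                          converged = FALSE, iterations = NA_integer_,
                          seed = seed),
                     class = "ica_result"))
  }

  comps <- t(result$S)
  csd <- apply(comps, 1L, stats::sd)
  comps <- comps / csd
  # comps rows are an orthogonal rotation of the unit-variance whitened rows,
  # so comps %*% t(comps) = (n-1) I; solve anyway for numerical safety.
  G <- tcrossprod(comps)
  mixing <- t(solve(G, comps %*% t(Xc)))
  rotation <- comps %*% t(wh$Z) / (n - 1) # q x q: whitened rows -> components
  unmixing <- rotation %*% (t(wh$basis) / wh$scale)
  structure(list(components = comps, mixing_estimate = mixing,
                 unmixing = unmixing, center = center,
                 method = backend$name, requested_q = q,
                 converged = converged, iterations = result$iter,
                 seed = seed),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat("ica_result:", x$method, "with q =", x$requested_q,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Reconstruct a signal matrix from a fitted ICA model
#'
#' Returns the rank-`q` reconstruction `mean(X) + A_hat S_hat`, i.e. the
#' projection of the centered data onto the fitted component subspace plus
#' the channel means.
#'
#' @param result a [fit_ica()] result carrying components; a non-converged
#'   fit reconstructs with a warning (the projection does not depend on the
#'   unconverged rotation).
#' @param original the [signal_matrix()] (or matrix) the model was fitted to;
#'   used for dimension checking and channel labels.
#' @return A [signal_matrix()] holding the reconstruction.
#' @export
reconstruct <- function(result, original) {
  if (!inherits(result, "ica_result")) stop("'result' must be an ica_result")
  if (is.null(result$components)) {
    stop("cannot reconstruct: the fit produced no components")
  }
  if (!isTRUE(result$converged)) {
    # the rank-q reconstruction is the projection onto the component
    # subspace and does not depend on the (unconverged) rotation
    warning("reconstructing from a non-converged fit")
  }
  m <- signal_data(original)
  if (nrow(m) != length(result$center) || ncol(m) != ncol(result$components)) {
    stop("dimensions of 'original' (", nrow(m), " x ", ncol(m),
         ") do not match the fitted model (", length(result$center), " x ",
         ncol(result$components), ")")
  }
  xhat <- result$mixing_estimate %*% result$components + result$center
  labels <- if (inherits(original, "signal_matrix")) original$channel_labels else NULL
  suppressWarnings(signal_matrix(xhat, channel_labels = labels))
}
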