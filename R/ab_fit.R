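#' Fit the aspect Bernoulli model
#'
#' Decomposes a binary genome-by-function matrix `Y` (G x F) into `K` latent
#' aspects. Each cell is modelled as an independent Bernoulli draw,
#' `Y_gf ~ Bernoulli(V_gf)` with `V = Gamma %*% Beta`, where the rows of
#' `Gamma` (G x K) are probability vectors giving each genome's aspect
#' weights, and `Beta` (K x F) holds each aspect's per-function presence
#' probabilities. A `Beta_kf` near 1 means function `f` is strongly
#' associated with aspect `k`; a `Gamma_gk` near 1 means genome `g` is
#' dominated by aspect `k`.
#'
#' The likelihood is maximized by expectation maximization: each cell carries
#' a latent indicator naming the aspect that generated it, responsibilities
#' are computed by Bayes' rule from the current parameters, and the M-step
#' averages them (`Gamma`) or takes responsibility-weighted presence
#' frequencies (`Beta`). EM is run from `n_restarts` random initializations
#' (aspect weights from a symmetric flat Dirichlet, presence probabilities
#' uniform on (0.25, 0.75) to avoid frozen boundary starts) and the restart
#' with the highest final log-likelihood is returned. Each restart stops
#' after `n_iter` iterations or when the relative log-likelihood change drops
#' below `tol`, whichever happens first.
#'
#' Aspects are unordered by construction; for stable output they are sorted
#' by descending total genome weight `sum_g Gamma_gk`.
#'
#' @param matrix a [binary_matrix] (or coercible 0/1 matrix), genomes in rows.
#' @param K number of aspects, `1 <= K <= F`.
#' @param n_iter maximum EM iterations per restart (default 500; the
#'   likelihood typically plateaus by then on matrices of a few thousand
#'   genomes).
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed; restart `r` uses `seed + r - 1`, so individual
#'   restarts are reproducible. Required for reproducible fits.
#' @param tol relative log-likelihood change below which a restart stops.
#'
#' @return An object of class `ab_fit`: a list with components `gamma`
#'   (G x K), `beta` (K x F), `K`, `loglik_trace` (per-iteration total
#'   log-likelihood of the winning restart, non-decreasing), `n_iter`
#'   (iterations actually run), `seed` (seed of the winning restart),
#'   `restart_loglik` (final log-likelihood of every restart), `converged`,
#'   and `Y` (the data, as a `binary_matrix`).
#'
#' @examples
#' Y <- binary_matrix(rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
#'                          matrix(c(0, 1), 10, 2, byrow = TRUE)))
#' fit <- fit_ab(Y, K = 2, n_iter = 200, n_restarts = 2, seed = 1)
#' round(coef(fit)$beta, 2)
#' @seealso [responsibilities()], [ab_scores()], [predict.ab_fit()]
#' @export
fit_ab <- function(matrix, K, n_iter = 500L, n_restarts = 10L, seed = NULL,
                   tol = 1e-10) {
  Y <- as_binary_matrix(matrix)
  G <- nrow(Y); F <- ncol(Y)
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("K must be a positive integer", call. = FALSE)
  if (K > F)
    stop("K (", K, ") cannot exceed the number of functions (", F, ")",
         call. = FALSE)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - n_restarts, 1L)
  seed <- as.integer(seed)
  Yd <- unclass(Y); storage.mode(Yd) <- "double"

  best <- NULL
  restart_ll <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    rseed <- seed + r - 1L
    set.seed(rseed)
    gamma0 <- matrix(rgamma(G * K, shape = 1), G, K)
    gamma0 <- gamma0 / rowSums(gamma0)
    beta0 <- matrix(runif(K * F, 0.25, 0.75), K, F)
    res <- tryCatch(
      ab_em_run(Yd, gamma0, beta0, as.integer(n_iter), tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("restart ", r, " aborted: ", conditionMessage(res),
              call. = FALSE)
      next
    }
    ll <- res$loglik_trace[length(res$loglik_trace)]
    restart_ll[r] <- ll
    if (is.null(best) || ll > best$loglik) {
      best <- list(res = res, loglik = ll, seed = rseed)
    }
  }
  if (is.null(best))
    stop("all EM restarts failed", call. = FALSE)

  gamma <- best$res$gamma
  beta <- best$res$beta
  ord <- order(colSums(gamma), decreasing = TRUE)
  gamma <- gamma[, ord, drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  aspect_names <- paste0("aspect", seq_len(K))
  dimnames(gamma) <- list(rownames(Y), aspect_names)
  dimnames(beta) <- list(aspect_names, colnames(Y))

  structure(list(
    gamma = gamma,
    beta = beta,
    K = K,
    loglik_trace = best$res$loglik_trace,
    n_iter = best$res$n_iter,
    converged = best$res$converged,
    seed = best$seed,
    restart_loglik = restart_ll,
    Y = Y,
    call = match.call()
  ), class = "ab_fit")
}

#' Per-cell aspect responsibilities
#'
#' Returns, for every cell (g, f), the posterior probability that each aspect
#' generated the observed value: for `Y_gf = 1` this is
#' `Gamma_gk * Beta_kf / V_gf` (Bayes' rule), and for `Y_gf = 0` it is
#' `Gamma_gk * (1 - Beta_kf) / (1 - V_gf)`.
#'
#' @param fit an [fit_ab()] result.
#' @param matrix the data matrix; defaults to the one stored in the fit. Must
#'   match the fit's dimensions.
#' @return a G x F x K array; for every (g, f) the K values sum to 1.
#' @export
responsibilities <- function(fit, matrix = fit$Y) {
  stopifnot(inherits(fit, "ab_fit"))
  Y <- as_binary_matrix(matrix)
  if (nrow(Y) != nrow(fit$gamma) || ncol(Y) != ncol(fit$beta))
    stop("matrix dimensions do not match the fit", call. = FALSE)
  K <- fit$K
  out <- array(NA_real_, dim = c(nrow(Y), ncol(Y), K),
               dimnames = list(rownames(Y), colnames(Y),
                               colnames(fit$gamma)))
  Yd <- unclass(Y)
  # numerators of Bayes' rule; normalizing by their sum (= V for Y = 1,
  # 1 - V for Y = 0) is exact and immune to V underflowing at the boundary
  for (k in seq_len(K)) {
    num1 <- fit$gamma[, k] %o% fit$beta[k, ]
    num0 <- fit$gamma[, k] %o% (1 - fit$beta[k, ])
    out[, , k] <- Yd * num1 + (1 - Yd) * num0
  }
  den <- apply(out, c(1, 2), sum)
  for (k in seq_len(K))
    out[, , k] <- ifelse(den > 0, out[, , k] / den,
                         matrix(fit$gamma[, k], nrow(Y), ncol(Y)))
  out
}

clip_unit <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

#' @export
print.ab_fit <- function(x, ...) {
  cat("Aspect Bernoulli fit\n")
  cat(sprintf("  %d genomes x %d functions, K = %d aspects\n",
              nrow(x$gamma), ncol(x$beta), x$K))
  cat(sprintf("  log-likelihood %.3f after %d iterations (%s)\n",
              logLik(x), x$n_iter,
              if (isTRUE(x$converged)) "converged" else "iteration cap"))
  cat(sprintf("  best of %d restarts (winning seed %d)\n",
              length(x$restart_loglik), x$seed))
  invisible(x)
}

#' @export
summary.ab_fit <- function(object, ...) {
  V <- fitted(object)
  s <- list(
    K = object$K,
    dim = dim(object$Y),
    loglik = as.numeric(logLik(object)),
    n_iter = object$n_iter,
    converged = object$converged,
    restart_loglik = object$restart_loglik,
    aspect_weight = colSums(object$gamma),
    density_observed = mean(object$Y),
    density_fitted = mean(V),
    mean_abs_residual = mean(abs(unclass(object$Y) - V))
  )
  class(s) <- "summary.ab_fit"
  s
}

#' @export
print.summary.ab_fit <- function(x, ...) {
  cat("Aspect Bernoulli fit\n")
  cat(sprintf("  %d genomes x %d functions, K = %d\n",
              x$dim[1], x$dim[2], x$K))
  cat(sprintf("  log-likelihood %.3f (%d iterations%s)\n", x$loglik,
              x$n_iter, if (isTRUE(x$converged)) ", converged" else ""))
  cat(sprintf("  observed density %.3f, fitted density %.3f, mean |Y - V| %.3f\n",
              x$density_observed, x$density_fitted, x$mean_abs_residual))
  cat("  total genome weight per aspect:\n")
  print(round(x$aspect_weight, 2))
  invisible(x)
}

#' @export
coef.ab_fit <- function(object, ...) {
  list(gamma = object$gamma, beta = object$beta)
}

#' @export
fitted.ab_fit <- function(object, ...) {
  object$gamma %*% object$beta
}

#' @export
logLik.ab_fit <- function(object, ...) {
  ll <- object$loglik_trace[length(object$loglik_trace)]
  structure(ll,
            df = nrow(object$gamma) * (object$K - 1) +
              object$K * ncol(object$beta),
            nobs = length(object$Y), class = "logLik")
}

#' Predict aspect weights or presence probabilities
#'
#' For new genomes (rows over the same function set), aspect weights are
#' obtained by "folding in": EM is run on the new rows with `Beta` held fixed
#' at the fitted values, updating only the genome aspect weights.
#'
#' @param object an `ab_fit`.
#' @param newdata optional binary matrix over the same functions; default is
#'   the training matrix.
#' @param type `"prob"` for the cell probabilities `V = Gamma %*% Beta`, or
#'   `"gamma"` for the genome aspect weights.
#' @param n_iter fold-in EM iterations for new genomes.
#' @param ... unused.
#' @export
predict.ab_fit <- function(object, newdata = NULL,
                           type = c("prob", "gamma"), n_iter = 200L, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    gamma <- object$gamma
  } else {
    Y <- as_binary_matrix(newdata)
    if (ncol(Y) != ncol(object$beta))
      stop("newdata must cover the same ", ncol(object$beta), " functions",
           call. = FALSE)
    gamma <- fold_in_gamma(unclass(Y), object$beta, n_iter)
    dimnames(gamma) <- list(rownames(Y), colnames(object$gamma))
  }
  if (type == "gamma") gamma else gamma %*% object$beta
}

fold_in_gamma <- function(Y, beta, n_iter) {
  G <- nrow(Y); K <- nrow(beta)
  gamma <- matrix(1 / K, G, K)
  for (it in seq_len(n_iter)) {
    V <- clip_unit(gamma %*% beta)
    gnew <- matrix(0, G, K)
    for (k in seq_len(K)) {
      W <- Y * ((gamma[, k] %o% beta[k, ]) / V) +
        (1 - Y) * ((gamma[, k] %o% (1 - beta[k, ])) / (1 - V))
      gnew[, k] <- rowMeans(W)
    }
    gamma <- gnew / rowSums(gnew)
  }
  gamma
}

#' Simulate presence/absence matrices from a fitted model
#'
#' Draws each cell independently as `Bernoulli(V_gf)` with
#' `V = Gamma %*% Beta` from the fit.
#'
#' @param object an `ab_fit`.
#' @param nsim number of matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` [binary_matrix] objects.
#' @export
simulate.ab_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- clip_unit(fitted(object))
  lapply(seq_len(nsim), function(i) {
    suppressWarnings(binary_matrix(
      matrix(rbinom(length(V), 1L, V), nrow(V), ncol(V),
             dimnames = dimnames(V))))
  })
}

#' @export
residuals.ab_fit <- function(object,
                             type = c("response", "pearson", "deviance"),
                             ...) {
  type <- match.arg(type)
  Y <- unclass(object$Y); storage.mode(Y) <- "double"
  V <- clip_unit(fitted(object))
  r <- Y - V
  switch(type,
         response = r,
         pearson = r / sqrt(V * (1 - V)),
         deviance = sign(r) * sqrt(-2 * (Y * log(V) + (1 - Y) * log(1 - V))))
}

#' @export
plot.ab_fit <- function(x, ...) {
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "l",
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "Aspect Bernoulli EM trace", ...)
  invisible(x)
}

#' Serialize a fit to a directory of delimited tables
#'
#' Writes `gamma.tsv`, `beta.tsv`, `loglik.tsv` and a `metadata.yaml` sidecar
#' (K, seed, iterations, convergence flag) so a fit can be archived or reused
#' without R serialization formats.
#'
#' @param fit an `ab_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ab_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "ab_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_named_table(fit$gamma, file.path(dir, "gamma.tsv"), "genome_id")
  write_named_table(fit$beta, file.path(dir, "beta.tsv"), "aspect")
  write.table(data.frame(iteration = seq_along(fit$loglik_trace),
                         loglik = fit$loglik_trace),
              file.path(dir, "loglik.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(K = fit$K, seed = fit$seed, n_iter = fit$n_iter,
                        converged = fit$converged),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a serialized fit
#'
#' Restores the parameter matrices written by [write_ab_fit()]. The data
#' matrix is not part of the serialization; score computations on a restored
#' fit must pass it explicitly.
#'
#' @param dir directory written by [write_ab_fit()].
#' @return an `ab_fit` with a `NULL` `Y`.
#' @export
read_ab_fit <- function(dir) {
  gamma <- read_named_table(file.path(dir, "gamma.tsv"))
  beta <- read_named_table(file.path(dir, "beta.tsv"))
  ll <- read.table(file.path(dir, "loglik.tsv"), header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  structure(list(gamma = gamma, beta = beta, K = meta$K,
                 loglik_trace = ll$loglik, n_iter = meta$n_iter,
                 converged = meta$converged, seed = meta$seed,
                 restart_loglik = NULL, Y = NULL, call = NULL),
            class = "ab_fit")
}

write_named_table <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_named_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
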