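#' Marginal attribution scores r
#'
#' For each function `f` and aspect `k`, the average over all genomes of the
#' posterior probability that aspect `k` generated a presence of `f`:
#' `r_fk = (1/G) sum_g Gamma_gk * Beta_kf / V_gf`. The average runs over
#' every genome, evaluating the presence-case Bayes expression whether or not
#' the genome actually carries `f` (the marginal reading of the score). With
#' `conditional = TRUE` the average instead runs only over the genomes with
#' `Y_gf = 1`; this variant is exposed for comparison but is not the default.
#'
#' Under the default, `sum_k r_fk = 1` for every function.
#'
#' @param fit an [fit_ab()] result.
#' @param matrix the data matrix (needed only for `conditional = TRUE`);
#'   defaults to the matrix stored in the fit.
#' @param conditional restrict the average to genomes carrying the function.
#' @return an F x K matrix.
#' @export
attribution_scores <- function(fit, matrix = fit$Y, conditional = FALSE) {
  stopifnot(inherits(fit, "ab_fit"))
  gamma <- fit$gamma; beta <- fit$beta
  K <- fit$K
  # Bayes numerators Gamma_gk * Beta_kf, normalized per cell by their sum
  # over aspects (= V_gf, but exact even where V underflows); cells with
  # zero total presence probability fall back to the prior Gamma row
  V <- gamma %*% beta
  r <- base::matrix(NA_real_, ncol(beta), K,
                    dimnames = list(colnames(beta), rownames(beta)))
  if (conditional) {
    Y <- as_binary_matrix(matrix)
    if (nrow(Y) != nrow(gamma) || ncol(Y) != ncol(beta))
      stop("matrix dimensions do not match the fit", call. = FALSE)
    Yd <- unclass(Y)
    npres <- colSums(Yd)
    for (k in seq_len(K)) {
      M <- ifelse(V > 0, (gamma[, k] %o% beta[k, ]) / V,
                  matrix(gamma[, k], nrow(gamma), ncol(beta)))
      r[, k] <- ifelse(npres > 0, colSums(M * Yd) / npres, NA_real_)
    }
    if (anyNA(r))
      warning("functions absent from every genome have undefined ",
              "conditional scores (NA)", call. = FALSE)
  } else {
    for (k in seq_len(K)) {
      M <- ifelse(V > 0, (gamma[, k] %o% beta[k, ]) / V,
                  matrix(gamma[, k], nrow(gamma), ncol(beta)))
      r[, k] <- colMeans(M)
    }
  }
  r
}

#' Probabilistic representatives of each aspect
#'
#' Genome `g` belongs to `A_k` when aspect `k` carries its largest aspect
#' weight AND that weight exceeds `2/K`; the threshold drops genomes whose
#' aspect weights are nearly uniform. The sets are pairwise disjoint; genomes
#' failing the threshold belong to no set. Argmax ties go to the lowest
#' aspect index with a warning (note that for `K = 2` the threshold is 1, so
#' no genome can qualify).
#'
#' @param fit an [fit_ab()] result.
#' @return a list of `K` character vectors of genome IDs.
#' @export
probabilistic_representatives <- function(fit) {
  stopifnot(inherits(fit, "ab_fit"))
  gamma <- fit$gamma
  K <- fit$K
  kmax <- max.col(gamma, ties.method = "first")
  rowmax <- gamma[cbind(seq_len(nrow(gamma)), kmax)]
  qualify <- rowmax > 2 / K
  n_tied <- sum(qualify & rowSums(gamma == rowmax) > 1L)
  if (n_tied > 0L)
    warning(n_tied, " genome(s) had tied maximal aspect weights; ",
            "assigned to the lowest aspect index", call. = FALSE)
  reps <- lapply(seq_len(K), function(k)
    rownames(gamma)[qualify & kmax == k])
  names(reps) <- colnames(gamma)
  reps
}

#' Abundance adjustment q
#'
#' For aspect `k` with representative set `A_k`, the ratio of each function's
#' abundance within `A_k` to the mean function abundance within `A_k`:
#' `q_fk = sum_{g in A_k} Y_gf / ((1/F) sum_f sum_{g in A_k} Y_gf)`. The
#' adjustment upweights functions that are unusually common among the
#' aspect's representative genomes. An empty `A_k` (possible at small `K`,
#' where the `2/K` threshold can exclude everyone) or an all-zero one yields
#' a zero column with a warning rather than an error.
#'
#' @param representatives list of genome-ID sets from
#'   [probabilistic_representatives()].
#' @param matrix the [binary_matrix] the representatives were computed from.
#' @return an F x K matrix; columns of non-degenerate aspects average to 1.
#' @export
abundance_adjustment <- function(representatives, matrix) {
  Y <- as_binary_matrix(matrix)
  K <- length(representatives)
  q <- base::matrix(0, ncol(Y), K,
                    dimnames = list(colnames(Y), names(representatives)))
  for (k in seq_len(K)) {
    g <- representatives[[k]]
    if (length(g) == 0L) {
      warning("aspect ", k, " has no probabilistic representatives; ",
              "abundance adjustment set to zero", call. = FALSE)
      next
    }
    cs <- colSums(Y[g, , drop = FALSE])
    den <- mean(cs)
    if (den == 0) {
      warning("aspect ", k, "'s representatives carry no functions; ",
              "abundance adjustment set to zero", call. = FALSE)
      next
    }
    q[, k] <- cs / den
  }
  q
}

#' Combine attribution and abundance into guild scores
#'
#' The guild score is the elementwise product `s_fk = r_fk * q_fk`. Within
#' each aspect, functions are ranked by descending score; ties are broken by
#' ascending function ID so rankings are deterministic.
#'
#' @param r F x K attribution matrix ([attribution_scores()]).
#' @param q F x K abundance adjustment ([abundance_adjustment()]).
#' @return a list with `s` (F x K) and `ranked_functions` (per aspect, the
#'   function IDs in score order).
#' @export
guild_scores <- function(r, q) {
  if (!identical(dim(r), dim(q)))
    stop("r and q must have identical dimensions", call. = FALSE)
  s <- r * q
  fids <- rownames(s) %||% as.character(seq_len(nrow(s)))
  ranked <- lapply(seq_len(ncol(s)), function(k)
    fids[order(-s[, k], fids)])
  names(ranked) <- colnames(s)
  list(s = s, ranked_functions = ranked)
}

#' Score table for a fitted aspect Bernoulli model
#'
#' Convenience wrapper running the full post-processing chain:
#' [attribution_scores()] (r), [probabilistic_representatives()] (A_k),
#' [abundance_adjustment()] (q) and [guild_scores()] (s = r * q with per-
#' aspect rankings).
#'
#' @param fit an [fit_ab()] result.
#' @param matrix data matrix; defaults to the one in the fit.
#' @param conditional passed to [attribution_scores()].
#' @return an object of class `ab_scores` with components `r`, `q`, `s`
#'   (all F x K), `ranked_functions` (list of K ID vectors),
#'   `representatives` (list of K genome-ID vectors), `gamma`, and `K`.
#' @export
ab_scores <- function(fit, matrix = fit$Y, conditional = FALSE) {
  stopifnot(inherits(fit, "ab_fit"))
  Y <- as_binary_matrix(matrix)
  r <- attribution_scores(fit, Y, conditional = conditional)
  reps <- probabilistic_representatives(fit)
  q <- abundance_adjustment(reps, Y)
  gs <- guild_scores(r, q)
  structure(list(r = r, q = q, s = gs$s,
                 ranked_functions = gs$ranked_functions,
                 representatives = reps,
                 gamma = fit$gamma, K = fit$K),
            class = "ab_scores")
}

#' @export
print.ab_scores <- function(x, n = 5L, ...) {
  cat(sprintf("Aspect Bernoulli score table: %d functions x %d aspects\n",
              nrow(x$s), x$K))
  for (k in seq_len(x$K)) {
    top <- head(x$ranked_functions[[k]], n)
    cat(sprintf("  aspect %d (%d representatives): %s\n", k,
                length(x$representatives[[k]]),
                paste(top, collapse = ", ")))
  }
  invisible(x)
}

#' Write score tables as TSV
#'
#' `scores.tsv` holds one row per (aspect, rank): columns `aspect`, `rank`,
#' `function_id`, `r`, `q`, `s`. `representatives.tsv` holds `aspect`,
#' `genome_id`, `gamma`.
#'
#' @param scores an [ab_scores()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ab_scores <- function(scores, dir) {
  stopifnot(inherits(scores, "ab_scores"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(seq_len(scores$K), function(k) {
    fid <- scores$ranked_functions[[k]]
    data.frame(aspect = k, rank = seq_along(fid), function_id = fid,
               r = scores$r[fid, k], q = scores$q[fid, k],
               s = scores$s[fid, k], stringsAsFactors = FALSE)
  }))
  write.table(rows, file.path(dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reps <- do.call(rbind, lapply(seq_len(scores$K), function(k) {
    g <- scores$representatives[[k]]
    if (length(g) == 0L) return(NULL)
    data.frame(aspect = k, genome_id = g, gamma = scores$gamma[g, k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(reps))
    reps <- data.frame(aspect = integer(), genome_id = character(),
                       gamma = numeric())
  write.table(reps, file.path(dir, "representatives.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
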