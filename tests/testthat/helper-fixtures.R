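# Fixtures are generated in code; nothing is read from disk.

# random 0/1 matrix with unique labels
rand_bm <- function(G, F, p = 0.5, seed = 1) {
  set.seed(seed)
  suppressWarnings(binary_matrix(
    matrix(rbinom(G * F, 1L, p), G, F,
           dimnames = list(sprintf("g%03d", seq_len(G)),
                           sprintf("f%03d", seq_len(F))))))
}

# perfectly separated blocks: genome group b carries exactly the b-th
# group of functions
block_bm <- function(G = 40, F = 10, n_blocks = 2) {
  stopifnot(G %% n_blocks == 0, F %% n_blocks == 0)
  gpb <- G / n_blocks; fpb <- F / n_blocks
  vals <- matrix(0L, G, F)
  for (b in seq_len(n_blocks))
    vals[(b - 1) * gpb + seq_len(gpb), (b - 1) * fpb + seq_len(fpb)] <- 1L
  binary_matrix(vals)
}

# hand-built fit object for closed-form score checks
toy_fit <- function(gamma, beta, Y = NULL) {
  K <- ncol(gamma)
  dimnames(gamma) <- list(rownames(gamma) %||%
                            paste0("g", seq_len(nrow(gamma))),
                          paste0("aspect", seq_len(K)))
  dimnames(beta) <- list(paste0("aspect", seq_len(K)),
                         colnames(beta) %||% paste0("f", seq_len(ncol(beta))))
  structure(list(gamma = gamma, beta = beta, K = K,
                 loglik_trace = 0, n_iter = 0L, converged = TRUE,
                 seed = 0L, restart_loglik = 0, Y = Y),
            class = "ab_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# score table stub: only the ranked lists matter for guild construction
toy_scores <- function(ranked) {
  structure(list(ranked_functions = ranked, K = length(ranked)),
            class = "ab_scores")
}
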