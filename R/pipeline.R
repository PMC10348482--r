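#' Run the full guild-identification pipeline
#'
#' Fit, score, guild definition (both approaches), specificity reports and
#' serialized outputs in one call: the workflow a command-line user runs as
#' `guildab.R run`. All outputs are plain TSV plus a YAML manifest recording
#' every parameter and seed needed to reproduce the run bit-for-bit.
#'
#' Outputs written under `output_dir`: `gamma.tsv`, `beta.tsv`, `loglik.tsv`,
#' `metadata.yaml` (the fit), `scores.tsv`, `representatives.tsv`,
#' `guilds.tsv`, `mapbacks.tsv`, `confidence.tsv`, `expansion.tsv` and
#' `manifest.yaml`.
#'
#' @param input path to a TSV/CSV presence/absence table, or a
#'   [binary_matrix].
#' @param output_dir directory for results (created if needed).
#' @param K number of aspects (default 10 — pick via [ksweep()] for new
#'   data).
#' @param n_iter,n_restarts,seed EM controls, see [fit_ab()].
#' @param m fixed guild size for approach 1 (default 5).
#' @param min_genomes minimum mapback support for approach 2 (default 100).
#' @param top_window retained for the manifest; hit detection applies only to
#'   simulated data.
#' @param dialect,transpose,binarize_threshold passed to [read_matrix()] when
#'   `input` is a path.
#' @return `output_dir`, invisibly. The fitted `ab_fit` and guild list are
#'   attached as attributes `fit` and `guilds`.
#' @export
run_pipeline <- function(input, output_dir, K = 10L, n_iter = 500L,
                         n_restarts = 10L, seed = 1L, m = 5L,
                         min_genomes = 100L, top_window = 15L,
                         dialect = NULL, transpose = FALSE,
                         binarize_threshold = NULL) {
  Y <- if (is.character(input))
    read_matrix(input, dialect = dialect, transpose = transpose,
                binarize_threshold = binarize_threshold)
  else as_binary_matrix(input)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- fit_ab(Y, K = K, n_iter = n_iter, n_restarts = n_restarts,
                seed = seed)
  write_ab_fit(fit, output_dir)

  scores <- ab_scores(fit, Y)
  write_ab_scores(scores, output_dir)

  guilds <- list()
  for (k in seq_len(fit$K)) {
    guilds[[length(guilds) + 1L]] <- define_guild_fixed(scores, Y, k, m = m)
    guilds[[length(guilds) + 1L]] <-
      define_guild_min_mapback(scores, Y, k, min_genomes = min_genomes)
  }
  write_ab_guilds(guilds, output_dir)

  curves <- do.call(rbind, lapply(seq_len(fit$K), function(k) {
    cv <- expansion_curve(scores, Y, k,
                          max_size = min(20L, ncol(Y)))
    cbind(aspect = k, cv)
  }))
  write.table(curves, file.path(output_dir, "expansion.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  reports <- lapply(guilds, function(g)
    suppressWarnings(guild_confidence_report(Y, g)))
  write_ab_confidence(reports, Y, file.path(output_dir, "confidence.tsv"))

  manifest <- list(
    package = "guildAB",
    version = as.character(utils::packageVersion("guildAB")),
    input = if (is.character(input)) normalizePath(input) else "<in-memory>",
    G = nrow(Y), F = ncol(Y),
    K = as.integer(K), n_iter = as.integer(n_iter),
    n_restarts = as.integer(n_restarts), seed = as.integer(seed),
    m = as.integer(m), min_genomes = as.integer(min_genomes),
    top_window = as.integer(top_window),
    winning_restart_seed = fit$seed,
    loglik = as.numeric(logLik(fit))
  )
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))

  out <- output_dir
  attr(out, "fit") <- fit
  attr(out, "guilds") <- guilds
  invisible(out)
}
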