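#' Match planted guilds to aspects
#'
#' A planted guild "hits" aspect `k` when every one of its functions appears
#' within the first `top_window` entries of aspect `k`'s score-ranked
#' function list. A guild may hit no aspect (missed), exactly one (the ideal
#' case), or several (a sign of over-fitting: the guild is split or
#' duplicated across aspects).
#'
#' @param scores an [ab_scores()] object computed on a simulated dataset.
#' @param truth the `truth` component of an `ab_simulation` (or the
#'   simulation itself).
#' @param top_window how deep into each ranked list to look (default 15).
#'   Must be at least as large as the largest planted guild, otherwise a hit
#'   is impossible by construction.
#' @return a list, one integer vector of matching aspect indices per guild.
#' @export
detect_hits <- function(scores, truth, top_window = 15L) {
  stopifnot(inherits(scores, "ab_scores"))
  if (inherits(truth, "ab_simulation")) truth <- truth$truth
  top_window <- as.integer(top_window)
  sizes <- vapply(truth, function(t) length(t$functions), 1L)
  if (top_window < max(sizes))
    stop("top_window (", top_window, ") is smaller than the largest ",
         "planted guild (", max(sizes), "); hits are impossible",
         call. = FALSE)
  tops <- lapply(scores$ranked_functions, head, top_window)
  lapply(truth, function(t) {
    which(vapply(tops, function(tp) all(t$functions %in% tp), TRUE))
  })
}

#' Hit rate and extra hits
#'
#' `hit_rate` is the fraction of planted guilds matched by at least one
#' aspect; with three planted guilds all recovered it is 1 ("three hits per
#' dataset"). `extra_hits` counts surplus appearances: for each guild,
#' `max(0, matches - 1)`, summed over guilds. Extra hits flag over-fitting —
#' the same guild surfacing atop more than one aspect list.
#'
#' @param matches per-guild aspect lists from [detect_hits()].
#' @param n_guilds number of planted guilds (defaults to `length(matches)`).
#' @return a list with `hit_rate` and `extra_hits`.
#' @export
hit_metrics <- function(matches, n_guilds = length(matches)) {
  stopifnot(n_guilds >= 1L)
  nm <- vapply(matches, length, 1L)
  list(hit_rate = sum(nm >= 1L) / n_guilds,
       extra_hits = sum(pmax(0L, nm - 1L)))
}

#' Sweep the number of aspects K over replicate simulations
#'
#' For each replicate, plants the specified artificial guilds into the base
#' matrix, then for each K fits the aspect Bernoulli model, computes scores
#' and detects hits. Reports per-K means of hit rate and extra hits across
#' replicates. Replicate datasets are shared across K values so K is the
#' only thing varying. Fit failures are counted per K and excluded from the
#' means rather than aborting the sweep.
#'
#' @param base a [binary_matrix] background.
#' @param specs a [guild_spec()] or list of them.
#' @param K_range integer vector of K values to sweep.
#' @param n_replicates replicates per K (default 20; increase for smoother
#'   curves).
#' @param seed integer seed driving both dataset generation and fits.
#' @param n_iter,n_restarts EM controls passed to [fit_ab()].
#' @param top_window passed to [detect_hits()].
#' @param verbose print one progress line per (K, replicate) to stderr.
#' @return an object of classes `ab_ksweep` and `data.frame` with columns
#'   `K`, `hit_rate`, `extra_hits`, `n_replicates`, `n_failed`.
#' @seealso [select_k()], [plot.ab_ksweep()]
#' @export
ksweep <- function(base, specs, K_range, n_replicates = 20L, seed = 1L,
                   n_iter = 500L, n_restarts = 10L, top_window = 15L,
                   verbose = FALSE) {
  K_range <- sort(unique(as.integer(K_range)))
  stopifnot(length(K_range) >= 1L, all(K_range >= 1L))
  seed <- as.integer(seed)
  sims <- generate_replicates(base, specs, n_replicates, seed)
  n_guilds <- length(sims[[1L]]$truth)
  out <- data.frame(K = K_range, hit_rate = NA_real_,
                    extra_hits = NA_real_,
                    n_replicates = as.integer(n_replicates),
                    n_failed = 0L)
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    hr <- eh <- numeric(0)
    failed <- 0L
    for (r in seq_along(sims)) {
      if (verbose)
        message(sprintf("ksweep: K = %d, replicate %d/%d", K, r,
                        length(sims)))
      res <- tryCatch({
        fit <- fit_ab(sims[[r]]$matrix, K = K, n_iter = n_iter,
                      n_restarts = n_restarts,
                      seed = seed + 1000L * i + r)
        sc <- suppressWarnings(ab_scores(fit))
        hit_metrics(detect_hits(sc, sims[[r]]$truth, top_window),
                    n_guilds)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        warning("fit failed at K = ", K, ", replicate ", r, ": ",
                conditionMessage(res), call. = FALSE)
      } else {
        hr <- c(hr, res$hit_rate)
        eh <- c(eh, res$extra_hits)
      }
    }
    out$hit_rate[i] <- if (length(hr)) mean(hr) else NA_real_
    out$extra_hits[i] <- if (length(eh)) mean(eh) else NA_real_
    out$n_failed[i] <- failed
  }
  attr(out, "seed") <- seed
  attr(out, "top_window") <- as.integer(top_window)
  class(out) <- c("ab_ksweep", "data.frame")
  out
}

#' Recommend K from a sweep
#'
#' The heuristic: a good K sits where the hit rate is maximized while extra
#' hits remain zero. Among the swept K values whose mean extra hits are at
#' most `tol` (default 0.05, absorbing simulation noise around zero), the
#' ones attaining the maximal hit rate are returned. When no K keeps extra
#' hits near zero the recommendation is empty and a diagnostic attribute
#' explains why.
#'
#' @param result an [ksweep()] result (a data.frame with `K`, `hit_rate`,
#'   `extra_hits` columns works too).
#' @param tol tolerance on mean extra hits counted as "zero".
#' @return integer vector of recommended K values (possibly empty), with a
#'   `diagnostic` attribute when empty.
#' @export
select_k <- function(result, tol = 0.05) {
  stopifnot(all(c("K", "hit_rate", "extra_hits") %in% names(result)))
  if (nrow(result) < 3L)
    warning("sweep covers fewer than 3 K values; recommendation is weakly ",
            "supported", call. = FALSE)
  ok <- !is.na(result$extra_hits) & result$extra_hits <= tol &
    !is.na(result$hit_rate)
  if (!any(ok)) {
    out <- integer(0)
    attr(out, "diagnostic") <- paste0(
      "no swept K kept mean extra hits <= ", tol,
      "; the model over-fits across the whole range — extend the sweep ",
      "to smaller K")
    return(out)
  }
  best <- max(result$hit_rate[ok])
  sort(result$K[ok & result$hit_rate >= best - 1e-12])
}

#' @export
print.ab_ksweep <- function(x, ...) {
  cat("Aspect-count sweep over planted-guild simulations\n")
  print.data.frame(x, row.names = FALSE, ...)
  rec <- select_k(x)
  if (length(rec))
    cat("recommended K:", paste(rec, collapse = ", "), "\n")
  else
    cat(attr(rec, "diagnostic"), "\n")
  invisible(x)
}

#' Hit-rate and extra-hit curves across K
#'
#' Two stacked panels: mean hit rate (top) and mean extra hits (bottom)
#' against K. The usable K region is where the top curve has saturated while
#' the bottom one is still flat at zero.
#'
#' @param x an [ksweep()] result.
#' @param ... passed to the underlying plot calls.
#' @export
plot.ab_ksweep <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$K, x$hit_rate, type = "b", pch = 19, ylim = c(0, 1),
       xlab = "K (number of aspects)", ylab = "mean hit rate", ...)
  plot(x$K, x$extra_hits, type = "b", pch = 19,
       ylim = c(0, max(1, x$extra_hits, na.rm = TRUE)),
       xlab = "K (number of aspects)", ylab = "mean extra hits", ...)
  invisible(x)
}
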