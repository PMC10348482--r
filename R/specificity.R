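#' Association-rule confidence between two functions
#'
#' `Conf(A -> B)` is the fraction of genomes carrying function A that also
#' carry function B: `sum_g Y_gA * Y_gB / sum_g Y_gA`. It is directional —
#' `Conf(A -> B)` and `Conf(B -> A)` differ in general. When no genome in
#' scope carries A the ratio is undefined and `NA` is returned (never coerced
#' to 0 or 1, which would bias minimum summaries).
#'
#' @param matrix a [binary_matrix].
#' @param A,B function IDs (antecedent, consequent).
#' @param genomes optional genome-ID subset restricting the computation
#'   (e.g. a guild's mapback genomes or their complement).
#' @return a value in `[0, 1]`, or `NA` when the antecedent has no support.
#' @export
confidence <- function(matrix, A, B, genomes = NULL) {
  Y <- as_binary_matrix(matrix)
  for (fn in c(A, B))
    if (!fn %in% colnames(Y))
      stop("unknown function ID: ", fn, call. = FALSE)
  if (!is.null(genomes)) {
    unknown <- setdiff(genomes, rownames(Y))
    if (length(unknown) > 0L)
      stop("unknown genome ID(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    Y <- Y[genomes, , drop = FALSE]
  }
  den <- sum(Y[, A])
  if (den == 0) return(NA_real_)
  sum(Y[, A] * Y[, B]) / den
}

# All ordered-pair confidences among `fns`, restricted to rows `genomes`.
# C[A, B] = co-occurrence count / antecedent count; rows with zero
# antecedent support become NA.
conf_matrix <- function(Y, fns, genomes) {
  sub <- unclass(Y)[genomes, fns, drop = FALSE]
  storage.mode(sub) <- "double"
  co <- crossprod(sub)           # co[A, B] = # genomes with both
  den <- diag(co)                # # genomes with antecedent
  out <- sweep(co, 1L, den, "/") # row A divided by support of A
  out[den == 0, ] <- NA_real_
  dimnames(out) <- list(fns, fns)
  out
}

#' Guild specificity report
#'
#' Computes forward and reverse confidences for every ordered pair of guild
#' functions in three scopes: the guild's mapback genomes, the outgroup (all
#' other genomes), and the whole dataset. Within the mapback genomes every
#' confidence is 1 by construction (each mapback genome carries every guild
#' function), so the informative numbers are the outgroup ones: low outgroup
#' confidence means the pair co-occurs essentially only inside the guild.
#'
#' Summaries (mean and minimum outgroup confidence) omit the diagonal, which
#' is 1 by definition, and skip undefined cells (antecedent absent from the
#' outgroup), reporting how many were skipped.
#'
#' @param matrix the [binary_matrix] the guild was derived from.
#' @param guild an `ab_guild` (see [define_guild_fixed()]).
#' @return an object of class `ab_confidence` with components `guild`,
#'   `mapback`, `outgroup`, `overall` (square confidence matrices over the
#'   guild functions), `avg_outgroup`, `min_outgroup`, `n_skipped`.
#' @export
guild_confidence_report <- function(matrix, guild) {
  stopifnot(inherits(guild, "ab_guild"))
  Y <- as_binary_matrix(matrix)
  fns <- guild$functions
  unknown <- setdiff(fns, colnames(Y))
  if (length(unknown) > 0L)
    stop("guild function(s) not in matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  inset <- rownames(Y) %in% guild$mapbacks
  if (!any(inset))
    warning("guild has no mapback genomes; mapback confidences are missing",
            call. = FALSE)
  mapback <- if (any(inset)) conf_matrix(Y, fns, which(inset)) else
    base::matrix(NA_real_, length(fns), length(fns),
                 dimnames = list(fns, fns))
  outgroup <- if (any(!inset)) conf_matrix(Y, fns, which(!inset)) else
    base::matrix(NA_real_, length(fns), length(fns),
                 dimnames = list(fns, fns))
  overall <- conf_matrix(Y, fns, seq_len(nrow(Y)))

  off <- outgroup[row(outgroup) != col(outgroup)]
  n_skipped <- sum(is.na(off))
  vals <- off[!is.na(off)]
  structure(list(
    guild = guild,
    mapback = mapback,
    outgroup = outgroup,
    overall = overall,
    avg_outgroup = if (length(vals)) mean(vals) else NA_real_,
    min_outgroup = if (length(vals)) min(vals) else NA_real_,
    n_skipped = n_skipped
  ), class = "ab_confidence")
}

#' @export
print.ab_confidence <- function(x, ...) {
  g <- x$guild
  cat(sprintf("Guild specificity (aspect %d, %d functions, %d mapback genomes)\n",
              g$aspect, length(g$functions), length(g$mapbacks)))
  cat(sprintf("  outgroup confidence: mean %s, min %s",
              fmt_or_missing(x$avg_outgroup), fmt_or_missing(x$min_outgroup)))
  if (x$n_skipped > 0)
    cat(sprintf(" (%d undefined pair(s) skipped)", x$n_skipped))
  cat("\n")
  invisible(x)
}

fmt_or_missing <- function(v) if (is.na(v)) "missing" else sprintf("%.3f", v)

#' Heatmap of outgroup confidences
#'
#' Displays the ordered-pair outgroup confidence matrix of a guild (rows =
#' antecedent, columns = consequent). The diagonal is masked: it is 1 by
#' definition. Asymmetry is meaningful — `A -> B` and `B -> A` condition on
#' different antecedents.
#'
#' @param x an `ab_confidence` report.
#' @param scope which confidence matrix to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.ab_confidence <- function(x, scope = c("outgroup", "mapback", "overall"),
                               ...) {
  scope <- match.arg(scope)
  m <- x[[scope]]
  diag(m) <- NA_real_
  n <- nrow(m)
  # image() draws x right / y up; flip rows so the matrix reads top-down
  image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
        zlim = c(0, 1), axes = FALSE, xlab = "consequent B",
        ylab = "antecedent A",
        main = sprintf("%s confidence, aspect %d", scope, x$guild$aspect),
        ...)
  axis(1, at = seq_len(n), labels = colnames(m), las = 2, cex.axis = 0.7)
  axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
       cex.axis = 0.7)
  invisible(x)
}

#' Write confidence tables as TSV
#'
#' `confidence.tsv`: columns `aspect`, `approach`, `antecedent`,
#' `consequent`, `scope` (mapback/outgroup/all), `confidence` (empty when
#' undefined), `n_antecedent`, `n_both`.
#'
#' @param reports list of `ab_confidence` objects.
#' @param matrix the [binary_matrix] the reports came from (for support
#'   counts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ab_confidence <- function(reports, matrix, path) {
  Y <- as_binary_matrix(matrix)
  rows <- do.call(rbind, lapply(reports, function(rep) {
    g <- rep$guild
    fns <- g$functions
    inset <- rownames(Y) %in% g$mapbacks
    scopes <- list(mapback = which(inset), outgroup = which(!inset),
                   all = seq_len(nrow(Y)))
    do.call(rbind, lapply(names(scopes), function(sc) {
      idx <- scopes[[sc]]
      sub <- unclass(Y)[idx, fns, drop = FALSE]
      storage.mode(sub) <- "double"
      co <- crossprod(sub)
      pairs <- expand.grid(antecedent = fns, consequent = fns,
                           stringsAsFactors = FALSE)
      nA <- diag(co)[pairs$antecedent]
      nAB <- co[cbind(pairs$antecedent, pairs$consequent)]
      data.frame(aspect = g$aspect, approach = g$approach,
                 antecedent = pairs$antecedent,
                 consequent = pairs$consequent,
                 scope = sc,
                 confidence = ifelse(nA > 0, nAB / nA, NA_real_),
                 n_antecedent = nA, n_both = nAB,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
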