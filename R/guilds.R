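#' Mapback genomes of a function set
#'
#' The mapback genomes of a guild are the genomes possessing every one of its
#' functions. They measure how strongly the data support the guild: a guild
#' with many mapback genomes describes a co-occurrence pattern actually
#' realized in the dataset.
#'
#' @param matrix a [binary_matrix].
#' @param functions character vector of function IDs. An empty set maps back
#'   to every genome (vacuous conjunction).
#' @return character vector of genome IDs (possibly empty).
#' @export
mapback_genomes <- function(matrix, functions) {
  Y <- as_binary_matrix(matrix)
  functions <- as.character(functions)
  unknown <- setdiff(functions, colnames(Y))
  if (length(unknown) > 0L)
    stop("unknown function ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(functions) == 0L) return(rownames(Y))
  sel <- rowSums(Y[, functions, drop = FALSE]) == length(functions)
  rownames(Y)[sel]
}

new_ab_guild <- function(aspect, functions, mapbacks, approach,
                         below_threshold = FALSE) {
  if (length(functions) < 2L)
    stop("a guild needs at least 2 functions", call. = FALSE)
  structure(list(aspect = as.integer(aspect),
                 functions = as.character(functions),
                 mapbacks = as.character(mapbacks),
                 approach = approach,
                 below_threshold = isTRUE(below_threshold)),
            class = "ab_guild")
}

#' @export
print.ab_guild <- function(x, ...) {
  cat(sprintf("Guild (aspect %d, approach '%s'): %d functions, %d mapback genomes%s\n",
              x$aspect, x$approach, length(x$functions), length(x$mapbacks),
              if (x$below_threshold) " [below mapback threshold]" else ""))
  cat("  functions: ", paste(x$functions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Define a guild by a fixed number of top-scoring functions
#'
#' Approach 1: the guild is the top `m` functions of the aspect's score
#' ranking (default 5), and its mapback genomes are the genomes carrying all
#' of them. Identical guilds can arise from aspects with identical presence
#' profiles; they are reported as-is.
#'
#' @param scores an [ab_scores()] object.
#' @param matrix the [binary_matrix] scores were computed from.
#' @param aspect aspect index in `1..K`.
#' @param m guild size, `2 <= m <= F`.
#' @return an `ab_guild`.
#' @export
define_guild_fixed <- function(scores, matrix, aspect, m = 5L) {
  stopifnot(inherits(scores, "ab_scores"))
  Y <- as_binary_matrix(matrix)
  m <- as.integer(m)
  if (m < 2L) stop("guild size m must be at least 2", call. = FALSE)
  if (m > ncol(Y))
    stop("m (", m, ") exceeds the number of functions (", ncol(Y), ")",
         call. = FALSE)
  fns <- head(scores$ranked_functions[[aspect]], m)
  new_ab_guild(aspect, fns, mapback_genomes(Y, fns), "fixed_size")
}

#' Define a guild by a minimum mapback support
#'
#' Approach 2: grow the guild along the aspect's score ranking, starting from
#' the top-2 prefix, and return the largest prefix whose mapback count still
#' meets `min_genomes` (default 100). Because adding a function can only
#' shrink the mapback set, the count is non-increasing in prefix size, so the
#' largest qualifying prefix is well defined. If even the size-2 prefix falls
#' short, the size-2 guild is returned with `below_threshold = TRUE`.
#'
#' @param scores an [ab_scores()] object.
#' @param matrix the [binary_matrix] scores were computed from.
#' @param aspect aspect index.
#' @param min_genomes minimum number of mapback genomes (inclusive).
#' @return an `ab_guild`.
#' @export
define_guild_min_mapback <- function(scores, matrix, aspect,
                                     min_genomes = 100L) {
  stopifnot(inherits(scores, "ab_scores"))
  Y <- as_binary_matrix(matrix)
  min_genomes <- as.integer(min_genomes)
  if (min_genomes < 1L) stop("min_genomes must be >= 1", call. = FALSE)
  curve <- expansion_curve(scores, Y, aspect, max_size = ncol(Y))
  ok <- curve$n_mapback >= min_genomes
  if (!any(ok)) {
    fns <- head(scores$ranked_functions[[aspect]], 2L)
    return(new_ab_guild(aspect, fns, mapback_genomes(Y, fns),
                        "min_mapback", below_threshold = TRUE))
  }
  size <- max(curve$size[ok])
  fns <- head(scores$ranked_functions[[aspect]], size)
  new_ab_guild(aspect, fns, mapback_genomes(Y, fns), "min_mapback")
}

#' Mapback counts along expanding guild prefixes
#'
#' For prefix sizes 2..`max_size` of an aspect's score-ranked function list,
#' counts the genomes possessing every function in the prefix. The sequence
#' is non-increasing: each added function is one more conjunct.
#'
#' @param scores an [ab_scores()] object.
#' @param matrix the [binary_matrix] scores were computed from.
#' @param aspect aspect index.
#' @param max_size largest prefix size to evaluate (default 20, capped at F).
#' @return a data.frame with columns `size` and `n_mapback`.
#' @export
expansion_curve <- function(scores, matrix, aspect, max_size = 20L) {
  stopifnot(inherits(scores, "ab_scores"))
  Y <- as_binary_matrix(matrix)
  max_size <- as.integer(max_size)
  if (max_size > ncol(Y))
    stop("max_size (", max_size, ") exceeds the number of functions (",
         ncol(Y), ")", call. = FALSE)
  if (max_size < 2L) stop("max_size must be at least 2", call. = FALSE)
  fns <- scores$ranked_functions[[aspect]]
  has_all <- unclass(Y)[, fns[1L]] == 1L
  counts <- integer(max_size - 1L)
  for (sz in 2:max_size) {
    has_all <- has_all & unclass(Y)[, fns[sz]] == 1L
    counts[sz - 1L] <- sum(has_all)
  }
  data.frame(size = 2:max_size, n_mapback = counts)
}

#' Write guild tables as TSV
#'
#' `guilds.tsv`: one row per (aspect, approach, rank) with the function at
#' that rank plus the guild's mapback count and below-threshold flag.
#' `mapbacks.tsv`: one row per (aspect, approach, genome).
#'
#' @param guilds a list of `ab_guild` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ab_guilds <- function(guilds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtab <- do.call(rbind, lapply(guilds, function(g)
    data.frame(aspect = g$aspect, approach = g$approach,
               rank = seq_along(g$functions), function_id = g$functions,
               n_mapback = length(g$mapbacks),
               below_threshold = g$below_threshold,
               stringsAsFactors = FALSE)))
  write.table(gtab, file.path(dir, "guilds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mtab <- do.call(rbind, lapply(guilds, function(g) {
    if (length(g$mapbacks) == 0L) return(NULL)
    data.frame(aspect = g$aspect, approach = g$approach,
               genome_id = g$mapbacks, stringsAsFactors = FALSE)
  }))
  if (is.null(mtab))
    mtab <- data.frame(aspect = integer(), approach = character(),
                       genome_id = character())
  write.table(mtab, file.path(dir, "mapbacks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
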