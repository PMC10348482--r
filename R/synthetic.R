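#' Specification of one planted artificial guild
#'
#' An artificial guild is "perfect": a genome either carries all of its
#' functions or none of them. The default design space mirrors the simulation
#' study the K-selection heuristic was calibrated on — guild sizes 5, 7 or 9
#' functions and abundances of 2%, 5% or 10% of genomes — but any size >= 2
#' and abundance in (0, 1) is accepted.
#'
#' @param n_functions number of functions in the guild (>= 2).
#' @param abundance fraction of genomes that carry the guild, in (0, 1).
#' @param overlap_mode `"non_overlapping"` (each genome joins at most one
#'   artificial guild; members drawn without replacement from the genomes not
#'   yet claimed by earlier guilds) or `"random"` (members drawn
#'   independently per guild, so genomes may join several).
#' @return an `ab_guild_spec`.
#' @export
guild_spec <- function(n_functions, abundance,
                       overlap_mode = c("non_overlapping", "random")) {
  n_functions <- as.integer(n_functions)
  if (n_functions < 2L) stop("n_functions must be >= 2", call. = FALSE)
  if (!(abundance > 0 && abundance < 1))
    stop("abundance must lie strictly between 0 and 1", call. = FALSE)
  structure(list(n_functions = n_functions, abundance = abundance,
                 overlap_mode = match.arg(overlap_mode)),
            class = "ab_guild_spec")
}

# nearest-integer member count; 0.02 * 3840 = 76.8 -> 77
member_count <- function(abundance, G) as.integer(floor(abundance * G + 0.5))

#' Generate a surrogate base matrix with latent aspect structure
#'
#' Draws a ground-truth aspect Bernoulli structure — `n_latent` aspects with
#' Dirichlet genome weights and presence probabilities that mix high (0.9)
#' and low (0.05) entries, rescaled so the expected overall density matches
#' `density` — and samples each cell as `Bernoulli(V_gf)`. The surrogate
#' stands in for a real genome-by-function table as the background into which
#' artificial guilds are planted.
#'
#' @param G,F numbers of genomes and functions.
#' @param n_latent number of latent aspects in the ground truth.
#' @param density target overall fraction of 1s, in (0, 0.9).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a [binary_matrix].
#' @export
generate_base_matrix <- function(G, F, n_latent = 5L, density = 0.25,
                                 seed = 1L) {
  stopifnot(G >= 1, F >= 1, n_latent >= 1)
  if (!(density > 0 && density < 0.9))
    stop("density must lie in (0, 0.9) for this structure", call. = FALSE)
  set.seed(as.integer(seed))
  gamma <- matrix(rgamma(G * n_latent, shape = 1), G, n_latent)
  gamma <- gamma / rowSums(gamma)
  p_high <- min(max((density - 0.05) / 0.85, 0), 1)
  beta <- matrix(0.05, n_latent, F)
  n_high <- max(1L, as.integer(round(p_high * F)))
  for (k in seq_len(n_latent))
    beta[k, sample.int(F, n_high)] <- 0.9
  V <- gamma %*% beta
  beta <- pmin(beta * density / mean(V), 0.98)
  V <- gamma %*% beta
  if (abs(mean(V) - density) > 0.05)
    stop("target density ", density,
         " unattainable with the requested structure", call. = FALSE)
  suppressWarnings(binary_matrix(
    matrix(rbinom(G * F, 1L, V), G, F,
           dimnames = list(sprintf("g%04d", seq_len(G)),
                           sprintf("fn%03d", seq_len(F))))))
}

#' Plant perfect artificial guilds into a base matrix
#'
#' For each spec, `n_functions` brand-new all-zero columns are appended to
#' the base matrix and set to 1 in `round(abundance * G)` member genomes, so
#' the planted functions co-occur perfectly in the members and are absent
#' everywhere else. Existing columns are never modified. Non-overlapping
#' specs draw members from the genomes not claimed by any earlier
#' non-overlapping guild; random specs draw independently.
#'
#' @param base a [binary_matrix] to plant into.
#' @param specs a single [guild_spec()] or a list of them.
#' @param seed integer seed for member selection.
#' @return an object of class `ab_simulation`: list with `matrix` (the
#'   augmented [binary_matrix]), `truth` (per guild: `guild_id`, `functions`,
#'   `members`), and `seed`.
#' @examples
#' base <- generate_base_matrix(200, 30, density = 0.2, seed = 1)
#' sim <- insert_artificial_guilds(base, guild_spec(5, 0.10), seed = 2)
#' length(sim$truth[[1]]$members)  # 20 = round(0.10 * 200)
#' @export
insert_artificial_guilds <- function(base, specs, seed = 1L) {
  Y <- as_binary_matrix(base)
  if (inherits(specs, "ab_guild_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "ab_guild_spec")))
  G <- nrow(Y)
  counts <- vapply(specs, function(s) member_count(s$abundance, G), 1L)
  nonov <- vapply(specs, function(s) s$overlap_mode == "non_overlapping",
                  TRUE)
  if (sum(counts[nonov]) > G)
    stop("non-overlapping guilds need ", sum(counts[nonov]),
         " member genomes but only ", G, " are available", call. = FALSE)
  set.seed(as.integer(seed))
  avail <- rownames(Y)
  truth <- vector("list", length(specs))
  newcols <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    members <- if (nonov[i]) {
      m <- sample(avail, counts[i])
      avail <- setdiff(avail, m)
      m
    } else {
      sample(rownames(Y), counts[i])
    }
    fns <- sprintf("ag%d_f%d", i, seq_len(s$n_functions))
    block <- matrix(0L, G, s$n_functions,
                    dimnames = list(rownames(Y), fns))
    block[members, ] <- 1L
    newcols[[i]] <- block
    truth[[i]] <- list(guild_id = sprintf("ag%d", i), functions = fns,
                       members = sort(members))
  }
  aug <- cbind(unclass(Y), do.call(cbind, newcols))
  structure(list(matrix = suppressWarnings(binary_matrix(aug)),
                 truth = truth, seed = as.integer(seed)),
            class = "ab_simulation")
}

#' @export
print.ab_simulation <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d genomes x %d functions, %d planted guild(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth)))
  for (t in x$truth)
    cat(sprintf("  %s: %d functions, %d member genomes\n",
                t$guild_id, length(t$functions), length(t$members)))
  invisible(x)
}

#' Generate replicate simulated datasets
#'
#' Replicate `i` is produced by [insert_artificial_guilds()] with seed
#' `seed + i`, so any single replicate can be regenerated without the rest.
#'
#' @param base a [binary_matrix].
#' @param specs a [guild_spec()] or list of them.
#' @param n_replicates number of replicates (default 100).
#' @param seed integer base seed.
#' @return a list of `ab_simulation` objects (empty for `n_replicates = 0`).
#' @export
generate_replicates <- function(base, specs, n_replicates = 100L,
                                seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 0L)
  lapply(seq_len(n_replicates), function(i)
    insert_artificial_guilds(base, specs, seed = as.integer(seed) + i))
}

#' Flip entries with a fixed probability
#'
#' Symmetric noise: every cell is toggled independently with probability `p`.
#' Useful for probing the fitter's robustness to false presences/absences;
#' planted guilds are no longer perfect after flipping.
#'
#' @param matrix a [binary_matrix].
#' @param p flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a [binary_matrix].
#' @export
flip_noise <- function(matrix, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  Y <- as_binary_matrix(matrix)
  set.seed(as.integer(seed))
  flips <- matrix(rbinom(length(Y), 1L, p), nrow(Y), ncol(Y))
  out <- (unclass(Y) + flips) %% 2L
  dimnames(out) <- dimnames(Y)
  suppressWarnings(binary_matrix(out))
}

#' Write planted-guild ground truth as TSV
#'
#' `truth.tsv`: columns `guild_id`, `function_ids` (comma-joined),
#' `genome_ids` (comma-joined).
#'
#' @param sim an `ab_simulation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "ab_simulation"))
  df <- do.call(rbind, lapply(sim$truth, function(t)
    data.frame(guild_id = t$guild_id,
               function_ids = paste(t$functions, collapse = ","),
               genome_ids = paste(t$members, collapse = ","),
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
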