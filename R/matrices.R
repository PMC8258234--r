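#' Draw a normalized interaction matrix
#'
#' Generates the N x N matrix of rescaled co-colonization trait deviations
#' `A = (alpha_ij)`, the dimensionless deviations of the co-colonization
#' susceptibility factors from their community mean.  Entries are drawn
#' i.i.d. from the standard normal distribution; structured variants zero the
#' diagonal or antisymmetrize.
#'
#' @param N strain pool size (positive integer).
#' @param seed integer seed; the draw is a pure function of
#'   `(N, seed, structure)`.
#' @param structure `"iid_normal"` (default) keeps all `N^2` entries as drawn;
#'   `"zero_diagonal"` zeroes the self-interaction deviations after drawing;
#'   `"skew"` antisymmetrizes as `(B - t(B))/sqrt(2)` so the off-diagonal
#'   marginal variance stays 1.
#'
#' @return An `N x N` numeric matrix with a `provenance` attribute recording
#'   distribution, seed, structure and RNG algorithm.
#' @export
#' @examples
#' A <- draw_normalized_matrix(4, seed = 1)
#' S <- draw_normalized_matrix(4, seed = 1, structure = "skew")
#' max(abs(S + t(S)))  # 0: antisymmetric by construction
draw_normalized_matrix <- function(N, seed,
                                   structure = c("iid_normal",
                                                 "zero_diagonal", "skew")) {
  structure <- match.arg(structure)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) ||
      N < 1 || N != round(N))
    stop("invalid size: N must be a positive integer")
  N <- as.integer(N)
  A <- with_seed(seed, matrix(rnorm(N * N), N, N))
  if (structure == "zero_diagonal") diag(A) <- 0
  if (structure == "skew") A <- (A - t(A)) / sqrt(2)
  attr(A, "provenance") <- list(distribution = "normal(0,1)",
                                seed = as.integer(seed),
                                structure = structure, N = N,
                                rng = "Mersenne-Twister/Inversion")
  A
}

#' Build the co-colonization susceptibility matrix
#'
#' Assembles the interaction matrix `K` with entries `K_ij = k + eps * alpha_ij`
#' from a normalized deviation matrix.  `K_ij > 1` means strain j faces
#' facilitation when co-colonizing a host already carrying i; `K_ij < 1`
#' means inhibition.
#'
#' @param A normalized interaction matrix (square numeric).
#' @param k mean interaction coefficient (dimensionless).
#' @param eps deviation scale, `eps >= 0`; the slow-fast reduction assumes it
#'   is small.
#'
#' @return Matrix `K` with attributes `k` and `eps`.  Negative entries are
#'   arithmetically possible when `eps * |alpha_ij| > k`; they are allowed
#'   here with a warning (the reduced dynamics only use `A` and `mu`) but the
#'   full compartmental model rejects them.
#' @export
build_interaction_matrix <- function(A, k, eps) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  if (eps < 0) stop("eps must be non-negative")
  K <- k + eps * unclass(A)
  attributes(K) <- attributes(K)[c("dim")]
  if (any(K < 0))
    warning("negative K entries produced (eps*|alpha| > k); ",
            "unphysical for the full compartmental model")
  attr(K, "k") <- k
  attr(K, "eps") <- eps
  K
}

#' Cyclic (rock-paper-scissors) interaction matrix for three strains
#'
#' Returns a fixed zero-diagonal 3 x 3 normalized interaction matrix whose
#' induced pairwise invasion outcomes at large single-to-co-colonization
#' ratio form an intransitive cycle (strain 1 excludes 2, 2 excludes 3,
#' 3 excludes 1), and whose boundary heteroclinic cycle is attracting at
#' large `mu` (the pairwise sums `alpha_ij + alpha_ji` are predominantly
#' negative, so exclusion "losses" outweigh invasion "wins").
#'
#' @return A 3 x 3 numeric matrix with zero diagonal and nonzero
#'   antisymmetric part.
#' @export
#' @examples
#' A <- make_rps_matrix()
#' L <- invasion_fitness_matrix(A, mu = 5)
#' classify_pair(L[1, 2], L[2, 1])  # strain 1 excludes strain 2
make_rps_matrix <- function() {
  A <- rbind(c(0.0, -0.5, 0.3),
             c(1.0, 0.0, -1.0),
             c(-0.9, 0.2, 0.0))
  attr(A, "provenance") <- list(distribution = "fixed", seed = NA_integer_,
                                structure = "rps", N = 3L,
                                rng = NA_character_)
  A
}

#' Write / read an interaction matrix as CSV
#'
#' Plain-text round trip: row-major values with a header row of strain
#' labels.  Provenance metadata, if present, is written alongside as JSON.
#'
#' @param A matrix to write.
#' @param path CSV file path; provenance goes to `paste0(path, ".json")`.
#' @export
write_matrix_csv <- function(A, path) {
  df <- as.data.frame(unclass(A))
  colnames(df) <- paste0("strain_", seq_len(ncol(A)))
  write.csv(df, path, row.names = FALSE)
  prov <- attr(A, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  A <- as.matrix(read.csv(path, check.names = FALSE))
  dimnames(A) <- NULL
  meta <- paste0(path, ".json")
  if (file.exists(meta))
    attr(A, "provenance") <- jsonlite::read_json(meta, simplifyVector = TRUE)
  A
}
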