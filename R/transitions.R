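#' k-th root of a row-stochastic matrix by eigendecomposition
#'
#' Computes the matrix `M` with `M^k = P` via the eigendecomposition
#' `P = V diag(lambda) V^-1`, taking the principal k-th root of each
#' eigenvalue. Used to shorten transition-probability cycle lengths (for
#' example converting a 3-month matrix to a monthly one). Small negative
#' entries arising from numerical noise (above `-1e-8`) are clipped to zero
#' and rows renormalized; imaginary residues below `1e-10` are truncated.
#'
#' @param P Square row-stochastic matrix.
#' @param k Positive integer; the cycle-length divisor.
#' @return Row-stochastic matrix `M` with `M^k = P` (elementwise within
#'   `1e-8` for well-conditioned `P`).
#' @details A valid stochastic root does not always exist. When `P` is not
#'   diagonalizable, or has a negative real eigenvalue (whose principal
#'   root is complex and cannot cancel), the function fails with an
#'   explicit error rather than returning a non-stochastic matrix.
#' @examples
#' P <- matrix(c(0.729, 0.271, 0, 1), 2, 2, byrow = TRUE)
#' matrix_root(P, 3)  # [[0.9, 0.1], [0, 1]]
#' @export
matrix_root <- function(P, k) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  k <- as.integer(k)
  if (k < 1) stop("k must be a positive integer")
  if (any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("P must be row-stochastic")
  if (k == 1L) return(P)
  e <- eigen(P)
  V <- e$vectors
  # non-diagonalizable P: eigenvector matrix is (numerically) singular
  sv <- svd(V)$d
  if (min(sv) / max(sv) < 1e-12)
    stop("no valid stochastic root: P is not diagonalizable")
  lam <- e$values
  real_neg <- abs(Im(lam)) < 1e-12 & Re(lam) < -1e-12
  if (any(real_neg))
    stop("no valid stochastic root: negative real eigenvalue")
  rootlam <- as.complex(lam)^(1 / k)  # principal branch
  M <- V %*% diag(rootlam, nrow = length(rootlam)) %*% solve(V)
  if (max(abs(Im(M))) > 1e-8)
    stop("no valid stochastic root: complex residue above tolerance")
  M <- Re(M)
  M[abs(M) < 1e-10] <- 0  # truncate numerical dust
  if (any(M < -1e-8))
    stop("no valid stochastic root: negative entries beyond numerical noise")
  M[M < 0] <- 0
  M / rowSums(M)
}

#' Build the monthly five-state transition matrix
#'
#' Assembles the monthly transition matrix over the states well, mild,
#' moderate, severe and dead. Off-diagonal morbidity entries come directly
#' from the monthly transition probabilities; the death column is the
#' monthly all-cause mortality, multiplied by the anxiety mortality rate
#' ratio for the states listed in `cfg$mortality_rr_states`; the diagonal
#' absorbs the remainder so each row sums to one; the dead state is
#' absorbing.
#'
#' @param values Named numeric vector of point values, see [base_values()].
#' @param cfg A [structural_config()] object.
#' @return A 5 x 5 row-stochastic matrix with `dimnames` set to the state
#'   names, of class `transition_matrix`.
#' @export
build_monthly_matrix <- function(values, cfg = structural_config()) {
  v <- values
  d <- v[["mortality_monthly"]]
  rr <- v[["rr_mortality_anxiety"]]
  death <- vapply(STATES[1:4], function(s)
    if (s %in% cfg$mortality_rr_states) d * rr else d, numeric(1))
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  M["well", c("mild", "moderate", "severe")] <-
    c(v[["p_well_mild"]], v[["p_well_mod"]], v[["p_well_sev"]])
  M["mild", c("well", "moderate", "severe")] <-
    c(v[["p_mild_well"]], v[["p_mild_mod"]], v[["p_mild_sev"]])
  M["moderate", c("well", "mild", "severe")] <-
    c(v[["p_mod_well"]], v[["p_mod_mild"]], v[["p_mod_sev"]])
  M["severe", c("well", "mild", "moderate")] <-
    c(v[["p_sev_well"]], v[["p_sev_mild"]], v[["p_sev_mod"]])
  M[1:4, "dead"] <- death
  out <- rowSums(M[1:4, ])
  if (any(out >= 1)) {
    bad <- STATES[1:4][out >= 1]
    stop("off-diagonal transition probabilities sum to >= 1 for state(s): ",
         paste(bad, collapse = ", "))
  }
  diag(M)[1:4] <- 1 - out
  M["dead", "dead"] <- 1
  structure(M, class = c("transition_matrix", "matrix", "array"))
}

#' Write / read a transition matrix as CSV
#'
#' CSV layout: a header of state names, first column the origin state.
#'
#' @param M A transition matrix.
#' @param path CSV path.
#' @return `write_transition_matrix()` returns `path` invisibly;
#'   `read_transition_matrix()` returns the matrix.
#' @export
write_transition_matrix <- function(M, path) {
  df <- data.frame(state = rownames(M), unclass(M), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1])
  rownames(M) <- df[[1]]
  structure(M, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, digits = 6, ...) {
  cat("Monthly transition matrix (rows = origin state)\n")
  print(round(unclass(x), digits))
  invisible(x)
}
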