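# Aitchison-geometry primitives for 4-part (or general D-part) time-use
# compositions: closure, pivot ilr coordinates and their inverse,
# compositional means, and symmetric-balance pairwise correlations.

#' Canonical part names of a 24-hour time-use composition
#'
#' The fixed part order used throughout the package: moderate-vigorous
#' physical activity, light physical activity, sedentary behaviour, sleep.
#'
#' @return Character vector of length 4.
#' @export
timeuse_parts <- function() c("mvpa", "lpa", "sb", "sleep")

#' Default closure constant (minutes in a day)
#' @return 1440.
#' @export
timeuse_kappa <- function() 1440

as_comp_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  x
}

check_positive <- function(x, what = "compositional parts") {
  if (any(!is.finite(x))) {
    stop(sprintf("%s must all be finite.", what), call. = FALSE)
  }
  if (any(x <= 0)) {
    stop(sprintf(
      "%s must be strictly positive: zero or negative parts are not representable in Aitchison geometry (handle zeros upstream, e.g. via the accelerometry zero-replacement rule).",
      what
    ), call. = FALSE)
  }
  invisible(x)
}

#' Closure: proportional rescaling to a constant sum
#'
#' Rescales a strictly positive vector (or the rows of a matrix) so that its
#' parts sum to `kappa`, the only operation under which compositional
#' information (the relative sizes of parts) is preserved.  For a daily
#' time-use composition `kappa` is 1440 minutes.
#'
#' @param x Numeric vector of strictly positive parts, or a matrix /
#'   data frame with one composition per row.
#' @param kappa Positive closure constant, default [timeuse_kappa()].
#' @return Object of the same shape as `x` whose (row) sums equal `kappa`.
#' @examples
#' closure(c(mvpa = 100, lpa = 200, sb = 700, sleep = 500))
#' @export
closure <- function(x, kappa = timeuse_kappa()) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0) {
    stop("`kappa` must be a single positive number.", call. = FALSE)
  }
  vec <- !is.matrix(x) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  check_positive(m)
  out <- m * (kappa / rowSums(m))
  if (vec) stats::setNames(drop(out), colnames(m)) else out
}

#' Pivot (sequential binary partition) ilr basis matrix
#'
#' Returns the D x (D-1) log-contrast matrix `V` of the pivot ilr basis, so
#' that `z = log(x) %*% V`.  Column i contrasts part i against the geometric
#' mean of parts i+1..D; the columns are orthonormal in the clr metric.
#'
#' @param D Number of parts (>= 2).
#' @return D x (D-1) matrix.
#' @export
pivot_basis <- function(D) {
  if (D < 2) stop("A composition needs at least two parts.", call. = FALSE)
  V <- matrix(0, D, D - 1L)
  for (i in seq_len(D - 1L)) {
    r <- D - i
    V[i, i] <- sqrt(r / (r + 1))
    V[(i + 1L):D, i] <- -sqrt(r / (r + 1)) / r
  }
  V
}

resolve_order <- function(order, cn, D) {
  if (is.null(order)) return(seq_len(D))
  if (is.character(order)) {
    if (is.null(cn) || !all(order %in% cn)) {
      stop("`pivot_order` names not found among composition parts.", call. = FALSE)
    }
    order <- match(order, cn)
  }
  if (length(order) != D || !setequal(order, seq_len(D))) {
    stop("`pivot_order` must be a permutation of the parts.", call. = FALSE)
  }
  as.integer(order)
}

#' Pivot ilr coordinates of a composition
#'
#' Maps a D-part composition to D-1 unconstrained real coordinates.  With the
#' default order, the first coordinate is
#' `sqrt((D-1)/D) * log(x1 / gmean(x2..xD))`, i.e. the first listed part
#' pivoted against the rest; the map is scale invariant, so closure is
#' irrelevant to the result.
#'
#' @param x Composition vector, or matrix / data frame of row compositions.
#' @param pivot_order Permutation of the parts (integer indices or part
#'   names); the first element is the pivot.  Default: given order.
#' @return Numeric vector of length D-1, or an n x (D-1) matrix, with columns
#'   `z1..z{D-1}` and the order stored in attribute `"pivot_order"`.
#' @examples
#' ilr_pivot(c(2, 1, 1, 1))  # (sqrt(3/4) * log 2, 0, 0)
#' @export
ilr_pivot <- function(x, pivot_order = NULL) {
  vec <- !is.matrix(x) && !is.data.frame(x)
  m <- as_comp_matrix(x)
  check_positive(m)
  ord <- resolve_order(pivot_order, colnames(m), ncol(m))
  z <- log(m[, ord, drop = FALSE]) %*% pivot_basis(ncol(m))
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (vec) z <- stats::setNames(drop(z), paste0("z", seq_len(ncol(m) - 1L)))
  z
}

#' Inverse pivot ilr transform
#'
#' Reconstructs the unique composition with sum `kappa` that maps to the
#' given ilr coordinates under [ilr_pivot()] with the same basis.
#'
#' @param z Coordinate vector of length D-1, or matrix of row coordinates.
#' @param kappa Closure constant for the reconstructed composition.
#' @param parts Optional part names for the output (length D).
#' @param pivot_order Permutation used when the coordinates were created.
#' @return Composition vector or matrix closed to `kappa`.
#' @export
ilr_inverse <- function(z, kappa = timeuse_kappa(), parts = NULL,
                        pivot_order = NULL) {
  vec <- !is.matrix(z) && !is.data.frame(z)
  zm <- as_comp_matrix(z)
  if (any(!is.finite(zm))) stop("ilr coordinates must be finite.", call. = FALSE)
  D <- ncol(zm) + 1L
  ord <- resolve_order(pivot_order, parts, D)
  clr <- zm %*% t(pivot_basis(D))
  x <- exp(clr)
  x[, ord] <- x
  colnames(x) <- parts %||% (if (D == 4L) timeuse_parts() else paste0("part", seq_len(D)))
  out <- closure(x, kappa)
  if (vec) stats::setNames(drop(out), colnames(x)) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compositional (geometric) mean
#'
#' The centre of a compositional sample: the per-part geometric mean, closed
#' to `kappa`.  Equivalent to mapping to ilr space, averaging, and mapping
#' back.
#'
#' @param x Matrix or data frame of row compositions (>= 1 row).
#' @param kappa Closure constant.
#' @return Named composition vector summing to `kappa`.
#' @export
compositional_mean <- function(x, kappa = timeuse_kappa()) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 1L) stop("Need at least one composition.", call. = FALSE)
  check_positive(m)
  closure(stats::setNames(exp(colMeans(log(m))), colnames(m)), kappa)
}

#' Symmetric-balance coordinate pair for two parts
#'
#' Constructs the pair of log-contrast coordinates that treat parts `i` and
#' `j` symmetrically against the average of the remaining parts.  The
#' clr-coefficient pattern of the first coordinate is `alpha` at `i`, `beta`
#' at `j` and `gamma` elsewhere, with `alpha > 0 > beta`; the second
#' coordinate swaps `alpha` and `beta`.  The coefficients are the unique
#' (up to sign) solution of zero sum, unit norm and mutual orthogonality:
#' `gamma = -1/sqrt(D(D-2))`, `alpha = (1 + sqrt((D-2)/D))/2`,
#' `beta = (sqrt((D-2)/D) - 1)/2`.  The Pearson correlation of the two
#' coordinates measures the co-dominance of parts `i` and `j` relative to
#' the rest (see [cor_coda()]).
#'
#' @param x Matrix / data frame of row compositions with D >= 3 parts.
#' @param i,j Distinct part indices or names.
#' @return List with elements `alpha`, `beta`, `gamma`, and per-sample
#'   coordinate vectors `z1` (dominance of `i`) and `z2` (dominance of `j`).
#' @export
symmetric_balance_coords <- function(x, i, j) {
  m <- as_comp_matrix(x)
  check_positive(m)
  D <- ncol(m)
  if (D < 3L) stop("Symmetric balances are undefined for D < 3.", call. = FALSE)
  idx <- function(k) if (is.character(k)) match(k, colnames(m)) else as.integer(k)
  i <- idx(i); j <- idx(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > D || j > D) {
    stop("Part indices out of range.", call. = FALSE)
  }
  if (i == j) stop("`i` and `j` must name distinct parts.", call. = FALSE)
  s <- sqrt((D - 2) / D)
  alpha <- (1 + s) / 2
  beta <- (s - 1) / 2
  gamma <- -1 / sqrt(D * (D - 2))
  lx <- log(m)
  rest <- rowSums(lx[, -c(i, j), drop = FALSE])
  list(
    alpha = alpha, beta = beta, gamma = gamma,
    z1 = alpha * lx[, i] + beta * lx[, j] + gamma * rest,
    z2 = beta * lx[, i] + alpha * lx[, j] + gamma * rest
  )
}

#' Compositional pairwise correlation via symmetric balances
#'
#' Pearson correlation between the two symmetric-balance coordinates of
#' parts `i` and `j`.  Interpreted as the dominance of one part over the
#' other: positive when the two parts increase together relative to the
#' average of the remaining parts, negative when one grows at the expense of
#' the other.  Unlike a raw Pearson correlation of the part values, it is
#' not distorted by the constant-sum constraint.
#'
#' @inheritParams symmetric_balance_coords
#' @return Correlation coefficient in \[-1, 1\].
#' @export
cor_coda <- function(x, i, j) {
  m <- as_comp_matrix(x)
  if (nrow(m) < 3L) stop("Need at least 3 samples.", call. = FALSE)
  sb <- symmetric_balance_coords(m, i, j)
  if (stats::sd(sb$z1) == 0 || stats::sd(sb$z2) == 0) {
    stop("Correlation undefined: a symmetric-balance coordinate has zero variance.",
         call. = FALSE)
  }
  stats::cor(sb$z1, sb$z2)
}

#' Read / write compositions as CSV
#'
#' Compositions travel as CSV with columns `mvpa_min`, `lpa_min`, `sb_min`,
#' `sleep_min`.
#'
#' @param path File path.
#' @param kappa Closure constant applied on read.
#' @return `read_compositions()`: matrix of closed compositions with columns
#'   [timeuse_parts()].
#' @export
read_compositions <- function(path, kappa = timeuse_kappa()) {
  d <- utils::read.csv(path)
  cols <- paste0(timeuse_parts(), "_min")
  if (!all(cols %in% names(d))) {
    stop(sprintf("Composition CSV must contain columns: %s.",
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(d[cols])
  colnames(m) <- timeuse_parts()
  closure(m, kappa)
}

#' @rdname read_compositions
#' @param x Matrix or data frame of compositions (columns [timeuse_parts()]).
#' @export
write_compositions <- function(x, path) {
  m <- as_comp_matrix(x)
  colnames(m) <- paste0(colnames(m) %||% timeuse_parts(), "_min")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}
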