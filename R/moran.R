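# Global Moran's I over areal rates, with the closed-form null expectation
# -1/(N-1) and one-sided permutation inference.

.moranWeights <- function(lattice, scheme, allowZeroRows = FALSE) {
  W <- as.matrix(adjacencyMatrix(lattice))
  if (scheme == "row") {
    rs <- rowSums(W)
    if (any(rs == 0) && !allowZeroRows)
      stop("isolated tract under the row-standardised scheme; set ",
           "allowZeroRows = TRUE to keep its weights at zero")
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  W
}

#' Moran's I statistic
#'
#' I = (N / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2, with w the lattice adjacency under the chosen weight scheme and
#' S0 the total weight. Typically applied to per-tract rates
#' (count / population); the statistic is invariant to adding a constant or
#' rescaling the values by a positive factor.
#'
#' @param values numeric vector, one value per tract in lattice order; must
#'   not be constant.
#' @param lattice a \linkS4class{TractLattice} with at least 2 tracts.
#' @param scheme \code{"binary"} (w_ij in 0/1) or \code{"row"}
#'   (row-standardised weights).
#' @param allowZeroRows keep isolated tracts with all-zero weights under
#'   the row scheme instead of erroring.
#' @return the scalar statistic.
#' @export
moransI <- function(values, lattice, scheme = c("binary", "row"),
                    allowZeroRows = FALSE) {
  scheme <- match.arg(scheme)
  N <- nTracts(lattice)
  stopifnot(N >= 2, length(values) == N)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I undefined: values have zero variance")
  W <- .moranWeights(lattice, scheme, allowZeroRows)
  S0 <- sum(W)
  if (S0 == 0) stop("lattice has no edges")
  (N / S0) * as.numeric(crossprod(z, W %*% z)) / denom
}

#' Moran's I permutation test
#'
#' One-sided (greater) randomisation test: values are permuted across
#' tracts \code{nPerm} times and p = (1 + #\{permuted I >= observed I\}) /
#' (1 + nPerm); ties count toward the numerator (conservative). The null
#' expectation is E[I] = -1/(N-1).
#'
#' @inheritParams moransI
#' @param nPerm number of permutations (>= 99).
#' @param seed optional integer seed (results reproducible given it).
#' @return a \linkS4class{MoranResult}.
#' @export
moranTest <- function(values, lattice, nPerm = 999, seed = NULL,
                      scheme = c("binary", "row"), allowZeroRows = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(nPerm >= 99)
  if (!is.null(seed)) set.seed(seed)
  N <- nTracts(lattice)
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I undefined: values have zero variance")
  W <- .moranWeights(lattice, scheme, allowZeroRows)
  S0 <- sum(W)
  obs <- (N / S0) * as.numeric(crossprod(z, W %*% z)) / denom
  perm <- vapply(seq_len(nPerm), function(b) {
    zp <- z[sample.int(N)]
    (N / S0) * as.numeric(crossprod(zp, W %*% zp)) / denom
  }, numeric(1))
  new("MoranResult", I = obs, expectedI = -1 / (N - 1),
      pValue = (1 + sum(perm >= obs)) / (1 + nPerm),
      nPerm = nPerm, scheme = scheme, n = N, permuted = perm)
}

#' Per-category, per-period Moran table for a set of panels
#'
#' Convenience wrapper shaped like an areal-autocorrelation summary table:
#' for each panel (category) and each requested period grouping it reports
#' the visit total n, Moran's I of the per-tract rates, and the permutation
#' p-value.
#'
#' @param panels named list of \linkS4class{CountPanel}s (one per
#'   category).
#' @param lattice the shared \linkS4class{TractLattice}.
#' @param periodGroups named list of period-label vectors (default: one
#'   group with all periods).
#' @param nPerm,seed,scheme passed to \code{\link{moranTest}}.
#' @return data.frame with columns category, period, n, I, expected_I, p.
#' @export
moranTable <- function(panels, lattice, periodGroups = NULL, nPerm = 999,
                       seed = NULL, scheme = "binary") {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cat in names(panels)) {
    panel <- panels[[cat]]
    groups <- periodGroups %||% list(all = periodLabels(panel))
    for (g in names(groups)) {
      keep <- periodLabels(panel) %in% groups[[g]]
      Y <- panelCounts(panel)[, keep, drop = FALSE]
      rates <- rowSums(Y) / unname(populations(panel))
      res <- moranTest(rates, lattice, nPerm = nPerm, scheme = scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, period = g, n = sum(Y), I = res@I,
        expected_I = res@expectedI, p = res@pValue)
    }
  }
  do.call(rbind, rows)
}
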