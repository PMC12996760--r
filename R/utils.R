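#' @keywords internal
"_PACKAGE"

## Conversion factor Hartree -> kcal/mol (CODATA); used for reporting only,
## all internal energies are Hartree.
HARTREE_TO_KCAL <- 627.5094740631

#' Unit conversion: Hartree to kcal/mol
#'
#' @param x energy in Hartree
#' @return energy in kcal/mol
#' @export
hartree_to_kcal <- function(x) x * HARTREE_TO_KCAL

## Symmetric positive-semidefinite pseudo-inverse with a relative eigenvalue
## cutoff. Eigenvalues below `rtol * max(eigenvalue)` are dropped. LS-THC
## metrics are routinely rank-deficient after pruning, so this is the
## workhorse inverse for every grid-metric solve.
psd_pinv <- function(S, rtol = 1e-10) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lmax <- max(ee$values, 0)
  keep <- ee$values > rtol * lmax
  if (!any(keep)) stop("psd_pinv: matrix has zero numerical rank")
  V <- ee$vectors[, keep, drop = FALSE]
  list(
    pinv = V %*% (t(V) / ee$values[keep]),
    rank = sum(keep)
  )
}

## Flatten a three-index DF factor B[p, q, J] into the (pq) x J pair matrix
## (column-major pair order: p fastest).
flatten_df <- function(B) {
  d <- dim(B)
  matrix(B, d[1] * d[2], d[3])
}

## Pair-product basis of a collocation: P[(pq), G] = X_left[p, G] * X_right[q, G].
## Rows are column-major pairs (left index fastest), matching flatten_df().
pair_basis <- function(coll) {
  nl <- nrow(coll$X_left)
  nr <- nrow(coll$X_right)
  pidx <- rep(seq_len(nl), times = nr)
  qidx <- rep(seq_len(nr), each = nl)
  coll$X_left[pidx, , drop = FALSE] * coll$X_right[qidx, , drop = FALSE]
}

## Deterministic per-stream seed derivation: a single experiment seed fans out
## to independent stages/species via a counter, staying inside 32-bit range.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 1009 + 11) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
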