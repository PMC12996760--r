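## Per-species feature construction and the unit-normal scaler.

#' THC goodness of fit
#'
#' `f = 1 - ||B - B_THC||_F / ||B||_F`, where `B_THC` is the projection of
#' the density-fitting factor onto the THC grid pair basis; `f = 1` is a
#' perfect fit, `f = 0` a projection that captures nothing.
#'
#' @param B density-fitting factor of one pair type.
#' @param B_thc its THC-basis projection (same shape).
#' @return scalar `f <= 1`.
#' @export
goodness_of_fit <- function(B, B_thc) {
  if (!identical(dim(B), dim(B_thc)))
    stop("goodness_of_fit: shape mismatch")
  nb <- sqrt(sum(B^2))
  if (nb == 0) stop("goodness_of_fit: ||B||_F = 0, measure undefined")
  1 - sqrt(sum((B - B_thc)^2)) / nb
}

## log(1 - f) with the argument clamped at 1e-16: f = 1 occurs in the exact
## THC limit and must not produce -Inf.
log_fit_feature <- function(f) log(pmax(1 - f, 1e-16))

#' Feature names of the two feature modes
#'
#' The default mode has 24 features: the Hartree-Fock energy, the two MP2a
#' and two MP2b components, the ten MP3b diagram components, the HOMO-LUMO
#' gap and total eigenvalue span, the three log-transformed THC fit
#' qualities, and the Frobenius and max-abs norms of the integral and
#' amplitude tensors. The full mode appends ten externally supplied MP3d
#' components (34 features).
#'
#' @param mode `"default"` (24) or `"full"` (34).
#' @return character vector of feature names in fixed column order.
#' @export
feature_names <- function(mode = c("default", "full")) {
  mode <- match.arg(mode)
  base <- c("E_HF", "EC_a", "EX_a", "EC_b", "EX_b",
            paste0("E", 1:10, "_b"),
            "gap", "span", "f_ab_t", "f_ai_t", "f_ij_t",
            "norm_g_F", "norm_t_F", "norm_g_inf", "norm_t_inf")
  if (mode == "full") c(base, paste0("E", 1:10, "_d")) else base
}

#' Extract the feature vector of one species
#'
#' Energies and Frobenius norms are divided by the number of active valence
#' electrons (size-intensive features); the max-abs norms, gap, span and fit
#' qualities are left unnormalized. Fit qualities enter as
#' `log(1 - f)` with the argument clamped at `1e-16`.
#'
#' @param suite a [thc_energy_suite()] result.
#' @param mp3d optional named numeric `E1_d ... E10_d` (external MP3d
#'   components, already in Hartree); supplying it switches to full mode.
#' @return named numeric feature vector (24 or 34 entries).
#' @export
extract_features <- function(suite, mp3d = NULL) {
  bd <- suite$breakdowns
  for (v in c("canonical", "mp2a", "mp2b", "mp3b"))
    if (is.null(bd[[v]])) stop("extract_features: missing breakdown: ", v)
  nval <- suite$system$n_valence
  fits <- suite$fits
  fval <- function(pt) fits$f[fits$pair_type == pt]
  feats <- c(
    E_HF = suite$system$e_scf / nval,
    EC_a = unname(bd$mp2a$e_c) / nval,
    EX_a = unname(bd$mp2a$e_x) / nval,
    EC_b = unname(bd$mp2b$e_c) / nval,
    EX_b = unname(bd$mp2b$e_x) / nval,
    stats::setNames(unname(bd$mp3b$components) / nval, paste0("E", 1:10, "_b")),
    gap = homo_lumo_gap(suite$system),
    span = eigenvalue_span(suite$system),
    f_ab_t = log_fit_feature(fval("vv")),
    f_ai_t = log_fit_feature(fval("ov")),
    f_ij_t = log_fit_feature(fval("oo")),
    norm_g_F = suite$norms$norm_g_F / nval,
    norm_t_F = suite$norms$norm_t_F / nval,
    norm_g_inf = suite$norms$norm_g_inf,
    norm_t_inf = suite$norms$norm_t_inf
  )
  if (!is.null(mp3d)) {
    if (length(mp3d) != 10L) stop("extract_features: mp3d must have 10 entries")
    feats <- c(feats, stats::setNames(as.numeric(mp3d) / nval, paste0("E", 1:10, "_d")))
  }
  if (!all(is.finite(feats)))
    stop("extract_features: non-finite feature(s): ",
         paste(names(feats)[!is.finite(feats)], collapse = ", "))
  feats
}

#' Build a feature table for a corpus
#'
#' @param suites list of [thc_energy_suite()] results.
#' @param mp3d_table optional data frame `species_id, E1_d ... E10_d`.
#' @return data frame with `species_id` and one fixed-order column per feature.
#' @export
build_feature_table <- function(suites, mp3d_table = NULL) {
  rows <- lapply(suites, function(s) {
    md <- NULL
    if (!is.null(mp3d_table)) {
      r <- mp3d_table[mp3d_table$species_id == s$species_id, , drop = FALSE]
      if (nrow(r) != 1L) stop("build_feature_table: missing mp3d row for ", s$species_id)
      md <- as.numeric(r[1, paste0("E", 1:10, "_d")])
    }
    fv <- extract_features(s, mp3d = md)
    cbind(data.frame(species_id = s$species_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Unit-normal feature/label scaler
#'
#' Computes per-column mean and standard deviation on training rows only;
#' [apply_scaler()] centers and scales to unit normal, mapping constant
#' columns (sd = 0) to zero, and [invert_scaler()] restores original units.
#' Any data beyond the training set must be transformed with the training
#' state, which therefore travels with the model.
#'
#' @param X numeric matrix or data frame of training rows.
#' @return an object of class `scaler_state` (`mean`, `sd`, `constant`).
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (nrow(X) == 1L) sdv[] <- 0
  structure(list(mean = mu, sd = sdv, constant = sdv == 0),
            class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state a fitted `scaler_state`.
#' @export
apply_scaler <- function(X, state) {
  if (!inherits(state, "scaler_state")) stop("apply_scaler: unfitted scaler")
  X <- as.matrix(X)
  if (ncol(X) != length(state$mean)) stop("apply_scaler: column mismatch")
  sdv <- ifelse(state$constant, 1, state$sd)
  out <- sweep(sweep(X, 2, state$mean), 2, sdv, `/`)
  out[, state$constant] <- 0
  out
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(X, state) {
  if (!inherits(state, "scaler_state")) stop("invert_scaler: unfitted scaler")
  X <- as.matrix(X)
  sdv <- ifelse(state$constant, 1, state$sd)
  sweep(sweep(X, 2, sdv, `*`), 2, state$mean, `+`)
}
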