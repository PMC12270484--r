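## optimize: learn the 20x4 interaction energy matrix gamma by maximizing the
## binding-energy gap between native and decoy sequence ensembles relative to
## the decoy energy variance, predict threaded binding energies, convert Kd
## ratios to free-energy differences, and recalibrate gamma against affinity
## tables by ridge regression.

GAS_CONSTANT_KCAL <- 1.98720425e-3  # kcal / (mol K)

#' Gap statistics of a training ensemble
#'
#' Computes `A`, the difference between the mean decoy feature vector and the
#' mean strong-binder (native) feature vector, and `B`, the population
#' covariance matrix of the decoy feature vectors. `A` quantifies how much
#' more often each amino-acid/nucleotide contact type occurs in decoys than
#' in strong binders; `B` captures the co-occurrence structure of contact
#' types among decoys.
#'
#' @param strong_phis Feature vectors of the strong binders: a list of
#'   [compute_phi()] matrices or an `n x 80` matrix (rows = sequences).
#' @param decoy_phis Feature vectors of the decoys, same formats; at least 2.
#' @return Object of class `gap_statistics`: list with vector `A` (length
#'   80), matrix `B` (80 x 80), and the sample counts.
#' @export
compute_gap_statistics <- function(strong_phis, decoy_phis) {
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    stopifnot(ncol(x) == feature_dim())
    x
  }
  S <- as_mat(strong_phis)
  D <- as_mat(decoy_phis)
  if (nrow(S) < 1L) stop("need at least one strong binder")
  if (nrow(D) < 2L) stop("need at least two decoys (covariance undefined)")
  A <- colMeans(D) - colMeans(S)
  Dc <- sweep(D, 2L, colMeans(D))
  B <- crossprod(Dc) / nrow(D)  # population covariance
  structure(list(A = A, B = B, n_strong = nrow(S), n_decoy = nrow(D)),
            class = "gap_statistics")
}

#' @rdname compute_gap_statistics
#' @param A Length-80 numeric vector (decoy-minus-strong mean contacts).
#' @param B 80x80 symmetric positive-semidefinite matrix.
#' @param n_strong,n_decoy Sample counts behind `A` and `B`.
#' @export
gap_statistics <- function(A, B, n_strong = 1L, n_decoy = 2L) {
  A <- as.numeric(A)
  B <- as.matrix(B)
  stopifnot(length(A) == feature_dim(), all(dim(B) == feature_dim()),
            isTRUE(all.equal(B, t(B), tolerance = 1e-8)))
  structure(list(A = A, B = B, n_strong = n_strong, n_decoy = n_decoy),
            class = "gap_statistics")
}

#' Gap-to-variance objective
#'
#' Evaluates `delta E / Delta E = (A' gamma) / sqrt(gamma' B gamma)`, the
#' mean energy gap between decoy and strong ensembles in units of the decoy
#' energy standard deviation, for an arbitrary `gamma`.
#'
#' @param gamma A 20x4 matrix or length-80 vector.
#' @param stats A [compute_gap_statistics()] result.
#' @return The dimensionless objective value.
#' @export
gap_ratio <- function(gamma, stats) {
  g <- as.numeric(gamma)
  denom <- sqrt(drop(t(g) %*% stats$B %*% g))
  if (denom == 0) return(NA_real_)
  sum(stats$A * g) / denom
}

#' Solve for the optimal interaction energy matrix
#'
#' The gap-to-variance objective is maximized by `gamma` proportional to
#' `B^{-1} A`. To suppress noise from finitely sampled contact types, `B` is
#' eigendecomposed, its eigenvalues are sorted in descending order, and all
#' eigenvalues beyond the leading `n_modes` are replaced by the `n_modes`-th
#' eigenvalue before inversion. The result is scaled to unit Euclidean norm
#' (the physical scale is undetermined; energies are in reduced units) and
#' oriented so that decoys score higher (weaker) than strong binders.
#'
#' @param stats A [compute_gap_statistics()] result.
#' @param n_modes Number of leading eigenmodes retained (default 70), or
#'   `NULL` to retain every numerically nonzero eigenmode — the choice that
#'   maximizes the utilization of the decoy covariance when the sampled
#'   contact types span fewer than 70 dimensions.
#' @param tol Relative eigenvalue tolerance: eigenvalues below
#'   `tol * max(eigenvalue)` count as zero.
#' @param meta Optional named list of training metadata stored on the model.
#' @return An object of class `energy_model` with fields `gamma` (20x4
#'   matrix, unit Frobenius norm), `n_modes`, `provenance = "gap-optimized"`,
#'   and `meta`.
#' @export
solve_gamma <- function(stats, n_modes = 70, tol = 1e-12, meta = list()) {
  d <- feature_dim()
  stopifnot(inherits(stats, "gap_statistics"))
  eig <- eigen(stats$B, symmetric = TRUE)
  vals <- eig$values  # descending
  if (vals[1] <= 0) stop("decoy covariance has no positive eigenvalues")
  ## auto mode count: keep modes carrying at least 0.1% of the leading
  ## variance; contact types that essentially never vary in the decoy
  ## ensemble produce a degenerate eigenvalue tail whose inverse only
  ## amplifies sampling noise in A
  if (is.null(n_modes)) n_modes <- sum(vals > 1e-3 * vals[1])
  stopifnot(n_modes >= 1, n_modes <= d)
  if (vals[n_modes] <= tol * vals[1]) {
    stop("insufficient decoy diversity: eigenvalue ", n_modes,
         " is numerically zero")
  }
  vals_f <- vals
  if (n_modes < d) vals_f[(n_modes + 1L):d] <- vals[n_modes]
  g <- eig$vectors %*% ((t(eig$vectors) %*% stats$A) / vals_f)
  g <- as.numeric(g)
  gap <- sum(stats$A * g)
  if (gap == 0) stop("degenerate training set: zero energy gap")
  if (gap < 0) g <- -g
  g <- g / sqrt(sum(g^2))
  energy_model(matrix(g, nrow = 20L, dimnames = list(aa_alphabet(), nt_alphabet())),
               n_modes = n_modes, provenance = "gap-optimized", meta = meta)
}

#' Energy model container
#'
#' @param gamma 20x4 numeric matrix of amino-acid x nucleotide interaction
#'   energies (reduced units).
#' @param n_modes Retained eigenmodes used in training (`NA` for ridge fits).
#' @param provenance `"gap-optimized"` or `"selex-ridge"`.
#' @param meta Named list of training metadata (complex ids, decoy counts,
#'   seed, switch parameters, ...).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(gamma, n_modes = NA_integer_,
                         provenance = c("gap-optimized", "selex-ridge"),
                         meta = list()) {
  provenance <- match.arg(provenance)
  gamma <- as.matrix(gamma)
  stopifnot(nrow(gamma) == 20L, ncol(gamma) == 4L, all(is.finite(gamma)))
  dimnames(gamma) <- list(aa_alphabet(), nt_alphabet())
  structure(list(gamma = gamma, n_modes = n_modes, provenance = provenance,
                 meta = meta),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Energy model (", x$provenance, "), 20 x 4, n_modes = ",
      x$n_modes, "\n", sep = "")
  cat("  strongest pair:", {
    i <- which.min(x$gamma)
    paste0(aa_alphabet()[(i - 1) %% 20 + 1], "/",
           nt_alphabet()[(i - 1) %/% 20 + 1],
           " (", signif(min(x$gamma), 3), ")")
  }, "\n")
  invisible(x)
}

#' Heatmap of an energy model
#'
#' Draws the 20x4 interaction matrix with amino acids on one axis and the
#' four nucleotides on the other; blue = favorable (low energy), red =
#' unfavorable (high energy).
#'
#' @param x An `energy_model`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.energy_model <- function(x, ...) {
  g <- x$gamma
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  lim <- max(abs(g))
  graphics::image(x = 1:4, y = 1:20, z = t(g), col = pal,
                  zlim = c(-lim, lim), axes = FALSE,
                  xlab = "nucleotide", ylab = "amino acid", ...)
  graphics::axis(1, at = 1:4, labels = nt_alphabet())
  graphics::axis(2, at = 1:20, labels = rownames(g), las = 1, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Predict threaded binding energies
#'
#' `E = sum_{a,n} gamma(a,n) * phi(a,n)` in reduced units; lower energy
#' means stronger predicted binding.
#'
#' @param model An [energy_model()].
#' @param phi A [compute_phi()] matrix, a length-80 vector, or an `n x 80`
#'   matrix of stacked feature vectors.
#' @return Numeric energy (vector when `phi` has stacked rows).
#' @export
predict_energy <- function(model, phi) {
  stopifnot(inherits(model, "energy_model"))
  g <- as.numeric(model$gamma)
  if (is.matrix(phi) && !inherits(phi, "feature_vector") &&
      ncol(phi) == feature_dim() && nrow(phi) != 20L) {
    return(drop(phi %*% g))
  }
  phi <- as.numeric(phi)
  if (length(phi) != feature_dim()) stop("feature vector has wrong dimension")
  sum(g * phi)
}

#' Convert a dissociation-constant ratio to a binding free-energy difference
#'
#' `ddG = R T ln(kd_ratio)` with `R = 1.98720425e-3` kcal/(mol K).
#'
#' @param kd_ratio Positive dimensionless Kd ratio(s).
#' @param temperature Temperature in Kelvin (default 298.15).
#' @return Free-energy difference(s) in kcal/mol.
#' @export
ddg_from_kd <- function(kd_ratio, temperature = 298.15) {
  if (any(kd_ratio <= 0)) stop("kd_ratio must be positive")
  GAS_CONSTANT_KCAL * temperature * log(kd_ratio)
}

#' @rdname ddg_from_kd
#' @param ddg Free-energy difference(s) in kcal/mol.
#' @export
kd_from_ddg <- function(ddg, temperature = 298.15) {
  exp(ddg / (GAS_CONSTANT_KCAL * temperature))
}

#' Fit an energy model to an affinity table by ridge regression
#'
#' Solves `argmin ||Phi gamma - ddg||^2 + alpha ||gamma||^2` in closed form
#' (via the singular value decomposition of `Phi`), yielding an energy model
#' calibrated directly against measured binding free energies, e.g. SELEX-
#' derived tables.
#'
#' @param phi_matrix `n x 80` matrix of stacked feature vectors, one row per
#'   measured sequence.
#' @param ddg Numeric vector of measured free-energy differences, length `n`.
#' @param alpha Ridge regularization parameter (default 0.01).
#' @param meta Optional metadata list.
#' @return An [energy_model()] with provenance `"selex-ridge"`.
#' @export
fit_gamma_selex <- function(phi_matrix, ddg, alpha = 0.01, meta = list()) {
  if (is.list(phi_matrix)) phi_matrix <- do.call(rbind, lapply(phi_matrix, as.numeric))
  stopifnot(is.matrix(phi_matrix), ncol(phi_matrix) == feature_dim(),
            nrow(phi_matrix) >= 2L, nrow(phi_matrix) == length(ddg),
            alpha >= 0)
  if (all(phi_matrix == 0)) stop("all-zero feature matrix")
  sv <- svd(phi_matrix)
  shrink <- sv$d / (sv$d^2 + alpha)
  g <- sv$v %*% (shrink * (t(sv$u) %*% ddg))
  energy_model(matrix(as.numeric(g), nrow = 20L),
               n_modes = NA_integer_, provenance = "selex-ridge",
               meta = c(meta, list(alpha = alpha, n_obs = length(ddg))))
}

#' Train an energy model from complexes and decoy sets
#'
#' Convenience wrapper over the full training path: native (strong-binder)
#' feature vectors from each complex are pooled with the feature vectors of
#' each complex's own decoys into one set of gap statistics, from which
#' [solve_gamma()] learns the interaction matrix. DNA and protein decoys are
#' pooled by default.
#'
#' @param complexes A [cg_complex()] or list of them.
#' @param interfaces Matching [extract_interface()] selection(s).
#' @param decoy_sets Matching [generate_decoys()] result(s).
#' @param params [switch_params()].
#' @param n_modes Retained eigenmodes; `NULL` (default) retains every
#'   numerically nonzero mode.
#' @param decoy_pool `"both"` (default), `"dna"`, or `"protein"`: which decoy
#'   sets enter the statistics.
#' @return An [energy_model()].
#' @export
train_gamma <- function(complexes, interfaces, decoy_sets,
                        params = switch_params(), n_modes = NULL,
                        decoy_pool = c("both", "dna", "protein")) {
  decoy_pool <- match.arg(decoy_pool)
  if (inherits(complexes, "cg_complex")) {
    complexes <- list(complexes); interfaces <- list(interfaces)
    decoy_sets <- list(decoy_sets)
  }
  strong <- list()
  decoys <- list()
  for (k in seq_along(complexes)) {
    pairs <- interface_pairs(complexes[[k]], interfaces[[k]], params)
    strong[[k]] <- as.numeric(compute_phi(complexes[[k]], interfaces[[k]],
                                          params = params, pairs = pairs))
    if (decoy_pool %in% c("both", "dna")) {
      decoys[[length(decoys) + 1L]] <- phi_matrix(
        complexes[[k]], interfaces[[k]], dna_strings = decoy_sets[[k]]$dna,
        params = params, pairs = pairs)
    }
    if (decoy_pool %in% c("both", "protein")) {
      decoys[[length(decoys) + 1L]] <- phi_matrix(
        complexes[[k]], interfaces[[k]], protein_strings = decoy_sets[[k]]$protein,
        params = params, pairs = pairs)
    }
  }
  stats <- compute_gap_statistics(do.call(rbind, lapply(strong, rbind)),
                                  do.call(rbind, decoys))
  meta <- list(
    complexes = vapply(complexes, function(x) x$source, character(1)),
    n_dna_decoys = sum(vapply(decoy_sets, function(d) length(d$dna), numeric(1))),
    n_protein_decoys = sum(vapply(decoy_sets, function(d) length(d$protein), numeric(1))),
    seed = decoy_sets[[1]]$seed,
    switch_params = unclass(params),
    decoy_pool = decoy_pool
  )
  solve_gamma(stats, n_modes = n_modes, meta = meta)
}

#' Serialize an energy model as TSV (+ JSON metadata sidecar)
#'
#' The TSV has 20 rows (one-letter amino acid row names) and 4 columns
#' (`DA`, `DT`, `DC`, `DG`); metadata goes to `<file>.json`.
#'
#' @param model An [energy_model()].
#' @param file Output TSV path.
#' @export
write_gamma_tsv <- function(model, file) {
  stopifnot(inherits(model, "energy_model"))
  df <- data.frame(aa = rownames(model$gamma), model$gamma, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(provenance = model$provenance, n_modes = model$n_modes,
               meta = model$meta)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_gamma_tsv
#' @export
read_gamma_tsv <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE)
  g <- as.matrix(tab[, nt_alphabet()])
  rownames(g) <- tab$aa
  g <- g[aa_alphabet(), , drop = FALSE]
  sidecar <- paste0(file, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  energy_model(g,
               n_modes = if (!is.null(meta) && !is.null(meta$n_modes)) meta$n_modes else NA_integer_,
               provenance = if (!is.null(meta) && !is.null(meta$provenance)) meta$provenance else "gap-optimized",
               meta = if (!is.null(meta)) meta$meta else list())
}
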