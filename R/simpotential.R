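## simpotential: convert a learned interaction matrix into the
## sequence-specific coarse-grained pair potential (tanh contact term) with
## its companion Debye-Hueckel electrostatic and excluded-volume terms, and
## export tabulated (r, E, -dE/dr) tables for simulation engines.

#' Normalize an energy model for use as a simulation interaction matrix
#'
#' `W = gamma / sum(|gamma|)`: signs (attraction/repulsion) are preserved and
#' the summed absolute interaction strength becomes exactly 1, leaving the
#' overall energy scale to an explicit user-supplied prefactor.
#'
#' @param model An [energy_model()] (or a bare 20x4 matrix).
#' @return A 20x4 matrix with `sum(abs(W)) == 1`.
#' @export
normalize_gamma <- function(model) {
  g <- if (inherits(model, "energy_model")) model$gamma else as.matrix(model)
  total <- sum(abs(g))
  if (total == 0) stop("all-zero energy matrix")
  g / total
}

#' Pair-potential parameter set
#'
#' Bundles everything needed to tabulate the protein-DNA pair interaction:
#' the normalized interaction matrix `W` (sum of absolute values 1), the
#' tanh contact term's midpoint `r0` (Angstrom) and steepness `eta`
#' (1/Angstrom), the solvent dielectric constant and Debye screening length
#' for the electrostatic term, and the excluded-volume radius `sigma` and
#' well-depth scale.
#'
#' @param W Normalized 20x4 interaction matrix (see [normalize_gamma()]).
#' @param r0 Contact midpoint in Angstrom (default 8).
#' @param eta Contact steepness in 1/Angstrom (default 0.7).
#' @param epsilon Solvent dielectric constant (default 78.0).
#' @param l_D Debye screening length in Angstrom (default 10).
#' @param sigma Excluded-volume radius in Angstrom (default 4).
#' @param eps_scale Excluded-volume well-depth scale (default 1).
#' @return Object of class `pair_potential_params`.
#' @export
pair_potential_params <- function(W, r0 = 8, eta = 0.7, epsilon = 78.0,
                                  l_D = 10, sigma = 4.0, eps_scale = 1) {
  stopifnot(r0 > 0, eta > 0, epsilon > 0, l_D > 0, sigma > 0, eps_scale >= 0)
  W <- as.matrix(W)
  stopifnot(nrow(W) == 20L, ncol(W) == 4L)
  if (abs(sum(abs(W)) - 1) > 1e-12) {
    stop("W must be normalized: sum(abs(W)) == 1 (use normalize_gamma())")
  }
  dimnames(W) <- list(aa_alphabet(), nt_alphabet())
  structure(list(W = W, r0 = r0, eta = eta, epsilon = epsilon, l_D = l_D,
                 sigma = sigma, eps_scale = eps_scale),
            class = "pair_potential_params")
}

#' Sequence-specific tanh contact potential
#'
#' `V(r) = (w/2) * (1 + tanh(eta * (r0 - r)))`: approaches `w` at contact,
#' passes through `w/2` at `r0`, and decays to 0 beyond the contact range.
#'
#' @param r Distance(s) in Angstrom, non-negative.
#' @param w Interaction strength: one entry of the normalized matrix `W`
#'   (times any overall energy scale).
#' @param r0 Midpoint (default 8 Angstrom).
#' @param eta Steepness (default 0.7 per Angstrom).
#' @return Energy value(s).
#' @export
v_pd <- function(r, w, r0 = 8, eta = 0.7) {
  stopifnot(all(r >= 0))
  (w / 2) * (1 + tanh(eta * (r0 - r)))
}

## analytic force -dV/dr of the tanh contact term:
## V'(r) = -(w/2) * eta * sech^2(eta (r0 - r))
v_pd_force <- function(r, w, r0 = 8, eta = 0.7) {
  (w / 2) * eta * (1 - tanh(eta * (r0 - r))^2)
}

#' Debye-Hueckel screened electrostatic potential
#'
#' `U(r) = (1 / (4 pi eps0)) * (qi qj / (epsilon r)) * exp(-r / l_D)` with
#' the vacuum permittivity taken as 1 (simulation-internal units).
#'
#' @param r Distance(s) in Angstrom, positive.
#' @param qi,qj Charges of the two beads (elementary charges).
#' @param l_D Debye screening length in Angstrom.
#' @param epsilon Solvent dielectric constant (default 78.0).
#' @return Energy value(s).
#' @export
u_elec <- function(r, qi, qj, l_D, epsilon = 78.0) {
  stopifnot(all(r > 0), l_D > 0)
  (1 / (4 * pi)) * (qi * qj / (epsilon * r)) * exp(-r / l_D)
}

u_elec_force <- function(r, qi, qj, l_D, epsilon = 78.0) {
  ## -dU/dr = U(r) * (1/r + 1/l_D)
  u_elec(r, qi, qj, l_D, epsilon) * (1 / r + 1 / l_D)
}

#' Excluded-volume (hard-wall) potential
#'
#' `U(r) = 4 * eps_scale * (sigma / r)^12`.
#'
#' @param r Distance(s) in Angstrom, positive.
#' @param sigma Apparent radius in Angstrom (default 4).
#' @param eps_scale Well-depth scale (default 1).
#' @return Energy value(s).
#' @export
u_exclude <- function(r, sigma = 4.0, eps_scale = 1) {
  stopifnot(all(r > 0))
  4 * eps_scale * (sigma / r)^12
}

u_exclude_force <- function(r, sigma = 4.0, eps_scale = 1) {
  48 * eps_scale * sigma^12 / r^13
}

#' Export tabulated pair potentials
#'
#' Writes one whitespace-separated table per amino-acid/nucleotide pair with
#' columns `r`, `E`, `F` (`F = -dE/dr`, computed analytically), plus a JSON
#' manifest recording all parameters and the energy-model provenance. The
#' tabulated energy is `scale * v_pd(r; W[a,n]) + u_exclude(r)` plus the
#' electrostatic term when both charges are nonzero.
#'
#' @param params A [pair_potential_params()] object.
#' @param dir Output directory (created if needed).
#' @param r_max Largest tabulated distance in Angstrom (default 20).
#' @param dr Grid spacing in Angstrom (default 0.1); the grid covers
#'   `(0, r_max]` and must exclude `r = 0`.
#' @param scale Overall energy scale of the contact term, in kcal/mol; the
#'   training leaves this prefactor undetermined, so it is an explicit user
#'   input (default 1).
#' @param qi,qj Bead charges for the electrostatic term (default 0 = off).
#' @param provenance Free-text note stored in the manifest.
#' @return Invisibly, the manifest path.
#' @export
export_tables <- function(params, dir, r_max = 20, dr = 0.1, scale = 1,
                          qi = 0, qj = 0, provenance = "") {
  stopifnot(inherits(params, "pair_potential_params"), dr > 0, r_max > dr)
  r <- seq(dr, r_max, by = dr)
  if (any(r <= 0)) stop("grid must exclude r = 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  elec_on <- qi * qj != 0
  for (a in seq_len(20L)) {
    for (n in seq_len(4L)) {
      w <- scale * params$W[a, n]
      E <- v_pd(r, w, params$r0, params$eta) +
        u_exclude(r, params$sigma, params$eps_scale)
      Fo <- v_pd_force(r, w, params$r0, params$eta) +
        u_exclude_force(r, params$sigma, params$eps_scale)
      if (elec_on) {
        E <- E + u_elec(r, qi, qj, params$l_D, params$epsilon)
        Fo <- Fo + u_elec_force(r, qi, qj, params$l_D, params$epsilon)
      }
      fname <- file.path(dir, paste0("pair_", aa_alphabet()[a], "_",
                                     nt_alphabet()[n], ".table"))
      header <- c(
        sprintf("# pair potential %s-%s", aa_alphabet()[a], nt_alphabet()[n]),
        sprintf("# W=%.17g scale=%g r0=%g eta=%g sigma=%g eps_scale=%g epsilon=%g l_D=%g qi=%g qj=%g",
                params$W[a, n], scale, params$r0, params$eta, params$sigma,
                params$eps_scale, params$epsilon, params$l_D, qi, qj),
        "# r E F"
      )
      body <- sprintf("%.10g %.17g %.17g", r, E, Fo)
      writeLines(c(header, body), fname)
      files <- c(files, fname)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(files = basename(files), r_max = r_max, dr = dr, scale = scale,
         qi = qi, qj = qj, r0 = params$r0, eta = params$eta,
         sigma = params$sigma, eps_scale = params$eps_scale,
         epsilon = params$epsilon, l_D = params$l_D,
         provenance = provenance),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back an exported pair-potential table
#'
#' @param file A table written by [export_tables()].
#' @return `data.frame` with columns `r`, `E`, `F`.
#' @export
read_potential_table <- function(file) {
  tab <- utils::read.table(file, comment.char = "#")
  names(tab) <- c("r", "E", "F")
  tab
}
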