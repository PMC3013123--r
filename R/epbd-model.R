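#' Boltzmann constant in eV/K
#' @keywords internal
KB_EV <- 8.617333e-5

# Internal unit system: length in Angstrom, mass in amu, energy in eV.
# The derived time unit is t0 = A * sqrt(amu/eV) = 10.1805 fs; all
# user-facing times (fs, ps) are converted at the interface so the
# integrator itself is unit-free.
T0_FS <- 10.180506  # fs per internal time unit
T0_PS <- T0_FS / 1000

ALL_STEPS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))

#' EPBD model parameters
#'
#' Constants of the extended Peyrard-Bishop-Dauxois Hamiltonian: a Morse
#' on-site potential per base pair, `D (exp(-a y) - 1)^2`, with separate
#' depth/width for A:T and G:C pairs, and an anharmonic nearest-neighbour
#' stacking term `(k/2) (1 + rho exp(-beta (y_n + y_{n-1}))) (y_n - y_{n-1})^2`
#' whose harmonic constant may be homogeneous or dinucleotide-step
#' dependent (the "extended" part of the model).
#'
#' Defaults are the standard parameterization of the mesoscopic DNA
#' breathing literature: D_AT = 0.05 eV, D_GC = 0.075 eV, a_AT = 4.2 1/A,
#' a_GC = 6.9 1/A, k = 0.025 eV/A^2, rho = 2, beta = 0.35 1/A, reduced
#' base-pair mass 300 amu. All are overridable here or via a YAML config
#' ([read_epbd_config()]); none is hard-coded in the force/energy kernels.
#'
#' @param D Named numeric, Morse depths in eV for classes `AT` and `GC`.
#' @param a Named numeric, Morse inverse widths in 1/Angstrom.
#' @param k Homogeneous harmonic stacking constant, eV/A^2; used for
#'   every dinucleotide step unless `k_stack` is given.
#' @param k_stack Optional named numeric covering all 16 dinucleotide
#'   steps (eV/A^2); enables the inhomogeneous (sequence-dependent)
#'   stacking table.
#' @param rho Dimensionless anharmonic stacking amplitude (>= 0).
#' @param beta Stacking nonlinearity decay, 1/Angstrom (>= 0).
#' @param mass Reduced base-pair mass, amu.
#' @param allow_inverted_depths Set `TRUE` to permit D_AT >= D_GC
#'   (normally rejected: A:T has two hydrogen bonds, G:C three).
#' @return An `epbd_parameters` object.
#' @export
epbd_parameters <- function(D = c(AT = 0.05, GC = 0.075),
                            a = c(AT = 4.2, GC = 6.9),
                            k = 0.025,
                            k_stack = NULL,
                            rho = 2.0,
                            beta = 0.35,
                            mass = 300,
                            allow_inverted_depths = FALSE) {
  D <- unlist(D); a <- unlist(a)
  stopifnot(all(c("AT", "GC") %in% names(D)), all(c("AT", "GC") %in% names(a)))
  D <- D[c("AT", "GC")]; a <- a[c("AT", "GC")]
  if (any(!is.finite(D)) || any(D <= 0)) stop("Morse depths D must be strictly positive")
  if (any(!is.finite(a)) || any(a <= 0)) stop("Morse inverse widths a must be strictly positive")
  if (!isTRUE(allow_inverted_depths) && D[["AT"]] >= D[["GC"]]) {
    stop("D[AT] must be < D[GC] (two vs three hydrogen bonds); set allow_inverted_depths = TRUE to override")
  }
  if (!is.finite(k) || k <= 0) stop("stacking constant k must be strictly positive")
  if (!is.null(k_stack)) {
    k_stack <- unlist(k_stack)
    missing_steps <- setdiff(ALL_STEPS, names(k_stack))
    if (length(missing_steps) > 0L) {
      stop("inhomogeneous stacking table must cover all 16 dinucleotide steps; missing: ",
           paste(missing_steps, collapse = ", "))
    }
    k_stack <- k_stack[ALL_STEPS]
    if (any(!is.finite(k_stack)) || any(k_stack <= 0)) stop("all stacking constants must be strictly positive")
  }
  if (!is.finite(rho) || rho < 0) stop("rho must be >= 0")
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  if (!is.finite(mass) || mass <= 0) stop("mass must be strictly positive")
  structure(
    list(D = D, a = a, k = as.numeric(k), k_stack = k_stack,
         rho = as.numeric(rho), beta = as.numeric(beta),
         mass = as.numeric(mass), k_B = KB_EV),
    class = "epbd_parameters"
  )
}

#' @export
print.epbd_parameters <- function(x, ...) {
  cat("EPBD parameters\n")
  cat(sprintf("  Morse:    D_AT = %g eV, D_GC = %g eV, a_AT = %g 1/A, a_GC = %g 1/A\n",
              x$D[["AT"]], x$D[["GC"]], x$a[["AT"]], x$a[["GC"]]))
  cat(sprintf("  stacking: %s, rho = %g, beta = %g 1/A\n",
              if (is.null(x$k_stack)) sprintf("homogeneous k = %g eV/A^2", x$k)
              else "inhomogeneous 16-step table",
              x$rho, x$beta))
  cat(sprintf("  mass = %g amu\n", x$mass))
  invisible(x)
}

# Per-site Morse constants for a sequence; per-step stacking constants.
site_constants <- function(seq, params) {
  cls <- base_classes(seq)
  list(D = unname(params$D[cls]), a = unname(params$a[cls]))
}

step_constants <- function(seq, params) {
  steps <- dinucleotide_steps(seq)
  if (is.null(params$k_stack)) rep(params$k, length(steps))
  else unname(params$k_stack[steps])
}

#' Morse on-site potential of a single base pair
#'
#' `V(y) = D (exp(-a y) - 1)^2`: zero at the closed minimum y = 0,
#' approaching the dissociation plateau D as the pair opens.
#'
#' @param y Pair stretch displacement(s), Angstrom.
#' @param base_class `"AT"` or `"GC"`.
#' @param params An [epbd_parameters] object.
#' @return Energy in eV (vectorized over `y`).
#' @export
onsite_potential <- function(y, base_class, params = epbd_parameters()) {
  stopifnot(inherits(params, "epbd_parameters"))
  if (!base_class %in% c("AT", "GC")) stop("unknown base class: ", base_class)
  D <- params$D[[base_class]]; a <- params$a[[base_class]]
  D * (exp(-a * y) - 1)^2
}

#' Anharmonic stacking potential of one dinucleotide step
#'
#' `W = (k/2) (1 + rho exp(-beta (y_n + y_prev))) (y_n - y_prev)^2`.
#' Harmonic with stiffness k(1 + rho) near the closed state, softening
#' toward k as both neighbours open — the entropic driving force of
#' cooperative bubble formation.
#'
#' @param y_n,y_prev Displacements of the step's two base pairs, Angstrom.
#' @param step Dinucleotide string such as `"AT"` (5'->3'); only
#'   consulted when the inhomogeneous table is enabled.
#' @param params An [epbd_parameters] object.
#' @return Energy in eV.
#' @export
stacking_potential <- function(y_n, y_prev, step = "AA", params = epbd_parameters()) {
  stopifnot(inherits(params, "epbd_parameters"))
  k <- if (is.null(params$k_stack)) params$k else {
    if (!step %in% ALL_STEPS) stop("unknown dinucleotide step: ", step)
    params$k_stack[[step]]
  }
  (k / 2) * (1 + params$rho * exp(-params$beta * (y_n + y_prev))) * (y_n - y_prev)^2
}

#' Total EPBD potential energy of a chain configuration
#'
#' Sum of per-site Morse terms and per-step stacking terms with open
#' boundaries (the terminal base pairs have a single stacking partner).
#'
#' @param y Numeric vector of pair stretches, Angstrom, one per base pair.
#' @param seq A [promoter_sequence] of matching length.
#' @param params An [epbd_parameters] object.
#' @return Total energy in eV; 0 iff `y` is identically 0.
#' @export
total_potential <- function(y, seq, params = epbd_parameters()) {
  stopifnot(inherits(seq, "promoter_sequence"), inherits(params, "epbd_parameters"))
  n <- nchar(seq$bases)
  if (length(y) != n) stop(sprintf("state length %d != sequence length %d", length(y), n))
  sc <- site_constants(seq, params)
  onsite <- sum(sc$D * (exp(-sc$a * y) - 1)^2)
  ks <- step_constants(seq, params)
  dy <- diff(y)
  s <- y[-1L] + y[-n]
  stacking <- sum((ks / 2) * (1 + params$rho * exp(-params$beta * s)) * dy^2)
  onsite + stacking
}

#' Analytic force vector of the EPBD potential
#'
#' Exact closed-form gradient `F_n = -d/dy_n total_potential`, including
#' the derivative of the `rho exp(-beta (y_n + y_{n-1}))` stacking
#' factor. Evaluated in compiled code (the same kernel the Langevin
#' integrator uses).
#'
#' @inheritParams total_potential
#' @return Numeric vector of forces, eV/Angstrom.
#' @export
total_force <- function(y, seq, params = epbd_parameters()) {
  stopifnot(inherits(seq, "promoter_sequence"), inherits(params, "epbd_parameters"))
  n <- nchar(seq$bases)
  if (length(y) != n) stop(sprintf("state length %d != sequence length %d", length(y), n))
  sc <- site_constants(seq, params)
  ks <- step_constants(seq, params)
  cpp_total_force(as.numeric(y), sc$D, sc$a, ks, params$rho, params$beta)
}

#' Read / write EPBD parameter configuration
#'
#' Human-readable YAML holding every Hamiltonian constant, so that runs
#' can echo their full effective parameterization for provenance.
#'
#' @param path YAML file path.
#' @return For `read_epbd_config`, an [epbd_parameters] object.
#' @export
read_epbd_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(epbd_parameters, cfg[intersect(names(cfg),
    c("D", "a", "k", "k_stack", "rho", "beta", "mass", "allow_inverted_depths"))])
}

#' @rdname read_epbd_config
#' @param params An [epbd_parameters] object to serialize.
#' @export
write_epbd_config <- function(params, path) {
  stopifnot(inherits(params, "epbd_parameters"))
  yaml::write_yaml(list(D = as.list(params$D), a = as.list(params$a),
                        k = params$k,
                        k_stack = if (is.null(params$k_stack)) NULL else as.list(params$k_stack),
                        rho = params$rho, beta = params$beta, mass = params$mass),
                   path)
  invisible(path)
}
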