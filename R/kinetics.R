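#' Define a sequential photocycle scheme
#'
#' A unidirectional chain of compartments (e.g. singlet excited flavin
#' \eqn{^1}FMN* -> triplet \eqn{^3}FMN* -> cysteinyl adduct A390 -> signaling
#' state SIG) in which compartment \eqn{i} decays with time constant
#' \eqn{\tau_i} and a branching yield \eqn{\phi_i \in (0,1]} of that decay
#' proceeds forward, the remainder returning directly to the ground state.
#' \eqn{\phi_1} is where the intersystem-crossing quantum yield
#' \eqn{\Phi_{ISC}} lives. Time constants must be strictly ascending: the
#' photocycle is a strictly slowing cascade and the ordering convention makes
#' compartment identity unambiguous.
#'
#' @param tau time constants in seconds, strictly ascending, all positive.
#'   One per compartment when \code{terminal_decays}, otherwise one per
#'   non-terminal compartment (the last compartment is a stable photoproduct
#'   on the observation window).
#' @param phi forward branching yields in (0, 1], one per transition
#'   (\code{n_compartments - 1} values). Default all 1 (no loss).
#' @param names compartment labels; defaults to \code{S1, S2, ...}.
#' @param terminal_decays logical; does the last compartment decay back to
#'   the dark-adapted ground state within the model?
#' @return An object of class \code{"kinetic_scheme"}.
#' @examples
#' # YF1-like: ISC in 2 ns, adduct formation in 8.7 us, recovery in 3800 s
#' kinetic_scheme(tau = c(2e-9, 8.7e-6, 3800), phi = c(0.65, 1),
#'                names = c("1FMN*", "3FMN*", "A390"), terminal_decays = TRUE)
#' @export
kinetic_scheme <- function(tau, phi = NULL, names = NULL,
                           terminal_decays = TRUE) {
  tau <- as.numeric(tau)
  if (length(tau) < 1 || !all(is.finite(tau)) || any(tau <= 0)) {
    stop("tau must be positive and finite", call. = FALSE)
  }
  if (any(diff(tau) <= 0)) {
    stop("tau must be strictly ascending (slowing-cascade convention)",
         call. = FALSE)
  }
  n <- if (terminal_decays) length(tau) else length(tau) + 1L
  if (is.null(phi)) phi <- rep(1, max(n - 1L, 0L))
  phi <- as.numeric(phi)
  if (length(phi) != n - 1L) {
    stop("need ", n - 1L, " branching yields for ", n, " compartments, got ",
         length(phi), call. = FALSE)
  }
  if (any(phi <= 0 | phi > 1)) {
    stop("branching yields must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names)) names <- paste0("S", seq_len(n))
  if (length(names) != n) stop("need ", n, " compartment names", call. = FALSE)
  structure(
    list(names = as.character(names), tau = tau, phi = phi,
         terminal_decays = isTRUE(terminal_decays)),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  n <- n_compartments(x)
  cat("<kinetic_scheme> ", paste(x$names, collapse = " -> "),
      if (x$terminal_decays) " -> ground" else "", "\n", sep = "")
  cat("  tau [s]: ", paste(format(x$tau, digits = 4), collapse = ", "), "\n",
      sep = "")
  if (n > 1) {
    cat("  phi:     ", paste(format(x$phi, digits = 4), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of compartments of a kinetic scheme
#' @param scheme a [kinetic_scheme()].
#' @return integer count.
#' @export
n_compartments <- function(scheme) {
  length(scheme$tau) + as.integer(!scheme$terminal_decays)
}

#' Separate near-degenerate rate constants
#'
#' The closed-form sequential solution divides by pairwise rate differences
#' \eqn{k_l - k_i}; when two time constants coincide to within 1e-9 relative
#' the denominators are ill-conditioned. This helper perturbs the later
#' member of any such pair multiplicatively by 1e-6, which keeps the
#' closed form within ~1e-6 of the exact (confluent) solution while avoiding
#' special-case formulas.
#'
#' @param tau ascending time constants in seconds.
#' @return The (possibly perturbed) time constants, still ascending.
#' @export
resolve_degenerate_rates <- function(tau) {
  tau <- as.numeric(tau)
  if (length(tau) < 2) return(tau)
  eps_rel <- 1e-9
  bump <- 1e-6
  for (j in 2:length(tau)) {
    k <- 1 / tau
    rel <- abs(k[j] - k[seq_len(j - 1)]) / pmax(k[j], k[seq_len(j - 1)])
    while (any(rel < eps_rel)) {
      tau[j] <- tau[j] * (1 + bump)
      pk_log("resolve_degenerate_rates: perturbed tau[%d] to %.9g s", j,
             tau[j])
      k <- 1 / tau
      rel <- abs(k[j] - k[seq_len(j - 1)]) / pmax(k[j], k[seq_len(j - 1)])
    }
  }
  tau
}

#' Closed-form populations of the sequential photocycle
#'
#' Evaluates the Bateman solution of the decay chain with branching losses:
#' \deqn{c_1(t) = e^{-k_1 t}, \qquad
#'   c_j(t) = \Big(\prod_{i<j} \phi_i k_i\Big)
#'   \sum_{i \le j} \frac{e^{-k_i t}}{\prod_{l \le j,\, l \ne i} (k_l - k_i)}}
#' with rates \eqn{k_i = 1/\tau_i}. A non-decaying terminal compartment is
#' handled as the limit \eqn{k_n = 0} of the same formula, which gives the
#' accumulating photoproduct population. Excitation is treated as
#' instantaneous at \eqn{t = 0}: the fastest fitted process (~2 ns ISC) is
#' four orders of magnitude slower than a femtosecond pump pulse, so
#' instrument-response convolution is omitted.
#'
#' @param scheme a [kinetic_scheme()].
#' @param t time axis in seconds (positive, ascending) or a numeric vector.
#' @return Matrix of dimension \code{length(t) x n_compartments}, columns
#'   named after the compartments. Entries lie in [0, 1]; row sums are <= 1
#'   (branching loses population to the ground state).
#' @examples
#' sc <- kinetic_scheme(tau = c(2, 4), names = c("A", "B"))
#' cp <- concentration_profiles(sc, t = c(1, 2, 5))
#' @export
concentration_profiles <- function(scheme, t) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  t <- as.numeric(t)
  if (!all(is.finite(t)) || any(t < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  n <- n_compartments(scheme)
  tau <- resolve_degenerate_rates(scheme$tau)
  k <- 1 / tau
  if (!scheme$terminal_decays) k <- c(k, 0)  # accumulating photoproduct
  phi <- scheme$phi
  cmat <- matrix(0, nrow = length(t), ncol = n)
  cmat[, 1] <- exp(-k[1] * t)
  if (n > 1) {
    for (j in 2:n) {
      pref <- prod(phi[seq_len(j - 1)] * k[seq_len(j - 1)])
      acc <- numeric(length(t))
      for (i in seq_len(j)) {
        denom <- prod(k[setdiff(seq_len(j), i)] - k[i])
        acc <- acc + exp(-k[i] * t) / denom
      }
      cmat[, j] <- pref * acc
    }
  }
  # clip the tiny negative excursions of catastrophic-cancellation origin
  cmat[cmat < 0 & cmat > -1e-12] <- 0
  colnames(cmat) <- scheme$names
  cmat
}
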