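# Model parameters: the 41 rate constants, capacities and Hill exponents of
# the thermosensing cascade and the peripheral clock gene network.

# canonical order; this order is frozen and mirrored by the compiled RHS
.param_names <- c(
  # thermosensing cascade + HSF1/HSP module (17)
  "vact0_ts1", "vact1_ts1", "vina_ts1", "vb_ts2", "kb_ts2", "n", "vd_ts2",
  "kT", "KT", "vact_hsf1", "HSF1tot", "vina_hsf1", "vb_hsp", "vd_hsp",
  "khsf1", "Khsf1", "khsf1_ci",
  # peripheral clock gene network (24)
  "v1b", "c", "k1b", "k1i", "p", "k1d", "k2b", "q", "k2d", "k2t", "k3t",
  "k3d", "v4b", "k4b", "r", "k4d", "k5b", "k5d", "k5t", "k6t", "k6d",
  "k6a", "k7a", "k7d"
)

.param_defaults <- c(
  vact0_ts1 = 0.13, vact1_ts1 = 0.65, vina_ts1 = 0.65, vb_ts2 = 8,
  kb_ts2 = 20, n = 3, vd_ts2 = 0.45, kT = 27.17, KT = 3.68,
  vact_hsf1 = 0.33, HSF1tot = 20.89, vina_hsf1 = 20.65, vb_hsp = 8.72,
  vd_hsp = 2.37, khsf1 = 39.97, Khsf1 = 1.07, khsf1_ci = 1,
  v1b = 9, c = 0.01, k1b = 1, k1i = 0.56, p = 8, k1d = 0.12, k2b = 0.3,
  q = 2, k2d = 0.05, k2t = 0.24, k3t = 0.02, k3d = 0.12, v4b = 3.6,
  k4b = 2.16, r = 3, k4d = 0.75, k5b = 0.24, k5d = 0.06, k5t = 0.45,
  k6t = 0.06, k6d = 0.12, k6a = 0.09, k7a = 0.003, k7d = 0.09
)

.hill_names <- c("n", "p", "q", "r")

# the 15 estimated cascade/entrainment parameters (Hill exponent n and the
# fixed competition constant khsf1_ci excluded) -- the default set varied,
# together with the 24 clock parameters, when building cell populations
.cascade_varied <- setdiff(.param_names[1:17], c("n", "khsf1_ci"))
.clock_varied <- .param_names[18:41]

.state_names <- c("TS1", "TS2", "actHSF1", "indHSP", "PerCry_mRNA", "PERCRY",
                  "nucPERCRY", "Bmal1_mRNA", "BMAL1", "nucBMAL1", "CLOCKBMAL1")

#' Nominal model parameters
#'
#' Returns the 41 nominal parameter values of the temperature-entrainment
#' circadian model as a one-row tibble, one column per parameter. Units:
#' activation rates of TS1 in nM h^-1 degC^-1, first-order rates in h^-1,
#' capacities and Michaelis constants in nM, Hill exponents and coupling
#' strengths dimensionless.
#'
#' @return A one-row tibble with 41 numeric columns.
#' @export
#' @examples
#' default_params()$vact0_ts1  # 0.13
default_params <- function() {
  tibble::as_tibble(as.list(.param_defaults))
}

#' Construct a model parameter set
#'
#' Starts from the nominal values and applies named overrides, validating
#' positivity (all rates, capacities and Michaelis constants must be >= 0)
#' and Hill exponents (n, p, q, r >= 1). Unknown parameter names are
#' rejected.
#'
#' @param ... Named numeric overrides, e.g. `khsf1 = 0`.
#' @param .base One-row data frame (or named vector) to start from instead
#'   of the nominal set.
#' @return A one-row tibble with 41 numeric columns.
#' @export
#' @examples
#' clock_params(khsf1 = 0)  # decouple the clock from the cascade
clock_params <- function(..., .base = default_params()) {
  over <- list(...)
  base <- as_param_vector(.base)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), .param_names)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    base[names(over)] <- vapply(over, as.numeric, numeric(1))
  }
  validate_params(base)
  tibble::as_tibble(as.list(base))
}

# accept a one-row data frame or a named vector; return named vector in
# canonical order
as_param_vector <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1L)
    params <- unlist(params[1, , drop = FALSE])
  }
  if (is.null(names(params))) {
    stop("parameters must be named", call. = FALSE)
  }
  extra <- setdiff(names(params), c(.param_names, "cell", "subject"))
  if (length(extra)) {
    stop("unknown parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.param_names, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params[.param_names]
}

# rows of a parameter table -> matrix ncell x 41 in canonical order
as_param_matrix <- function(params) {
  if (is.data.frame(params)) {
    missing <- setdiff(.param_names, names(params))
    if (length(missing)) {
      stop("missing parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(params[, .param_names, drop = FALSE])
  } else {
    m <- matrix(as_param_vector(params), nrow = 1,
                dimnames = list(NULL, .param_names))
  }
  storage.mode(m) <- "double"
  m
}

validate_params <- function(pv) {
  bad <- names(pv)[!is.finite(pv) | pv < 0]
  if (length(bad)) {
    stop("parameter(s) must be finite and >= 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hill <- pv[.hill_names]
  if (any(hill < 1)) {
    stop("Hill exponent(s) must be >= 1: ",
         paste(.hill_names[hill < 1], collapse = ", "), call. = FALSE)
  }
  invisible(pv)
}

#' Default initial state
#'
#' All eleven components start at 1 nM; simulations discard a burn-in
#' (480 h by default in the metrics) so results do not depend on this
#' choice -- the entrained limit cycle is attracting for nominal parameters.
#'
#' @return Named numeric vector of length 11 (nM).
#' @export
default_init <- function() {
  stats::setNames(rep(1, length(.state_names)), .state_names)
}

#' Model state component names
#'
#' The frozen ordering of the 11 state variables: the thermosensing
#' intermediates (TS1, TS2), the heat-shock module (actHSF1, indHSP) and the
#' clock gene network (Per/Cry mRNA through the CLOCK/BMAL1 complex).
#'
#' @return Character vector of length 11.
#' @export
state_names <- function() .state_names

#' Model parameter names
#'
#' @return Character vector of the 41 parameter names in canonical order.
#' @export
param_names <- function() .param_names
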