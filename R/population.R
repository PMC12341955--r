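# Heterogeneous cell populations and individual subjects: quasi-random
# parameter sampling and shared-schedule ensemble simulation.

#' Sample a heterogeneous cell population
#'
#' Draws `n` parameter sets around a nominal set using the Sobol sequence.
#' By default the 15 estimated cascade parameters vary uniformly within
#' +/- 10% of nominal and the 24 clock parameters within +/- 2% (the Hill
#' exponent of TS2 production and the fixed competition constant khsf1_ci
#' are held at nominal). The clock range sets the intrinsic-period
#' dispersion (sd ~ 0.2 h around the ~23.8 h free-run), calibrated so the
#' nominal 3 degC rhythm entrains the population robustly while a 1 degC
#' rhythm synchronizes it only partially; heterogeneity comes entirely
#' from the parameters, while every cell shares one initial state.
#'
#' @param n Number of cells (>= 2 for ensemble metrics).
#' @param nominal Nominal parameter set the ranges are centred on.
#' @param vary Character vector of parameter names to vary.
#' @param range_frac Half-width of the uniform range as a fraction of
#'   nominal: a scalar applied to every varied parameter, a named vector
#'   of per-parameter fractions, or `NULL` for the calibrated default
#'   (0.10 cascade / 0.02 clock).
#' @param seed Integer seed for the Sobol digital shift; a fixed seed gives
#'   identical samples on every call.
#' @param skip Sobol points to skip.
#' @return A tibble with a `cell` column and the 41 parameter columns.
#' @export
#' @examples
#' pop <- sample_population(5, seed = 1)
#' range(pop$vb_ts2) / 8  # within 0.9 .. 1.1
sample_population <- function(n = 200, nominal = default_params(),
                              vary = c(.cascade_varied, .clock_varied),
                              range_frac = NULL, seed = 0, skip = 0) {
  stopifnot(n >= 1)
  nom <- as_param_vector(nominal)
  unknown <- setdiff(vary, .param_names)
  if (length(unknown)) {
    stop("unknown parameter(s) in `vary`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(range_frac)) {
    range_frac <- ifelse(vary %in% .clock_varied, 0.02, 0.10)
  } else if (length(range_frac) == 1L) {
    range_frac <- rep(range_frac, length(vary))
  } else {
    range_frac <- range_frac[vary]
  }
  names(range_frac) <- vary
  stopifnot(all(is.finite(range_frac)), all(range_frac >= 0),
            all(range_frac < 1))
  mat <- matrix(rep(nom, each = n), nrow = n,
                dimnames = list(NULL, .param_names))
  active <- vary[range_frac > 0]
  if (length(active)) {
    u <- sobol_points(n, length(active), seed = seed, skip = skip)
    lo <- nom[active] * (1 - range_frac[active])
    hi <- nom[active] * (1 + range_frac[active])
    for (j in seq_along(active)) {
      mat[, active[j]] <- lo[j] + u[, j] * (hi[j] - lo[j])
    }
  }
  if (any(mat[, setdiff(.param_names, .hill_names)] < 0) ||
      any(mat[, .hill_names] < 1)) {
    stop("sampling range produced invalid parameter values", call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(cell = seq_len(n)),
                   tibble::as_tibble(as.data.frame(mat)))
}

#' Sample individual subjects' temperature-sensing triples
#'
#' Each subject is characterised by an individualised thermosensing triple
#' (vact0_ts1, vact1_ts1, kb_ts2), drawn log-uniformly within
#' \[`lower` x, `upper` x\] nominal by Sobol sampling. All other parameters
#' stay nominal.
#'
#' @param n Number of subjects.
#' @param nominal Nominal parameter set.
#' @param lower,upper Multiplicative range of the log-uniform draw.
#' @param seed Integer seed for the Sobol digital shift.
#' @return A tibble with `subject`, `vact0_ts1`, `vact1_ts1`, `kb_ts2`.
#' @export
sample_individuals <- function(n = 50, nominal = default_params(),
                               lower = 0.5, upper = 2, seed = 0) {
  stopifnot(n >= 1, lower > 0, upper > lower)
  nom <- as_param_vector(nominal)
  who <- c("vact0_ts1", "vact1_ts1", "kb_ts2")
  u <- sobol_points(n, 3, seed = seed)
  fac <- exp(log(lower) + u * (log(upper) - log(lower)))
  out <- sweep(fac, 2, nom[who], `*`)
  colnames(out) <- who
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n)),
                   tibble::as_tibble(as.data.frame(out)))
}

#' Simulate a cell population under a shared schedule
#'
#' Integrates every cell of a parameter table under the same temperature
#' schedule on a shared output grid. Cells are mathematically uncoupled --
#' entrainment acts only through the shared zeitgeber -- and are stacked
#' into one ODE system so a segment is integrated once for all cells.
#'
#' @param cells Parameter table from [sample_population()] (one row per
#'   cell; a `cell` id column is optional).
#' @param schedule A `temp_schedule`.
#' @param t_end Horizon, h.
#' @param dt Output grid spacing, h (0.25 by default for ensembles).
#' @param keep State components to retain (all 11 by default; keep fewer
#'   for long runs to bound memory).
#' @param init Shared initial state.
#' @param rtol,atol Solver tolerances (ensemble defaults trade a little
#'   tightness for speed; metrics need ~1e-3).
#' @param method deSolve method for the stacked system; `"adams"`
#'   (non-stiff, Jacobian-free) by default.
#' @return A `clock_ensemble`: list with `time_h`, `components` (named list
#'   of cells x time matrices), `cells` (the parameter table), `schedule`.
#' @export
#' @examples
#' \donttest{
#' ens <- simulate_population(sample_population(5), t_end = 480,
#'                            keep = "PerCry_mRNA")
#' r_syn(ens, "PerCry_mRNA", window = c(240, 480))
#' }
simulate_population <- function(cells, schedule = pattern_schedule(),
                                t_end = 1680, dt = 0.25,
                                keep = state_names(),
                                init = default_init(),
                                rtol = 1e-6, atol = 1e-9,
                                method = "adams") {
  pm <- as_param_matrix(cells)
  n <- nrow(pm)
  stopifnot(n >= 1)
  keep <- match.arg(keep, .state_names, several.ok = TRUE)
  out <- .integrate_piecewise(pm, schedule, t_end, dt, init,
                              rtol, atol, method)
  time_h <- out[, 1]
  comps <- lapply(keep, function(cmp) {
    j <- match(cmp, .state_names)
    m <- t(out[, 1 + j + 11 * (seq_len(n) - 1), drop = FALSE])
    rownames(m) <- NULL
    m
  })
  names(comps) <- keep
  structure(list(time_h = time_h, components = comps,
                 cells = if (is.data.frame(cells)) tibble::as_tibble(cells)
                         else tibble::as_tibble(as.list(pm[1, ])),
                 schedule = schedule, dt = dt),
            class = "clock_ensemble")
}

#' @export
print.clock_ensemble <- function(x, ...) {
  cat(sprintf("<clock_ensemble> %d cells x %d time points (%g-%g h), components: %s\n",
              nrow(x$components[[1]]), length(x$time_h), min(x$time_h),
              max(x$time_h), paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' Ensemble mean-field time series
#'
#' Pointwise mean over cells of one component on the shared grid.
#'
#' @param ensemble A `clock_ensemble`.
#' @param component State component name.
#' @return A tibble with `time_h` and `value`.
#' @export
ensemble_average <- function(ensemble, component = "PerCry_mRNA") {
  m <- .ens_component(ensemble, component)
  tibble::tibble(time_h = ensemble$time_h, value = colMeans(m))
}

.ens_component <- function(ensemble, component) {
  stopifnot(inherits(ensemble, "clock_ensemble"))
  m <- ensemble$components[[component]]
  if (is.null(m)) {
    stop("component not stored in this ensemble: ", component,
         call. = FALSE)
  }
  m
}

#' @export
tidy.clock_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$components, function(m, cmp) {
    tibble::tibble(component = cmp,
                   cell = rep(seq_len(nrow(m)), times = ncol(m)),
                   time_h = rep(x$time_h, each = nrow(m)),
                   value = as.vector(m))
  })
}
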