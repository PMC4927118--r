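#' Build the coefficient set of the proteome-allocation constraint
#'
#' Assembles per-reaction allocation weights from a classified model. Each
#' enzymatic reaction receives an E-sector weight `w_i` (g h/mmol) applied to
#' both flux directions; the designated carbon-source exchange carries `w_C`
#' on its uptake direction; the biomass reaction carries `w_R` (h) so that the
#' growth rate enters the single allocation row
#' \deqn{w_C v_C + \sum_i w_i |v_i| + w_R \lambda \le \phi_{max}.}
#' Exchanges, carbon-intake pathway reactions and the maintenance reaction
#' carry no weight; transports optionally receive a tiny loop-suppressing
#' weight `eps_weight` on both directions.
#'
#' @param model a classified [metabolic_model].
#' @param w named numeric vector of E-sector weights covering every enzymatic
#'   reaction, or a single value applied uniformly.
#' @param w_C proteome cost per unit carbon influx (g h/mmol).
#' @param w_R proteome cost per unit growth rate (h); 0.169 h for
#'   carbon-limited E. coli.
#' @param phi_max growth-rate-dependent proteome budget, dimensionless
#'   (0.484 for E. coli K-12 MG1655).
#' @param eps_weight small weight (g h/mmol) suppressing futile loops among
#'   excluded reactions; applied to categories in `eps_categories`.
#' @param eps_categories categories receiving `eps_weight`.
#' @return an object of class `cafba_weights` with per-direction weight
#'   vectors `w_fwd`, `w_bwd`, the E-sector map `w_i`, and the scalar
#'   parameters.
#' @export
cafba_weights <- function(model, w, w_C, w_R, phi_max,
                          eps_weight = 1e-9, eps_categories = "transport") {
  stopifnot(w_C >= 0, w_R >= 0, phi_max >= 0, all(w >= 0))
  enz <- model$reactions[model$category == "enzymatic"]
  if (length(w) == 1L && is.null(names(w)))
    w <- stats::setNames(rep(w, length(enz)), enz)
  missing_w <- setdiff(enz, names(w))
  if (length(missing_w))
    stop("no weight for enzymatic reaction(s): ",
         paste(missing_w, collapse = ", "))
  n <- length(model$reactions)
  w_fwd <- w_bwd <- stats::setNames(numeric(n), model$reactions)
  w_fwd[enz] <- w_bwd[enz] <- w[enz]
  epsr <- model$reactions[model$category %in% eps_categories]
  w_fwd[epsr] <- w_bwd[epsr] <- eps_weight
  if (!is.na(model$carbon_source))
    w_bwd[model$carbon_source] <- w_C # uptake is the negative flux direction
  w_fwd[model$biomass_reaction] <- w_R
  structure(list(w_fwd = w_fwd, w_bwd = w_bwd,
                 w_i = w[enz],
                 w_C = w_C, w_R = w_R, phi_max = phi_max,
                 eps_weight = eps_weight, eps_categories = eps_categories,
                 spec = NULL, seed = NULL),
            class = "cafba_weights")
}

#' @export
print.cafba_weights <- function(x, ...) {
  cat("<cafba_weights>  w_C =", x$w_C, " w_R =", x$w_R,
      " phi_max =", x$phi_max, "\n")
  cat("  E-sector weights:", length(x$w_i), "reactions,",
      if (length(unique(round(x$w_i, 12))) == 1L)
        paste("homogeneous w_E =", x$w_i[1])
      else sprintf("range [%.3g, %.3g]", min(x$w_i), max(x$w_i)), "\n")
  invisible(x)
}

#' Update the control parameters of a weight set
#'
#' Replaces `w_C` and/or `w_R` while keeping the E-sector weights fixed;
#' used by sweeps over carbon or translational limitation.
#'
#' @param weights a [cafba_weights] object.
#' @param model the model the weights were built for.
#' @param w_C,w_R new values (NULL keeps the current one).
#' @return the updated weights.
#' @export
set_control <- function(weights, model, w_C = NULL, w_R = NULL) {
  if (!is.null(w_C)) {
    stopifnot(w_C >= 0)
    weights$w_C <- w_C
    if (!is.na(model$carbon_source))
      weights$w_bwd[model$carbon_source] <- w_C
  }
  if (!is.null(w_R)) {
    stopifnot(w_R >= 0)
    weights$w_R <- w_R
    weights$w_fwd[model$biomass_reaction] <- w_R
  }
  weights
}

#' Homogeneous E-sector weights
#'
#' Sets every enzymatic weight to the same value `w_E`, the parameterization
#' in which a single number controls the cost of the entire biosynthetic
#' sector.
#'
#' @inheritParams cafba_weights
#' @param w_E uniform E-sector weight (g h/mmol).
#' @return a [cafba_weights] object.
#' @export
homogeneous_weights <- function(model, w_E, w_C, w_R, phi_max, ...) {
  stopifnot(w_E >= 0)
  cafba_weights(model, w = w_E, w_C = w_C, w_R = w_R, phi_max = phi_max, ...)
}

#' Specification of a heterogeneous weight distribution
#'
#' The log-uniform family has density \eqn{p(w) \propto 1/w} on
#' \eqn{[w_{min}, w_{max}]} and is fully determined by its mean `mean_w` and
#' decade width `delta` = log10(w_max/w_min): with \eqn{r = 10^\delta},
#' \eqn{w_{min} = \langle w\rangle \ln(r)/(r-1)} and
#' \eqn{w_{max} = r\, w_{min}}, so the analytic mean equals `mean_w` exactly.
#' The log-normal family is parameterized by its mean and the standard
#' deviation of log(w).
#'
#' @param family `"log_uniform"`, `"log_normal"` or `"homogeneous"`.
#' @param mean_w distribution mean (g h/mmol).
#' @param delta decade width (log-uniform only); `delta = 1` spans one order
#'   of magnitude.
#' @param sigma_log standard deviation of the natural log (log-normal only).
#' @param seed integer seed for reproducible sampling.
#' @return an object of class `weight_spec`.
#' @export
weight_spec <- function(family = c("log_uniform", "log_normal", "homogeneous"),
                        mean_w, delta = 1, sigma_log = 1, seed = 1L) {
  family <- match.arg(family)
  stopifnot(mean_w > 0, delta >= 0, sigma_log >= 0)
  structure(list(family = family, mean_w = mean_w, delta = delta,
                 sigma_log = sigma_log, seed = as.integer(seed)),
            class = "weight_spec")
}

log_uniform_bounds <- function(mean_w, delta) {
  if (delta == 0) return(c(mean_w, mean_w))
  r <- 10^delta
  w_min <- mean_w * log(r) / (r - 1)
  c(w_min, r * w_min)
}

# map i.i.d. uniform(0,1) quantiles to weights under the spec
quantiles_to_weights <- function(u, spec) {
  switch(spec$family,
         homogeneous = rep(spec$mean_w, length(u)),
         log_uniform = {
           b <- log_uniform_bounds(spec$mean_w, spec$delta)
           b[1] * (b[2] / b[1])^u
         },
         log_normal = {
           mu <- log(spec$mean_w) - spec$sigma_log^2 / 2
           exp(mu + spec$sigma_log * stats::qnorm(u))
         })
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a heterogeneous weight set
#'
#' Draws one i.i.d. weight per enzymatic reaction from the distribution in
#' `spec`; reproducible given `spec$seed`.
#'
#' @inheritParams cafba_weights
#' @param spec a [weight_spec].
#' @return a [cafba_weights] object carrying the spec and seed as provenance.
#' @export
sample_weights <- function(model, spec, w_C, w_R, phi_max, ...) {
  stopifnot(inherits(spec, "weight_spec"))
  enz <- model$reactions[model$category == "enzymatic"]
  u <- with_seed(spec$seed, stats::runif(length(enz)))
  w <- stats::setNames(quantiles_to_weights(u, spec), enz)
  wt <- cafba_weights(model, w = w, w_C = w_C, w_R = w_R,
                      phi_max = phi_max, ...)
  wt$spec <- spec
  wt$seed <- spec$seed
  wt
}

#' Calibrate the homogeneous weight to a target maximal growth rate
#'
#' Finds `w_E` such that the optimal growth rate at the given control
#' parameters (conventionally `w_C = 0`, i.e. saturating carbon) matches
#' `lambda_target`, by bisection on the monotone map `w_E` to `lambda*`.
#'
#' @inheritParams cafba_weights
#' @param lambda_target target growth rate (1/h).
#' @param tol calibration tolerance on the growth rate (1/h).
#' @param w_E_start initial upper-bracket guess, doubled until it
#'   under-shoots the target.
#' @param max_iter bisection iteration cap.
#' @return calibrated `w_E` (g h/mmol), with attributes `lambda`,
#'   `iterations` and `bracket`.
#' @export
calibrate_homogeneous <- function(model, lambda_target, w_C = 0, w_R, phi_max,
                                  tol = 1e-3, w_E_start = 1e-3,
                                  max_iter = 200, ...) {
  f <- function(w_E) {
    s <- solve_cafba(model,
                     homogeneous_weights(model, w_E, w_C, w_R, phi_max, ...))
    if (s$status != "optimal") stop("solve failed during calibration (w_E = ",
                                    w_E, "): ", s$status)
    s$growth_rate
  }
  calibrate_scalar(f, lambda_target, tol, w_E_start, max_iter,
                   what = "w_E")
}

calibrate_scalar <- function(f, target, tol, hi_start, max_iter, what) {
  lam0 <- f(0)
  if (lam0 < target - tol)
    stop("target growth rate ", target, "/h unachievable: ceiling at ",
         what, " = 0 is ", signif(lam0, 6), "/h")
  if (abs(lam0 - target) <= tol)
    return(structure(0, lambda = lam0, iterations = 0L, bracket = c(0, 0)))
  lo <- 0; hi <- hi_start
  it <- 0L
  while (f(hi) > target && it < 60L) { lo <- hi; hi <- hi * 2; it <- it + 1L }
  if (it >= 60L) stop("failed to bracket the calibration target")
  lam_mid <- NA_real_
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    lam_mid <- f(mid)
    if (abs(lam_mid - target) <= tol) {
      return(structure(mid, lambda = lam_mid, iterations = k,
                       bracket = c(lo, hi)))
    }
    if (lam_mid > target) lo <- mid else hi <- mid
  }
  stop("calibration did not converge within ", max_iter, " iterations ",
       "(last lambda = ", lam_mid, ")")
}

#' Calibrate the mean heterogeneous weight to a target mean growth rate
#'
#' Bisects on the distribution mean so that the Monte-Carlo average of the
#' maximal growth rate over weight realizations matches `lambda_target`.
#' The per-realization uniform quantiles are drawn once from `spec$seed` and
#' reused across bisection steps (common random numbers), which makes the
#' simulated mean a numerically monotone function of the mean weight.
#'
#' @inheritParams calibrate_homogeneous
#' @param spec a [weight_spec]; its `mean_w` is the initial upper-bracket
#'   guess and its family/width/seed define the ensemble.
#' @param n_realizations ensemble size per bisection step (default 500).
#' @return calibrated mean weight, with attributes as in
#'   [calibrate_homogeneous()].
#' @export
calibrate_mean_weight <- function(model, lambda_target, spec,
                                  n_realizations = 500, w_C = 0, w_R, phi_max,
                                  tol = 1e-3, max_iter = 200, ...) {
  stopifnot(inherits(spec, "weight_spec"), n_realizations >= 1)
  enz <- model$reactions[model$category == "enzymatic"]
  U <- with_seed(spec$seed,
                 matrix(stats::runif(n_realizations * length(enz)),
                        nrow = n_realizations))
  f <- function(mean_w) {
    if (mean_w == 0) {
      s <- solve_cafba(model,
                       homogeneous_weights(model, 0, w_C, w_R, phi_max, ...))
      return(s$growth_rate)
    }
    sp <- spec; sp$mean_w <- mean_w
    lam <- vapply(seq_len(n_realizations), function(k) {
      w <- stats::setNames(quantiles_to_weights(U[k, ], sp), enz)
      wt <- cafba_weights(model, w = w, w_C = w_C, w_R = w_R,
                          phi_max = phi_max, ...)
      s <- solve_cafba(model, wt)
      if (s$status != "optimal") NA_real_ else s$growth_rate
    }, numeric(1))
    mean(lam, na.rm = TRUE)
  }
  calibrate_scalar(f, lambda_target, tol, spec$mean_w, max_iter,
                   what = "mean weight")
}

#' Serialize a weight set to TSV
#'
#' Writes one `reaction_id`/`w_i` row per enzymatic reaction, preceded by a
#' single JSON header comment line carrying `w_C`, `w_R`, `phi_max`, the
#' sampling spec and seed.
#'
#' @param weights a [cafba_weights] object.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  hdr <- jsonlite::toJSON(list(w_C = weights$w_C, w_R = weights$w_R,
                               phi_max = weights$phi_max,
                               spec = unclass(weights$spec),
                               seed = weights$seed),
                          auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(data.frame(reaction_id = names(weights$w_i),
                                w_i = unname(weights$w_i)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
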