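#' Distribution specifications for Monte Carlo parameters
#'
#' Constructors for the per-parameter probability models accepted by
#' [mc_config()]: a degenerate (fixed) value, uniform, (truncated) normal,
#' (truncated) lognormal, and triangular. Truncation bounds keep draws in a
#' parameter's validity domain (e.g. positive body weight, ET <= 24 h);
#' draws are redrawn until inside the bounds.
#'
#' `dist_lognormal()` takes the log-scale parameters; use [lnorm_moments()]
#' to moment-match an arithmetic mean and standard deviation.
#'
#' @param value,min,max,mean,sd,meanlog,sdlog,mode Distribution parameters.
#' @param lower,upper Truncation bounds.
#' @return A `mc_dist` specification object.
#' @name mc_distributions
NULL

mc_dist <- function(family, pars, lower = -Inf, upper = Inf) {
  if (lower >= upper) abort("Truncation needs lower < upper", class = "pm10risk_params_error")
  structure(list(family = family, pars = pars, lower = lower, upper = upper),
            class = "mc_dist")
}

#' @rdname mc_distributions
#' @export
dist_fixed <- function(value) mc_dist("fixed", list(value = value))

#' @rdname mc_distributions
#' @export
dist_uniform <- function(min, max) {
  if (min >= max) abort("uniform needs min < max", class = "pm10risk_params_error")
  mc_dist("uniform", list(min = min, max = max))
}

#' @rdname mc_distributions
#' @export
dist_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("normal needs sd >= 0", class = "pm10risk_params_error")
  mc_dist("normal", list(mean = mean, sd = sd), lower, upper)
}

#' @rdname mc_distributions
#' @export
dist_lognormal <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  if (sdlog < 0) abort("lognormal needs sdlog >= 0", class = "pm10risk_params_error")
  mc_dist("lognormal", list(meanlog = meanlog, sdlog = sdlog), lower, upper)
}

#' @rdname mc_distributions
#' @export
dist_triangular <- function(min, mode, max) {
  if (!(min <= mode && mode <= max && min < max)) {
    abort("triangular needs min <= mode <= max with min < max",
          class = "pm10risk_params_error")
  }
  mc_dist("triangular", list(min = min, mode = mode, max = max))
}

#' Moment-matched lognormal parameters
#'
#' Log-scale parameters of the lognormal whose arithmetic mean and standard
#' deviation equal the targets: `sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2/2`.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic standard deviation (>= 0).
#' @return List with `meanlog` and `sdlog`.
#' @export
#' @examples
#' lnorm_moments(104.16, 66.28)
lnorm_moments <- function(mean, sd) {
  if (mean <= 0) abort("lognormal moment matching needs mean > 0",
                       class = "pm10risk_params_error")
  if (sd < 0) abort("sd must be >= 0", class = "pm10risk_params_error")
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

draw_dist <- function(d, n, name, max_retries = 1000) {
  one_batch <- function(k) {
    switch(d$family,
      fixed = rep(d$pars$value, k),
      uniform = runif(k, d$pars$min, d$pars$max),
      normal = rnorm(k, d$pars$mean, d$pars$sd),
      lognormal = rlnorm(k, d$pars$meanlog, d$pars$sdlog),
      triangular = rtri(k, d$pars$min, d$pars$mode, d$pars$max),
      abort(paste0("Unknown distribution family: ", d$family))
    )
  }
  x <- one_batch(n)
  bad <- which(x < d$lower | x > d$upper)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > max_retries) {
      abort(paste0("Parameter '", name,
                   "' could not produce draws inside its truncation bounds"),
            class = "pm10risk_mc_error")
    }
    x[bad] <- one_batch(length(bad))
    bad <- bad[x[bad] < d$lower | x[bad] > d$upper]
  }
  x
}

# Inverse-CDF sampler for the triangular distribution.
rtri <- function(n, a, m, b) {
  u <- runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Monte Carlo configuration
#'
#' Bundles the iteration count, the global seed and the per-parameter
#' distribution specifications. Each parameter draws from its own RNG
#' substream derived deterministically from the global seed, so adding a
#' parameter does not perturb the draws of the others.
#'
#' @param params Named list of `mc_dist` specifications (see
#'   [mc_distributions]).
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer global seed.
#' @return A `mc_config` object.
#' @export
#' @examples
#' cfg <- mc_config(list(BW = dist_normal(70, 10, lower = 0)), seed = 1)
mc_config <- function(params, n_iterations = 10000, seed = 1L) {
  if (n_iterations < 1) abort("n_iterations must be >= 1", class = "pm10risk_params_error")
  if (length(params) == 0 || is.null(names(params)) || any(names(params) == "")) {
    abort("params must be a non-empty named list", class = "pm10risk_params_error")
  }
  ok <- vapply(params, inherits, logical(1), "mc_dist")
  if (!all(ok)) {
    abort(paste0("Not distribution specs: ", paste(names(params)[!ok], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  structure(list(params = params, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Draw the joint Monte Carlo sample matrix
#'
#' @param cfg A [mc_config()].
#' @return Tibble with one column per parameter and `n_iterations` rows;
#'   identical for identical configs and seeds.
#' @export
mc_draws <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  substreams <- sample.int(.Machine$integer.max - 1, length(cfg$params))
  cols <- purrr::imap(cfg$params, function(d, nm) {
    set.seed(substreams[[match(nm, names(cfg$params))]])
    draw_dist(d, cfg$n_iterations, nm)
  })
  as_tibble(cols)
}

#' Propagate uncertainty through a risk computation
#'
#' Evaluates a deterministic risk function on `n_iterations` independent
#' joint draws of the configured parameters and summarises the output
#' distribution (mean; 5th, 50th, 95th percentiles by the type-7
#' linear-interpolation quantile definition), together with a Spearman
#' rank-correlation sensitivity per varied parameter. Identical seeds give
#' identical results.
#'
#' @param risk_fn Function taking a data frame of parameter draws (one row
#'   per iteration) and returning one numeric output per row.
#' @param cfg A [mc_config()].
#' @param ... Further fixed arguments passed to `risk_fn`.
#' @return A `mc_result` list: `summary` (tibble `output, mean, p05, p50,
#'   p95`), `sensitivity` (tibble `parameter, rho, contribution`),
#'   `samples`, `outputs`, `cfg`.
#' @export
#' @examples
#' cfg <- mc_config(list(u = dist_uniform(0, 1)), n_iterations = 1000, seed = 7)
#' mc_propagate(function(d) d$u, cfg)$summary
mc_propagate <- function(risk_fn, cfg, ...) {
  draws <- mc_draws(cfg)
  out <- risk_fn(draws, ...)
  if (!is.numeric(out) || length(out) != nrow(draws)) {
    abort("risk_fn must return one numeric value per iteration",
          class = "pm10risk_mc_error")
  }
  qs <- quantile(out, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  varied <- names(cfg$params)[vapply(cfg$params, function(d) d$family != "fixed",
                                     logical(1))]
  sens <- mc_sensitivity(draws[, varied, drop = FALSE], out)
  res <- list(
    summary = tibble(output = "risk", mean = mean(out),
                     p05 = qs[1], p50 = qs[2], p95 = qs[3]),
    sensitivity = sens,
    samples = draws,
    outputs = out,
    cfg = cfg
  )
  class(res) <- "mc_result"
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo result (%d iterations, seed %d)\n",
              x$cfg$n_iterations, x$cfg$seed))
  print(x$summary)
  if (nrow(x$sensitivity) > 0) {
    cat("Sensitivity (Spearman rho):\n")
    print(x$sensitivity)
  }
  invisible(x)
}

#' Rank-correlation sensitivity of an output to sampled parameters
#'
#' Spearman rank correlation of each varied parameter against the output,
#' with a normalized contribution (squared coefficient over the sum of
#' squares). A constant output yields `NA` coefficients.
#'
#' @param samples Data frame of parameter draws (columns = parameters).
#' @param outputs Numeric output vector, same length as `nrow(samples)`.
#' @return Tibble `parameter, rho, contribution`, sorted by |rho|.
#' @export
mc_sensitivity <- function(samples, outputs) {
  samples <- as_tibble(samples)
  if (ncol(samples) == 0) {
    return(tibble(parameter = character(), rho = numeric(),
                  contribution = numeric()))
  }
  if (nrow(samples) != length(outputs)) {
    abort("samples and outputs must have the same length",
          class = "pm10risk_mc_error")
  }
  if (nrow(samples) < 10) {
    abort("Sensitivity needs at least 10 samples", class = "pm10risk_mc_error")
  }
  const_out <- stats::sd(outputs) == 0
  rho <- vapply(samples, function(x) {
    if (const_out || stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, outputs, method = "spearman")
  }, numeric(1))
  ss <- sum(rho^2, na.rm = TRUE)
  contribution <- if (ss > 0) rho^2 / ss else rep(NA_real_, length(rho))
  tibble(parameter = names(rho), rho = unname(rho),
         contribution = unname(contribution)) %>%
    arrange(dplyr::desc(abs(.data$rho)))
}

#' Probabilistic cancer-risk summaries for the standard outputs
#'
#' Convenience wrapper reproducing the probabilistic risk table layout:
#' for a zone's concentrations it propagates lognormal concentration
#' uncertainty (moment-matched to the zone mean and sd), a lognormal
#' inhalation rate and a truncated-normal body weight through the CR (per
#' carcinogenic metal) and ILCR equations, holding ET/EF/ED fixed at the
#' scenario preset. Distribution choices are recorded in the result.
#'
#' @param metal_summary,pah_summary Single-zone summary tibbles (`species`,
#'   `mean`, `sd`).
#' @param params An [exposure_params()] preset for the fixed parameters and
#'   the IR/BW central values.
#' @param toxicity A [toxicity_table()].
#' @param n_iterations,seed Monte Carlo size and seed.
#' @param ir_cv,bw_cv Coefficients of variation for IR (lognormal) and BW
#'   (normal truncated at +/- 3 sd and > 0).
#' @return Tibble `output, mean, p05, p50, p95` (one row per carcinogenic
#'   metal CR and one ILCR row) with per-output sensitivity tables in the
#'   `sensitivity` attribute.
#' @export
mc_zone_risk <- function(metal_summary, pah_summary,
                         params = exposure_params(),
                         toxicity = toxicity_table(),
                         n_iterations = 10000, seed = 1L,
                         ir_cv = 0.2, bw_cv = 0.15) {
  validate_exposure_params(params)
  bw_sd <- params$BW * bw_cv
  base <- list(
    IR = do.call(dist_lognormal, lnorm_moments(params$IR, params$IR * ir_cv)),
    BW = dist_normal(params$BW, bw_sd,
                     lower = max(1e-6, params$BW - 3 * bw_sd),
                     upper = params$BW + 3 * bw_sd)
  )
  rows <- list(); sens <- list()
  carcinogens <- metal_summary$species[
    !is.na(toxicity$IUR_per_ug_m3[match(metal_summary$species, toxicity$species)])]
  for (sp in carcinogens) {
    row <- metal_summary[metal_summary$species == sp, ]
    iur <- toxicity$IUR_per_ug_m3[toxicity$species == sp]
    conc <- if (row$sd > 0) {
      do.call(dist_lognormal, lnorm_moments(row$mean, row$sd))
    } else dist_fixed(row$mean)
    cfg <- mc_config(c(list(C = conc), base), n_iterations, seed)
    res <- mc_propagate(function(d) {
      cancer_risk(exposure_concentration(d$C / 1000, params), iur)
    }, cfg)
    rows[[sp]] <- mutate(res$summary, output = paste0("CR_", sp))
    sens[[paste0("CR_", sp)]] <- res$sensitivity
  }
  tef <- require_toxicity_field(toxicity, pah_summary$species, "TEF", "mc_zone_risk")
  sf <- toxicity$SF_per_mg_kg_day[toxicity$species == "BaP"]
  teq_mean <- sum(pah_summary$mean * tef)
  teq_sd <- sqrt(sum((pah_summary$sd * tef)^2))
  cfg <- mc_config(c(list(TEQ = do.call(dist_lognormal,
                                        lnorm_moments(teq_mean, teq_sd))),
                     base), n_iterations, seed)
  res <- mc_propagate(function(d) {
    d$TEQ * sf * d$IR * params$EF * params$ED * 1e-6 / (d$BW * params$AT)
  }, cfg)
  rows[["ILCR"]] <- mutate(res$summary, output = "ILCR")
  sens[["ILCR"]] <- res$sensitivity
  out <- bind_rows(rows)
  attr(out, "sensitivity") <- sens
  attr(out, "distributions") <- c(
    "concentrations/TEQ: lognormal (moment-matched to zone mean/sd)",
    sprintf("IR: lognormal (cv %.2f); BW: normal (cv %.2f, truncated +/-3sd, >0)",
            ir_cv, bw_cv),
    "ET/EF/ED: fixed at scenario preset")
  out
}
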