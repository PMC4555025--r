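#' MCMC settings for the hard-core null model
#'
#' The null model states that vesicles are located independently and
#' uniformly in the free synapse interior, subject only to the physical
#' constraint that their ellipsoids overlap neither each other nor the
#' membrane nor any organelle.  With the vesicle count and radii fixed
#' at their observed values this distribution is uniform over the set of
#' feasible configurations, and is simulated by a Metropolis relocation
#' chain (single-vesicle moves; a symmetric proposal accepted iff all
#' constraints hold).
#'
#' @param n_samples configurations to emit (default 1000, matching the
#'   usual simulation size; envelope construction requires at least 40).
#' @param moves_per_sample proposals between emitted samples; default
#'   `10 * N`, set when the chain is run.
#' @param burn_in proposals before the first sample; default `100 * N`.
#' @param proposal_sd translation proposal scale in nm for Gaussian
#'   steps, or `NULL` (default) for proposals drawn uniformly in the
#'   domain bounding box.  Both proposals are symmetric, so the
#'   stationary law is the same.
#' @param reorient draw a fresh uniform random orientation with each
#'   proposal (default `TRUE`: the null randomizes orientations, since
#'   it models vesicles placed independently of each other).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_samples = 1000, moves_per_sample = NULL,
                          burn_in = NULL, proposal_sd = NULL,
                          reorient = TRUE, seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(proposal_sd) && proposal_sd <= 0)
    stop("proposal_sd must be positive (or NULL for uniform proposals)")
  structure(list(n_samples = as.integer(n_samples),
                 moves_per_sample = moves_per_sample, burn_in = burn_in,
                 proposal_sd = proposal_sd, reorient = isTRUE(reorient),
                 seed = seed),
            class = "mcmc_settings")
}

#' Simulate the hard-core null model
#'
#' Runs the Metropolis relocation chain initialized in the observed
#' configuration (which must be feasible): each proposal picks one
#' vesicle uniformly at random, proposes a new center (uniform in the
#' domain bounding box, or a Gaussian step of scale `proposal_sd`) and,
#' if `reorient`, a fresh uniform random orientation, keeping the radii;
#' the move is accepted iff the relocated ellipsoid stays inside the
#' membrane, avoids all organelles and overlaps no other vesicle.  The
#' stationary distribution is uniform over feasible configurations with
#' fixed `N` and fixed radii -- the hard-core null.
#'
#' @param config a feasible [vesicle_configuration()].
#' @param settings an [mcmc_settings()].
#' @param margin hard-core tolerance, nm (see [ellipsoids_overlap()]).
#' @return list of class `"null_samples"`: `configurations` (list of
#'   [vesicle_configuration()]), `acceptance_rate`, `settings`.
#' @export
sample_null <- function(config, settings = mcmc_settings(),
                        margin = 0.1) {
  stopifnot(inherits(config, "vesicle_configuration"),
            inherits(settings, "mcmc_settings"))
  chk <- verify_configuration(config, margin)
  if (!chk$ok) {
    npv <- nrow(chk$pair_violations)
    stop("initial configuration is infeasible: ", npv,
         " overlapping pair(s) [",
         paste(apply(chk$pair_violations, 1, paste, collapse = "-"),
               collapse = ", "), "], ",
         length(chk$domain_violations),
         " domain violation(s) [",
         paste(chk$domain_violations, collapse = ", "), "]")
  }
  N <- config$N
  mps <- if (is.null(settings$moves_per_sample)) 10L * N
         else as.integer(settings$moves_per_sample)
  burn <- if (is.null(settings$burn_in)) 100L * N
          else as.integer(settings$burn_in)
  psd <- if (is.null(settings$proposal_sd)) -1 else settings$proposal_sd
  if (!is.null(settings$seed)) set.seed(settings$seed)

  arr <- config_arrays(config)
  mem <- mesh_arrays(config$domain$membrane)
  obs <- meshes_concat(config$domain$obstacles)
  bb <- mesh_bbox(config$domain$membrane)
  res <- cpp_run_chain(arr$centers, arr$radii, arr$axes, mem$V, mem$F,
                       obs$V, obs$F, bb$lo, bb$hi, margin,
                       settings$n_samples, mps, burn,
                       settings$reorient, psd)
  rate <- res$accepted / res$proposals
  if (rate < 0.01)
    warning(sprintf("acceptance rate %.2f%% is very low; %s", 100 * rate,
                    "consider a smaller proposal_sd"))
  cfgs <- vector("list", settings$n_samples)
  for (s in seq_len(settings$n_samples)) {
    cfgs[[s]] <- config_from_state(
      config$domain, arr$radii,
      list(centers = matrix(res$centers[, , s], ncol = 3),
           axes = matrix(res$axes[, , s], nrow = 3)))
  }
  structure(list(configurations = cfgs, acceptance_rate = rate,
                 settings = settings),
            class = "null_samples")
}

#' @export
print.null_samples <- function(x, ...) {
  cat("null_samples:", length(x$configurations),
      sprintf("configurations, acceptance rate %.1f%%\n",
              100 * x$acceptance_rate))
  invisible(x)
}

#' Pointwise simulation envelope
#'
#' Evaluates a summary statistic on each null-model sample and returns
#' the pointwise empirical 2.5% and 97.5% quantiles (linear-interpolation
#' convention) together with the observed curve and exceedance flags.
#'
#' @param observed a [summary_function()] computed on the data.
#' @param null_samples a [sample_null()] result, or a plain list of
#'   [vesicle_configuration()] objects; at least 40 are required.
#' @param statistic function mapping a configuration to a
#'   [summary_function()] on the same grid as `observed`.
#' @param probs the two quantile levels (default `c(0.025, 0.975)`).
#' @return object of class `"envelope_result"`: data.frame `t`,
#'   `observed`, `lo`, `hi`, `exceed_lo`, `exceed_hi`, plus attribute
#'   `n_sim`.
#' @export
envelope <- function(observed, null_samples, statistic,
                     probs = c(0.025, 0.975)) {
  stopifnot(inherits(observed, "summary_function"))
  cfgs <- if (inherits(null_samples, "null_samples"))
    null_samples$configurations else null_samples
  n_sim <- length(cfgs)
  if (n_sim < 40L)
    stop("at least 40 null samples are required (got ", n_sim, ")")
  vals <- matrix(NA_real_, n_sim, nrow(observed))
  for (s in seq_len(n_sim)) {
    sf <- tryCatch(statistic(cfgs[[s]]), error = function(e)
      stop("statistic failed on null sample ", s, ": ",
           conditionMessage(e)))
    if (!isTRUE(all.equal(sf$t, observed$t)))
      stop("statistic grid does not match the observed grid")
    vals[s, ] <- sf$value
  }
  qs <- apply(vals, 2, quantile, probs = probs, na.rm = TRUE,
              names = FALSE, type = 7)
  out <- data.frame(t = observed$t, observed = observed$value,
                    lo = qs[1, ], hi = qs[2, ])
  out$exceed_lo <- !is.na(out$observed) & !is.na(out$lo) &
    out$observed < out$lo
  out$exceed_hi <- !is.na(out$observed) & !is.na(out$hi) &
    out$observed > out$hi
  attr(out, "n_sim") <- n_sim
  attr(out, "kind") <- attr(observed, "kind")
  class(out) <- c("envelope_result", "data.frame")
  out
}

#' Plot an envelope result
#'
#' Observed curve with the pointwise null band, in the style of the
#' usual L-function and variogram envelope figures.
#'
#' @param x an [envelope()] result.
#' @param ... passed to [graphics::plot()].
#' @param shade fill the null band.
#' @export
plot.envelope_result <- function(x, ..., shade = TRUE) {
  kind <- attr(x, "kind")
  ylab <- switch(kind %||% "statistic", K = "K(t) (nm^3)",
                 L = "L(t) (nm)", variogram_scalar = "V(t)",
                 variogram_angle = "V(t) (degrees)", "statistic")
  ylim <- range(c(x$observed, x$lo, x$hi), na.rm = TRUE)
  graphics::plot(x$t, x$observed, type = "n", xlab = "t (nm)",
                 ylab = ylab, ylim = ylim, ...)
  if (shade) {
    ok <- !is.na(x$lo) & !is.na(x$hi)
    graphics::polygon(c(x$t[ok], rev(x$t[ok])),
                      c(x$lo[ok], rev(x$hi[ok])),
                      col = "grey85", border = NA)
  }
  graphics::lines(x$t, x$lo, lty = 2)
  graphics::lines(x$t, x$hi, lty = 2)
  graphics::lines(x$t, x$observed, lwd = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
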