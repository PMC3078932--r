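#' Fit a fossil-calibrated relaxed-clock dating model
#'
#' The main entry point: runs `config$replicates` independent MCMC chains
#' ([run_mcmc()]), discards the burn-in, combines replicates, and returns a
#' fitted-model object with the usual methods (`print`, `summary`, `coef`,
#' `plot`). A warning is issued when any parameter's combined ESS falls below
#' `config$ess_threshold`.
#'
#' @param align a [dna_alignment()], or `NULL` for a prior-only fit.
#' @param tree a [time_tree()]: the fixed topology with starting ages.
#' @param calibrations list of [calibration()]s.
#' @param scheme a [partition_scheme()] (required when `align` is given).
#' @param models optional named list of [subst_model()]s per partition group;
#'   defaults are built from the scheme's model strings with empirical base
#'   frequencies.
#' @param config a [divtime_config()].
#' @param rel_rates optional fixed per-partition relative rates, passed to
#'   [run_mcmc()].
#' @return an object of class `divtime_fit` with elements `trace` (combined
#'   post-burn-in trace), `replicates` (per-chain traces), `tree`,
#'   `calibrations`, `cal_nodes`, `acceptance`, `summary` and `config`.
#' @examples
#' \donttest{
#' tr <- simulate_tree(8, r = 0.08, a = 0.2, seed = 1)
#' cals <- make_calibrations(tr, n_cal = 2, seed = 1)
#' fit <- divtime(NULL, tr, cals,
#'                config = divtime_config(chain_length = 2000,
#'                                        sample_every = 10,
#'                                        replicates = 1, prior_only = TRUE))
#' summary(fit)
#' }
#' @export
divtime <- function(align = NULL, tree, calibrations = list(), scheme = NULL,
                    models = NULL, config = divtime_config(),
                    rel_rates = NULL) {
  if (!inherits(tree, "time_tree")) stop2("'tree' must be a time_tree")
  if (!is.null(align) && is.null(scheme))
    stop2("'scheme' is required when an alignment is given")
  if (!is.null(align) && is.null(models))
    models <- default_models_for_scheme(scheme, align)
  reps <- lapply(seq_len(config$replicates), function(i)
    run_mcmc(align, tree, scheme, models, calibrations, config,
             rel_rates = rel_rates, replicate = i))
  trace <- combine_traces(reps, config$burnin)
  smry <- trace_summary(trace)
  low <- smry$parameter[smry$ess < config$ess_threshold &
                          !smry$parameter %in% c("posterior", "likelihood", "prior")]
  if (length(low))
    warning("ESS below ", config$ess_threshold, " for: ",
            paste(low, collapse = ", "), call. = FALSE)
  acc <- Reduce(`+`, lapply(reps, attr, "proposed"))
  accn <- Reduce(`+`, lapply(reps, function(r)
    attr(r, "acceptance") * attr(r, "proposed")))
  structure(list(trace = trace, replicates = reps, tree = tree,
                 calibrations = calibrations,
                 cal_nodes = attr(reps[[1L]], "cal_nodes"),
                 acceptance = accn / pmax(acc, 1), summary = smry,
                 models = models, scheme = scheme, config = config),
            class = "divtime_fit")
}

#' @export
print.divtime_fit <- function(x, ...) {
  cat("divtime fit:", x$tree$n_tip, "taxa,",
      length(x$calibrations), "calibrations,",
      x$config$replicates, "replicate chains of",
      x$config$chain_length, "generations",
      if (x$config$prior_only) "(prior only)" else "", "\n")
  root_col <- paste0("age.", x$tree$root)
  s <- x$summary[x$summary$parameter == root_col, ]
  cat(sprintf("root age: %.2f Ma (95%% HPD %.2f-%.2f, ESS %.0f)\n",
              s$mean, s$hpd_low, s$hpd_high, s$ess))
  invisible(x)
}

#' Posterior summaries of a fitted dating model
#'
#' @param object a `divtime_fit`.
#' @param level HPD mass.
#' @param ... unused.
#' @return data.frame with one row per parameter and per internal node age:
#'   posterior mean, median, HPD bounds and ESS.
#' @export
summary.divtime_fit <- function(object, level = 0.95, ...) {
  out <- trace_summary(object$trace, level)
  class(out) <- c("summary.divtime_fit", "data.frame")
  out
}

#' @export
print.summary.divtime_fit <- function(x, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) signif(v, 5))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.divtime_fit <- function(object, ...) {
  s <- object$summary
  setNames(s$mean, s$parameter)[!(s$parameter %in%
                                    c("posterior", "likelihood", "prior"))]
}

#' Trace plots for a fitted dating model
#'
#' Plots the log posterior and the root-age series per replicate (base
#' graphics), the standard first look at mixing and replicate agreement.
#'
#' @param x a `divtime_fit`.
#' @param pars parameter columns to plot; defaults to the log posterior and
#'   the root age.
#' @param ... passed to [graphics::plot()].
#' @export
plot.divtime_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) pars <- c("posterior", paste0("age.", x$tree$root))
  oldpar <- graphics::par(mfrow = c(length(pars), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (p in pars) {
    graphics::plot(x$trace$state, x$trace[[p]], type = "n",
                   xlab = "generation", ylab = p, main = p, ...)
    for (r in unique(x$trace$replicate)) {
      sel <- x$trace$replicate == r
      graphics::lines(x$trace$state[sel], x$trace[[p]][sel],
                      col = r + 1L)
    }
  }
  invisible(x)
}

#' Posterior node-age table
#'
#' @param fit a `divtime_fit`.
#' @param level HPD mass.
#' @return data.frame with node id, the taxa defining it (two exemplar tips),
#'   posterior mean age, and HPD bounds, sorted old to young.
#' @export
node_ages <- function(fit, level = 0.95) {
  internal <- (fit$tree$n_tip + 1L):(2L * fit$tree$n_tip - 1L)
  tips <- descendant_tips(fit$tree)
  rows <- lapply(internal, function(nd) {
    x <- fit$trace[[paste0("age.", nd)]]
    h <- if (sd(x) == 0) c(x[1L], x[1L]) else hpd(x, level)
    ex <- fit$tree$tip_label[range(tips[[nd]])]
    data.frame(node = nd, clade = paste(ex, collapse = "|"),
               mean = mean(x), hpd_low = h[1L], hpd_high = h[2L])
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean), ]
}
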