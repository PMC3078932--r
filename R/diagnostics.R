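#' Effective sample size of an MCMC series
#'
#' `ESS = N / (1 + 2 * sum(rho_k))` where the autocorrelation sum is
#' truncated by Geyer's initial positive sequence rule (consecutive pairs of
#' autocorrelations are summed while the pair sums stay positive). The result
#' is capped at `N`. A constant series has no information about mixing and is
#' reported as `N` with a warning.
#'
#' @param series numeric vector of at least 10 samples.
#' @return the effective sample size.
#' @export
ess <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop2("need at least 10 samples for an ESS estimate")
  if (sd(series) == 0 || !is.finite(sd(series))) {
    warning("constant series: ESS reported as N", call. = FALSE)
    return(n)
  }
  max_lag <- min(n - 1L, max(50L, floor(10 * log10(n))^2))
  rho <- as.numeric(acf(series, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  # Geyer initial positive sequence on pair sums rho[2m] + rho[2m+1]
  s <- 0
  m <- 1L
  while (m <= length(rho)) {
    pair <- rho[m] + if (m + 1L <= length(rho)) rho[m + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    m <- m + 2L
  }
  min(n, n / (1 + 2 * s))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of sorted samples whose endpoints enclose
#' the requested posterior mass: endpoints `x[i]` and `x[i + gap]` with
#' `gap = ceiling(level * N)`, minimizing the width over `i`.
#'
#' @param samples numeric vector, at least 20 values.
#' @param level interval mass in `(0, 1)`.
#' @return numeric `c(low, high)`.
#' @export
hpd <- function(samples, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop2("level must be in (0, 1)")
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 20L) stop2("need at least 20 samples for an HPD interval")
  gap <- min(n - 1L, max(1L, ceiling(level * n)))
  starts <- seq_len(n - gap)
  width <- x[starts + gap] - x[starts]
  i <- starts[which.min(width)]
  c(x[i], x[i + gap])
}

#' Combine replicate traces after burn-in removal
#'
#' @param traces list of traces from [run_mcmc()] sharing one schema.
#' @param burnin fraction of each replicate's records discarded from the
#'   start.
#' @return a single `mcmc_trace` with replicate ids preserved.
#' @export
combine_traces <- function(traces, burnin = 0.1) {
  check_prob(burnin, "burnin")
  if (!length(traces)) stop2("no traces to combine")
  schema <- names(traces[[1L]])
  for (i in seq_along(traces))
    if (!identical(names(traces[[i]]), schema))
      stop2("trace ", i, " has a different schema")
  kept <- lapply(traces, function(tr) {
    drop <- floor(nrow(tr) * burnin)
    tr[(drop + 1L):nrow(tr), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  for (a in c("internal_nodes", "cal_nodes"))
    attr(out, a) <- attr(traces[[1L]], a)
  class(out) <- c("mcmc_trace", "data.frame")
  out
}

# Kolmogorov-Smirnov distance between samples and an analytic CDF
ks_distance <- function(samples, cdf, ...) {
  x <- sort(samples)
  n <- length(x)
  Fx <- cdf(x, ...)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

#' Read / write trace logs
#'
#' Tab-separated with a single header line (columns `state`, `posterior`,
#' `likelihood`, `prior`, then parameters), mirroring common trace-file
#' conventions so external trace viewers can open the files.
#'
#' @param trace an `mcmc_trace` data.frame.
#' @param path file path.
#' @return `read_trace` returns the trace data.frame.
#' @export
write_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  class(out) <- c("mcmc_trace", "data.frame")
  out
}

# per-column summary used by summary.divtime_fit and the CLI
trace_summary <- function(trace, level = 0.95) {
  num <- trace[, !(names(trace) %in% c("state", "replicate")), drop = FALSE]
  stats <- lapply(names(num), function(nm) {
    x <- num[[nm]]
    if (sd(x) == 0) {
      h <- c(x[1L], x[1L]); e <- suppressWarnings(ess(x))
    } else {
      h <- hpd(x, level); e <- ess(x)
    }
    data.frame(parameter = nm, mean = mean(x), median = median(x),
               hpd_low = h[1L], hpd_high = h[2L], ess = e)
  })
  out <- do.call(rbind, stats)
  rownames(out) <- NULL
  out
}
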