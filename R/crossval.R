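#' Prior-posterior concordance of a calibration
#'
#' The fraction of posterior age samples for the calibrated node that fall
#' inside the calibration's central 95% prior interval (hard bounds used
#' as-is for uniform calibrations; 2.5/97.5% quantiles for the lognormal and
#' normal kinds). A well-corroborated constraint scores near 1; a constraint
#' contradicted by the rest of the data scores near 0.
#'
#' @param samples numeric vector of posterior node-age samples (>= 100).
#' @param cal a [calibration()].
#' @param level prior interval mass.
#' @return score in `[0, 1]`.
#' @export
concordance <- function(samples, cal, level = 0.95) {
  if (length(samples) < 100L)
    stop2("need at least 100 posterior samples (got ", length(samples), ")")
  iv <- calibration_interval(cal, level)
  mean(samples >= iv[1L] & samples <= iv[2L])
}

#' Iterative leave-one-out cross-validation of calibrations
#'
#' Round 1 relaxes each calibration in turn and estimates the age of its node
#' from all other calibrations; the relaxed constraint is scored by
#' [concordance()] against that posterior. Calibrations scoring below
#' `threshold` are excluded and the analysis is repeated with the reduced
#' set; previously excluded calibrations are then re-scored against the
#' reduced run's posterior for their node and re-included when they now fit
#' (a constraint can look unreliable only because another, genuinely bad one
#' dragged its node's estimate away). Rounds iterate to a fixed point or
#' `max_rounds`; a final run uses the stable set.
#'
#' @param align a [dna_alignment()].
#' @param tree a [time_tree()].
#' @param scheme a [partition_scheme()].
#' @param models named list of [subst_model()]s (or `NULL` for defaults).
#' @param calibrations named list of at least two [calibration()]s.
#' @param config a [divtime_config()] used for the inner runs (typically
#'   shorter chains than a final production run).
#' @param rel_rates optional fixed per-partition relative rates.
#' @param threshold concordance score below which a calibration is excluded.
#' @param max_rounds cap on re-inclusion rounds.
#' @return an object of class `crossval_report`: data.frame `scores`
#'   (per-calibration score, posterior mean and 95% HPD of the relaxed node,
#'   decision), `history` (round-by-round record), `final_set` (names of
#'   retained calibrations) and `final_fit` (the [divtime()] fit under the
#'   stable set).
#' @export
crossval_calibrations <- function(align, tree, scheme = NULL, models = NULL,
                                  calibrations, config = divtime_config(),
                                  rel_rates = NULL, threshold = 0.5,
                                  max_rounds = 5L) {
  if (length(calibrations) < 2L)
    stop2("untestable: need at least 2 calibrations for cross-validation")
  if (is.null(names(calibrations)))
    names(calibrations) <- vapply(calibrations, `[[`, "", "name")
  cal_nodes <- resolve_calibrations(tree, calibrations)
  nms <- names(calibrations)

  node_samples <- function(fit, nd) fit$trace[[paste0("age.", nd)]]
  run <- function(cals) divtime(align, tree, cals, scheme, models, config,
                                rel_rates = rel_rates)

  # round 1: leave each constraint out in turn
  score1 <- numeric(length(nms))
  post1 <- vector("list", length(nms))
  for (i in seq_along(nms)) {
    fit <- run(calibrations[-i])
    post1[[i]] <- node_samples(fit, cal_nodes[i])
    score1[i] <- concordance(post1[[i]], calibrations[[i]])
  }
  retained <- nms[score1 >= threshold]
  excluded <- setdiff(nms, retained)
  # a single grossly wrong constraint can drag every other node in round 1;
  # if nothing survives, keep all but the single worst scorer so the
  # re-inclusion rounds have an anchored run to re-score against
  if (!length(retained) && threshold > 0) {
    worst <- nms[which.min(score1)]
    retained <- setdiff(nms, worst)
    excluded <- worst
  }
  decision <- setNames(ifelse(nms %in% retained, "retained", "excluded"), nms)
  score_latest <- setNames(score1, nms)
  post_latest <- setNames(post1, nms)
  history <- list(data.frame(round = 1L, calibration = nms, score = score1,
                             decision = unname(decision[nms])))

  if (threshold > 0) {
    round <- 2L
    while (length(excluded) && round <= max_rounds) {
      # a re-inclusion run needs at least one retained calibration to anchor
      # the time scale (it is a plain dating run, not a leave-one-out)
      if (length(retained) < 1L) break
      fit <- run(calibrations[retained])
      rescored <- vapply(excluded, function(nm) {
        s <- node_samples(fit, cal_nodes[nm])
        post_latest[[nm]] <<- s
        concordance(s, calibrations[[nm]])
      }, 0)
      score_latest[excluded] <- rescored
      back <- excluded[rescored >= threshold]
      history[[round]] <- data.frame(
        round = round, calibration = excluded, score = unname(rescored),
        decision = ifelse(excluded %in% back, "re-included", "excluded"))
      if (!length(back)) break
      decision[back] <- "re-included"
      retained <- nms[nms %in% c(retained, back)]
      excluded <- setdiff(excluded, back)
      round <- round + 1L
    }
  }

  final_fit <- run(calibrations[retained])
  scores <- do.call(rbind, lapply(nms, function(nm) {
    s <- post_latest[[nm]]
    h <- if (sd(s) == 0) c(s[1L], s[1L]) else hpd(s)
    data.frame(calibration = nm, score_initial = score1[match(nm, nms)],
               score = unname(score_latest[nm]), decision = unname(decision[nm]),
               post_mean = mean(s), hpd_low = h[1L], hpd_high = h[2L])
  }))
  rownames(scores) <- NULL
  structure(list(scores = scores, history = do.call(rbind, history),
                 final_set = retained, final_fit = final_fit,
                 threshold = threshold),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("calibration cross-validation (threshold ", x$threshold, "):\n", sep = "")
  y <- x$scores
  y[c("score_initial", "score", "post_mean", "hpd_low", "hpd_high")] <-
    lapply(y[c("score_initial", "score", "post_mean", "hpd_low", "hpd_high")],
           function(v) signif(v, 4))
  print.data.frame(y, row.names = FALSE)
  cat("final set:", paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes the per-calibration score table as TSV and a structured YAML
#' summary (decision history and final set).
#'
#' @param report a `crossval_report`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_crossval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "crossval_scores.tsv")
  yml <- file.path(dir, "crossval_summary.yaml")
  write.table(report$scores, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    schema = "divtime-crossval/1", threshold = report$threshold,
    final_set = as.list(report$final_set),
    history = lapply(seq_len(nrow(report$history)), function(i)
      as.list(report$history[i, ]))), yml)
  invisible(c(tsv, yml))
}
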