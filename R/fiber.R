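#' @include AllClasses.R
NULL

#' Convert tract lengths from micrometres to kilobases
#'
#' Linear conversion using the standard stretched-fiber factor
#' 1 um = 2.59 kb.
#'
#' @param lengthUm length(s) in micrometres, >= 0.
#' @param factor kilobases per micrometre (default 2.59).
#' @return Lengths in kb.
#' @export
#' @examples
#' umToKb(1)      # 2.59
#' umToKb(c(0, 10))
umToKb <- function(lengthUm, factor = 2.59) {
  if (any(lengthUm < 0)) stop("tract lengths must be >= 0")
  lengthUm * factor
}

#' Classify fork events as stalled or restarted
#'
#' A fork event requires a first-label (IdU) tract; it is stalled when the
#' second-label (CldU) tract is absent (length <= \code{minSecondLabel},
#' default exactly 0) and restarted otherwise. Rows without a first-label
#' tract are not fork events (e.g. new origins); they are excluded and
#' counted.
#'
#' @param dataset a \linkS4class{FiberDataset} or its tracks data.frame.
#' @param minSecondLabel tolerance on "absent" second label (um).
#' @return The tracks with an added factor column \code{event}
#'   ("stalled"/"restarted"), non-events removed; attribute
#'   \code{excluded_non_events} holds the dropped row count.
#' @export
classifyEvents <- function(dataset, minSecondLabel = 0) {
  tr <- if (is(dataset, "FiberDataset")) tracks(dataset) else dataset
  nonEvent <- tr$first_label_um <= 0
  out <- tr[!nonEvent, , drop = FALSE]
  out$event <- factor(ifelse(out$second_label_um <= minSecondLabel,
                             "stalled", "restarted"),
                      levels = c("stalled", "restarted"))
  rownames(out) <- NULL
  attr(out, "excluded_non_events") <- sum(nonEvent)
  out
}

#' Percentage of stalled forks
#'
#' 100 x stalled / (stalled + restarted), per replicate within each
#' condition and pooled per condition. Replicates with fewer than
#' \code{minFibers} fork events trigger a warning (the scoring convention
#' calls for at least 150 per independent experiment).
#'
#' @param dataset a \linkS4class{FiberDataset}.
#' @param byReplicate when FALSE only the pooled per-condition table is
#'   returned.
#' @param minSecondLabel passed to \code{\link{classifyEvents}}.
#' @param minFibers replicate-minimum for the warning.
#' @return list with data.frames \code{per_replicate} (condition,
#'   replicate, n_events, percent_stalled) and \code{pooled} (condition,
#'   n_events, percent_stalled).
#' @export
#' @examples
#' fd <- simulateFiberDataset(200L, 0.3, seed = 2L)
#' percentStalled(fd)$pooled
percentStalled <- function(dataset, byReplicate = TRUE, minSecondLabel = 0,
                           minFibers = 150L) {
  ev <- classifyEvents(dataset, minSecondLabel)
  if (!nrow(ev)) stop("no fork events in the dataset")
  agg <- function(df) 100 * sum(df$event == "stalled") / nrow(df)
  perRep <- do.call(rbind, lapply(
    split(ev, list(ev$condition, ev$replicate), drop = TRUE),
    function(df) data.frame(condition = df$condition[1L],
                            replicate = df$replicate[1L],
                            n_events = nrow(df),
                            percent_stalled = agg(df))))
  perRep <- perRep[order(perRep$condition, perRep$replicate), , drop = FALSE]
  rownames(perRep) <- NULL
  low <- perRep$n_events < minFibers
  if (any(low))
    warning(sprintf("%d replicate(s) have fewer than %d fork events",
                    sum(low), minFibers))
  pooled <- do.call(rbind, lapply(split(ev, ev$condition), function(df)
    data.frame(condition = df$condition[1L], n_events = nrow(df),
               percent_stalled = agg(df))))
  rownames(pooled) <- NULL
  if (byReplicate) list(per_replicate = perRep, pooled = pooled)
  else list(pooled = pooled)
}

#' Extract tract-length samples in kb
#'
#' Selects first- or second-label segment lengths, converts to kb, and
#' applies the scheme-appropriate restriction: for restart-scheme
#' second-label analysis only restarted forks (both labels present) are
#' measured by default; protection and under-HU schemes use all tracts.
#'
#' @param dataset a \linkS4class{FiberDataset}.
#' @param which "first" (IdU) or "second" (CldU).
#' @param restrict "restarted_only", "all", or NULL for the scheme default.
#' @param minSecondLabel stalled/restarted tolerance (um).
#' @return Named list of numeric kb vectors, one per condition.
#' @export
tractLengths <- function(dataset, which = c("second", "first"),
                         restrict = NULL, minSecondLabel = 0) {
  which <- match.arg(which)
  ev <- classifyEvents(dataset, minSecondLabel)
  scheme <- if (nrow(ev)) as.character(ev$scheme[1L]) else "restart"
  if (is.null(restrict))
    restrict <- if (scheme == "restart" && which == "second")
      "restarted_only" else "all"
  restrict <- match.arg(restrict, c("restarted_only", "all"))
  if (restrict == "restarted_only")
    ev <- ev[ev$event == "restarted", , drop = FALSE]
  if (!nrow(ev))
    stop("empty selection after restriction ('", restrict, "')")
  fac <- if (is(dataset, "FiberDataset")) dataset@umToKb else 2.59
  col <- if (which == "first") "first_label_um" else "second_label_um"
  lapply(split(ev, ev$condition, drop = TRUE),
         function(df) umToKb(df[[col]], fac))
}

#' Replicate-level fiber summary with Welch and Mann-Whitney statistics
#'
#' Percent stalled is summarized as mean +/- s.d. of replicate-level
#' percentages with a two-sided Welch t-test of each condition against the
#' control; tract lengths (second label, scheme-appropriate restriction)
#' are pooled across replicates and summarized as mean +/- s.e.m. with a
#' two-sided Mann-Whitney test against the control.
#'
#' @param dataset a \linkS4class{FiberDataset} containing the control and
#'   at least one other condition (a single condition is summarized without
#'   tests).
#' @param control control condition label.
#' @param minSecondLabel stalled/restarted tolerance (um).
#' @return A \linkS4class{FiberSummary}.
#' @export
#' @examples
#' fd <- combineFiberDatasets(
#'   simulateFiberDataset(200L, 0.2, condition = "control", seed = 1L),
#'   simulateFiberDataset(200L, 0.5, condition = "treated", seed = 2L))
#' summarizeFibers(fd, "control")
summarizeFibers <- function(dataset, control, minSecondLabel = 0) {
  tr <- tracks(dataset)
  if (!control %in% tr$condition)
    stop(sprintf("control condition '%s' not present", control))
  notes <- character()
  ps <- withCallingHandlers(
    percentStalled(dataset, minSecondLabel = minSecondLabel),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  perRep <- ps$per_replicate
  conds <- unique(tr$condition)
  ctrlPct <- perRep$percent_stalled[perRep$condition == control]
  pctRows <- lapply(conds, function(cond) {
    v <- perRep$percent_stalled[perRep$condition == cond]
    if (length(v) < 2L)
      notes <<- c(notes, sprintf("condition '%s': single replicate, s.d. undefined", cond))
    p <- if (cond == control || length(v) < 2L || length(ctrlPct) < 2L)
      NA_real_
    else stats::t.test(v, ctrlPct, var.equal = FALSE)$p.value
    data.frame(condition = cond, n_replicates = length(v),
               mean_percent_stalled = mean(v),
               sd_percent_stalled = if (length(v) > 1L) stats::sd(v) else NA_real_,
               welch_p_vs_control = p)
  })
  pctTab <- do.call(rbind, pctRows)

  lens <- tryCatch(tractLengths(dataset, "second",
                                minSecondLabel = minSecondLabel),
                   error = function(e) {
                     notes <<- c(notes, conditionMessage(e)); NULL
                   })
  lenTab <- data.frame(condition = character(0), n = integer(0),
                       mean_kb = numeric(0), sem_kb = numeric(0),
                       mannwhitney_p_vs_control = numeric(0))
  if (!is.null(lens)) {
    ctrlLen <- lens[[control]]
    lenTab <- do.call(rbind, lapply(names(lens), function(cond) {
      v <- lens[[cond]]
      p <- if (cond == control || is.null(ctrlLen)) NA_real_
      else stats::wilcox.test(v, ctrlLen, exact = FALSE)$p.value
      data.frame(condition = cond, n = length(v), mean_kb = mean(v),
                 sem_kb = stats::sd(v) / sqrt(length(v)),
                 mannwhitney_p_vs_control = p)
    }))
  }
  rownames(pctTab) <- rownames(lenTab) <- NULL
  new("FiberSummary", percentStalled = pctTab, tractLengths = lenTab,
      control = control, notes = notes)
}
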