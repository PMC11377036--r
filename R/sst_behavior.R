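# Stop-signal-task behavioural metrics and cohort inclusion rules.
#
# The task presents Go trials (left/right arrows) and occasional Stop trials in
# which a stop signal follows the go stimulus after a staircase-tracked delay
# (SSD, 250-900 ms on a 50 ms grid). Sustained attention is indexed by the
# intra-individual coefficient of variation (ICV): SD of Go reaction times
# divided by their mean; lower ICV = better sustained attention.

#' Validate a trial table
#'
#' @param trials data.frame with columns `trial_index`, `trial_type`
#'   ("go"/"stop"), `onset` (s), `ssd` (ms, stop trials only), `response`
#'   ("left"/"right"/"none"), `correct_side` ("left"/"right"), `rt` (ms, NA
#'   when no response), `late_flag` (logical).
#' @return the validated data.frame (invisibly usable downstream).
#' @keywords internal
validate_trials <- function(trials) {
  needed <- c("trial_type", "response", "correct_side", "rt")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop(invalid_input(paste(
      "trial table lacks columns:", paste(missing_cols, collapse = ", ")
    )))
  }
  if (!all(trials$trial_type %in% c("go", "stop"))) {
    stop(invalid_input("trial_type must be 'go' or 'stop'"))
  }
  if (any(!is.na(trials$rt) & trials$rt <= 0)) {
    stop(invalid_input("reaction times must be positive when present"))
  }
  if (is.null(trials$late_flag)) trials$late_flag <- FALSE
  trials$late_flag[is.na(trials$late_flag)] <- FALSE
  trials
}

#' Summarise stop-signal-task behaviour for one subject
#'
#' Computes the Table-1-style per-subject metrics: ICV (sample SD of correct,
#' on-time Go RTs over their mean), Go RT mean/SD, stop-fail RT, mean SSD,
#' omission / choice-error / commission percentages, and the Go error rate
#' used by the inclusion rule (wrong-side + omitted + late Go trials).
#'
#' @param trials trial table, see [validate_trials()].
#' @return object of class `behavioral_summary`.
#' @examples
#' tr <- data.frame(
#'   trial_type = "go", response = "left", correct_side = "left",
#'   rt = c(400, 500, 600), late_flag = FALSE
#' )
#' compute_behavioral_summary(tr)$icv # 0.2
#' @export
compute_behavioral_summary <- function(trials) {
  trials <- validate_trials(trials)
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  n_go <- nrow(go)
  n_stop <- nrow(st)

  responded <- go$response != "none"
  if (sum(responded) < 2L) {
    stop(degenerate_input("fewer than 2 responded Go trials"))
  }
  omission <- !responded
  choice_error <- responded & go$response != go$correct_side
  late <- responded & !choice_error & go$late_flag
  correct_ontime <- responded & !choice_error & !late

  rts <- go$rt[correct_ontime]
  if (length(rts) < 2L) {
    stop(degenerate_input("fewer than 2 correct, on-time Go responses"))
  }
  mean_go_rt <- mean(rts)
  if (mean_go_rt == 0) stop(invalid_input("zero mean Go RT"))
  sd_go_rt <- stats::sd(rts)

  stop_responded <- st$response != "none"
  stop_rt <- if (any(stop_responded)) mean(st$rt[stop_responded]) else NA_real_
  mean_ssd <- if (n_stop > 0) mean(st$ssd) else NA_real_

  out <- list(
    icv = sd_go_rt / mean_go_rt,
    mean_go_rt = mean_go_rt,
    sd_go_rt = sd_go_rt,
    stop_rt = stop_rt,
    mean_ssd = mean_ssd,
    p_omission = 100 * sum(omission) / n_go,
    p_choice_error = 100 * sum(choice_error) / n_go,
    p_commission = if (n_stop > 0) 100 * sum(stop_responded) / n_stop else NA_real_,
    n_go = n_go,
    n_stop = n_stop,
    go_error_rate = (sum(omission) + sum(choice_error) + sum(late)) / n_go,
    n_late = sum(late),
    go_rts_responded = go$rt[responded & !omission]
  )
  class(out) <- "behavioral_summary"
  out
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "SST behavioural summary\n",
      "  ICV            %.3f\n  Go RT          %.1f +/- %.1f ms\n",
      "  Stop RT        %.1f ms\n  mean SSD       %.1f ms\n",
      "  pOmission      %.1f%%\n  pChoiceError   %.1f%%\n",
      "  pCommission    %.1f%%\n  Go error rate  %.1f%%\n"
    ),
    x$icv, x$mean_go_rt, x$sd_go_rt, x$stop_rt, x$mean_ssd,
    x$p_omission, x$p_choice_error, x$p_commission, 100 * x$go_error_rate
  ))
  invisible(x)
}

#' Estimate the stop-signal reaction time
#'
#' Integration method (default): SSRT = the p(respond|signal) quantile of the
#' Go RT distribution minus the mean SSD, with omitted Go trials replaced by
#' the slowest observed Go RT. Mean method: mean Go RT minus mean SSD.
#'
#' @param trials trial table.
#' @param method "integration" or "mean".
#' @return list with `ssrt` (ms), `method`, and `reliable` (FALSE when the
#'   commission rate sits on the 0/1 boundary).
#' @export
compute_ssrt <- function(trials, method = c("integration", "mean")) {
  method <- match.arg(method)
  s <- compute_behavioral_summary(trials)
  if (s$n_stop < 1L) stop(degenerate_input("no stop trials"))
  if (method == "mean") {
    return(list(ssrt = s$mean_go_rt - s$mean_ssd, method = method, reliable = TRUE))
  }
  p_respond <- s$p_commission / 100
  go_dist <- s$go_rts_responded
  n_omit <- round(s$p_omission / 100 * s$n_go)
  if (n_omit > 0) go_dist <- c(go_dist, rep(max(go_dist), n_omit))
  reliable <- TRUE
  if (p_respond %in% c(0, 1)) {
    warning("commission rate at boundary (0 or 1); SSRT unreliable")
    reliable <- FALSE
  }
  q <- stats::quantile(go_dist, probs = p_respond, names = FALSE, type = 7)
  list(ssrt = q - s$mean_ssd, method = method, reliable = reliable)
}

#' Apply the cohort inclusion rule
#'
#' Subjects are excluded when they made more than 20% errors on Go trials
#' (wrong-side responses, omissions, or late responses) or when their mean
#' framewise displacement exceeds 0.5 mm; both inequalities are strict.
#'
#' @param summary a [compute_behavioral_summary()] result.
#' @param mean_fd mean framewise displacement in mm.
#' @return list with `include` (logical) and `reasons` (character vector among
#'   "go_errors", "motion").
#' @export
apply_exclusion <- function(summary, mean_fd) {
  if (!inherits(summary, "behavioral_summary")) {
    stop(invalid_input("summary must be a behavioral_summary"))
  }
  if (!is.numeric(mean_fd) || length(mean_fd) != 1L || is.na(mean_fd) || mean_fd < 0) {
    stop(invalid_input("mean_fd must be a single nonnegative number"))
  }
  reasons <- character()
  if (summary$go_error_rate > 0.20) reasons <- c(reasons, "go_errors")
  if (mean_fd > 0.5) reasons <- c(reasons, "motion")
  list(include = length(reasons) == 0L, reasons = reasons)
}

#' Read a trial-level TSV
#'
#' Expected columns: trial_index, trial_type, onset, ssd, response,
#' correct_side, rt, late_flag; empty fields are missing values.
#' @param path file path.
#' @export
read_sst_trials <- function(path) {
  tr <- utils::read.delim(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!is.null(tr$late_flag)) tr$late_flag <- as.logical(tr$late_flag)
  validate_trials(tr)
}

#' Flatten behavioural summaries into a Table-1-style data.frame
#'
#' @param summaries list of `behavioral_summary` objects (optionally named by
#'   subject id).
#' @export
behavioral_summary_table <- function(summaries) {
  if (inherits(summaries, "behavioral_summary")) summaries <- list(summaries)
  fields <- c(
    "icv", "mean_go_rt", "sd_go_rt", "stop_rt", "mean_ssd",
    "p_omission", "p_choice_error", "p_commission", "n_go", "n_stop",
    "go_error_rate"
  )
  out <- do.call(rbind, lapply(summaries, function(s) {
    as.data.frame(s[fields])
  }))
  if (!is.null(names(summaries))) out <- cbind(subject = names(summaries), out)
  rownames(out) <- NULL
  out
}
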