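#' Kaplan-Meier product-limit estimate
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over distinct event
#' times, with censoring at an event time conventionally ordered after the
#' events (the censored subject counts as at risk at that time). Computed
#' via `survival::survfit`.
#'
#' @param records tibble with columns `time` (non-negative, months) and
#'   `event` (logical/0-1, TRUE = event observed); optionally `sample_id`.
#' @return tibble with `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   restricted to distinct observed times, of class `exlr_km`.
#' @export
km_estimate <- function(records) {
  records <- as_tibble(records)
  check_survival_records(records)
  fit <- survival::survfit(
    survival::Surv(records$time, as.integer(records$event)) ~ 1)
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  class(out) <- c("exlr_km", class(out))
  out
}

check_survival_records <- function(records) {
  if (!all(c("time", "event") %in% names(records))) {
    abort("survival records need columns 'time' and 'event'.")
  }
  if (!nrow(records)) abort("no survival records.")
  if (anyNA(records$time) || anyNA(records$event)) {
    abort("NA in survival time or event.")
  }
  if (any(records$time < 0)) abort("negative survival time.")
  invisible(records)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square \eqn{(O - E)^2 / V} summed over event times,
#' referred to chi-square on 1 df, via `survival::survdiff`.
#'
#' @param group_a,group_b record tibbles as for [km_estimate()].
#' @return tibble with `chi_sq`, `p`, `n_a`, `n_b`, `events`. With zero
#'   events overall, `p` is `NA` with a warning.
#' @export
logrank_test <- function(group_a, group_b) {
  check_survival_records(group_a)
  check_survival_records(group_b)
  time <- c(group_a$time, group_b$time)
  event <- as.integer(c(group_a$event, group_b$event))
  grp <- rep(c("a", "b"), c(nrow(group_a), nrow(group_b)))
  n_events <- sum(event)
  if (n_events == 0) {
    warn("no events in either group; log-rank p is NA.")
    return(tibble(chi_sq = NA_real_, p = NA_real_,
                  n_a = nrow(group_a), n_b = nrow(group_b), events = 0L))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  tibble(
    chi_sq = sd_fit$chisq,
    p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
    n_a = nrow(group_a), n_b = nrow(group_b), events = n_events
  )
}

#' Screen per-sample scores against survival by median split
#'
#' For each score set (row), CRC samples with endpoint data are dichotomized
#' at the median score — ties go to the low group — and the high and low
#' arms compared by log-rank. The direction is the sign of the association
#' between score and survival: `"positive"` when the high-score arm survives
#' longer (by median survival, falling back to the KM curves at the last
#' event time), `"negative"` otherwise. Only CRC samples enter, matching the
#' prognostic question asked of the scores.
#'
#' @param scores sets x samples matrix ([ssgsea_score()]).
#' @param design design tibble with `sample_id`, `cohort` and the endpoint
#'   columns (`os_time`/`os_event` or `dfs_time`/`dfs_event`).
#' @param endpoint `"OS"` or `"DFS"`.
#' @param min_arm minimum samples required per arm.
#' @return tibble with `set`, `direction`, `chi_sq`, `p`, `n_high`, `n_low`.
#'   Sets with a constant score or an undersized arm are skipped.
#' @export
screen_scores <- function(scores, design, endpoint = c("OS", "DFS"),
                          min_arm = 2) {
  endpoint <- match.arg(endpoint)
  design <- validate_design(design)
  tcol <- if (endpoint == "OS") "os_time" else "dfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "dfs_event"
  if (!all(c(tcol, ecol) %in% names(design))) {
    abort(sprintf("design lacks %s/%s columns.", tcol, ecol))
  }
  eligible <- design$cohort == "CRC" &
    !is.na(design[[tcol]]) & !is.na(design[[ecol]]) &
    design$sample_id %in% colnames(scores)
  ids <- design$sample_id[eligible]
  if (length(ids) < 2 * min_arm) {
    abort("too few CRC samples with endpoint data.")
  }
  time <- design[[tcol]][eligible]
  event <- as.logical(design[[ecol]][eligible])
  rows <- purrr::map(rownames(scores), function(set) {
    v <- scores[set, ids]
    if (sd(v) == 0) {
      warn(sprintf("set '%s' skipped: constant score.", set))
      return(NULL)
    }
    med <- median(v)
    high <- v > med  # ties -> low arm
    if (sum(high) < min_arm || sum(!high) < min_arm) {
      warn(sprintf("set '%s' skipped: arm smaller than %d.", set, min_arm))
      return(NULL)
    }
    rec_high <- tibble(time = time[high], event = event[high])
    rec_low <- tibble(time = time[!high], event = event[!high])
    lr <- suppressWarnings(logrank_test(rec_high, rec_low))
    tibble(set = set,
           direction = km_direction(rec_high, rec_low),
           chi_sq = lr$chi_sq, p = lr$p,
           n_high = sum(high), n_low = sum(!high))
  })
  dplyr::bind_rows(rows)
}

# positive = high-score arm survives longer
km_direction <- function(rec_high, rec_low) {
  med_h <- km_median(rec_high)
  med_l <- km_median(rec_low)
  if (!is.na(med_h) && !is.na(med_l) && med_h != med_l) {
    return(if (med_h > med_l) "positive" else "negative")
  }
  # fall back to the curve ordering at the last shared event time
  kh <- km_estimate(rec_high)
  kl <- km_estimate(rec_low)
  t_max <- min(max(kh$time), max(kl$time))
  sh <- km_surv_at(kh, t_max)
  sl <- km_surv_at(kl, t_max)
  if (sh >= sl) "positive" else "negative"
}

km_median <- function(records) {
  km <- km_estimate(records)
  idx <- which(km$survival <= 0.5)
  if (!length(idx)) return(NA_real_)
  km$time[idx[1]]
}

km_surv_at <- function(km, t) {
  idx <- which(km$time <= t)
  if (!length(idx)) return(1)
  km$survival[max(idx)]
}
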