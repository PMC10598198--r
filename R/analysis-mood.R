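#' Filter and normalize choice response times
#'
#' Applies the standard RT cleaning per participant: keep only trials
#' with 0.75 s < RT < 10 s that also fall within the participant's
#' median +/- 3 SD interval; z-score the surviving RTs; then regress
#' out the session indicator (categorical) and the trial number within
#' session (continuous), keeping the residuals.
#'
#' @param records Trial tibble with columns `rt`, `session`, `index`,
#'   and optionally `subject` (a single participant is assumed
#'   otherwise).
#' @return A list of class `rt_preprocess`: `trials` (kept rows with
#'   added `rt_z` and `rt_resid`) and `exclusions` (per subject:
#'   n_total, n_excluded, and an `all_excluded` flag -- flagged, not
#'   fatal).
#' @export
preprocess_rt <- function(records) {
  if (!"subject" %in% names(records)) records$subject <- 1L
  if (!"session" %in% names(records)) records$session <- 1L
  split_logs <- split(records, records$subject)
  kept <- list()
  excl <- list()
  for (s in names(split_logs)) {
    d <- split_logs[[s]]
    in_range <- d$rt > 0.75 & d$rt < 10
    med <- stats::median(d$rt[in_range])
    sdv <- stats::sd(d$rt[in_range])
    ok <- in_range
    if (is.finite(sdv) && sdv > 0) {
      ok <- ok & abs(d$rt - med) <= 3 * sdv
    }
    excl[[s]] <- tibble::tibble(
      subject = d$subject[1], n_total = nrow(d),
      n_excluded = sum(!ok), all_excluded = !any(ok)
    )
    if (!any(ok)) next
    k <- d[ok, ]
    k$rt_z <- as.numeric(scale(k$rt))
    if (stats::sd(k$rt) == 0) k$rt_z <- 0
    form <- if (length(unique(k$session)) > 1) {
      rt_z ~ factor(session) + index
    } else {
      rt_z ~ index
    }
    k$rt_resid <- unname(stats::residuals(stats::lm(form, data = k)))
    kept[[s]] <- k
  }
  structure(
    list(trials = dplyr::bind_rows(kept),
         exclusions = dplyr::bind_rows(excl)),
    class = "rt_preprocess"
  )
}

#' Reconstruct the trial-by-trial AUC trace from a trial log
#'
#' Replays the OTG sliding-window update over an observed (or
#' simulated) choice sequence -- per session and cost type -- and
#' records the area under the indifference curve after every choice.
#' Deterministic given the log. The AUC is then z-scored per session
#' and linearly interpolated across the 4-trial cost-type cycle so that
#' every trial carries a value for every cost type's latest estimate.
#'
#' @param trials One subject's trial log (columns `session`, `index`,
#'   `cost_type`, `small_reward`, `cost_level`, `choice`).
#' @param otg_cfg An [otg_config()].
#' @param grid An `otg_grid`.
#' @return The log with added columns `auc` (this trial's cost type,
#'   post-update) and `auc_interp` (per-session z-scored AUC averaged
#'   over cost types after linear interpolation in trial index).
#' @export
auc_trace <- function(trials, otg_cfg = otg_config(),
                      grid = build_grids()) {
  if (!"session" %in% names(trials)) trials$session <- 1L
  out <- dplyr::group_modify(
    dplyr::group_by(trials, .data$session),
    function(d, key) {
      d <- d[order(d$index), ]
      auc <- numeric(nrow(d))
      per_type <- matrix(NA_real_, nrow(d), 4,
                         dimnames = list(NULL, cost_types()))
      for (ct in cost_types()) {
        rows <- which(d$cost_type == ct)
        for (i in seq_along(rows)) {
          m <- update_indifference_model(d[rows[seq_len(i)], ], otg_cfg)
          auc[rows[i]] <- compute_auc(m, grid)
        }
        per_type[rows, ct] <- auc[rows]
        # linear interpolation across the 4-trial cycle
        if (length(rows) >= 2) {
          per_type[, ct] <- stats::approx(rows, auc[rows],
                                          xout = seq_len(nrow(d)),
                                          rule = 2)$y
        } else if (length(rows) == 1) {
          per_type[, ct] <- auc[rows]
        }
      }
      z <- function(x) {
        s <- stats::sd(x)
        if (!is.finite(s) || s == 0) return(rep(0, length(x)))
        (x - mean(x)) / s
      }
      d$auc <- auc
      d$auc_interp <- z(rowMeans(per_type))
      d
    }
  )
  dplyr::ungroup(out)
}

group_ttest <- function(x, label) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || stats::sd(x) == 0) {
    return(tibble::tibble(term = label, mean = mean(x), se = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  tt <- stats::t.test(x)
  tibble::tibble(term = label, mean = mean(x),
                 se = stats::sd(x) / sqrt(length(x)),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value, n = length(x))
}

#' Model-free analysis of mood effects on choice
#'
#' The standard battery run on a cohort of trial logs, all tests
#' two-tailed at the group level (paired / one-sample t-tests on
#' per-subject statistics; no multiple-testing correction, alpha
#' reported alongside):
#' 1. costly-choice-rate contrast between positive and negative
#'    episodes, pooled and per cost type;
#' 2. per-subject logistic regression of choice on the same-trial
#'    z-scored mood rating, coefficients tested against zero (skipped
#'    with a warning when mood is missing);
#' 3. RT regression with main effects and interaction of choice and
#'    episode condition, on [preprocess_rt()] residuals;
#' 4. within-episode slopes of the reconstructed AUC trace
#'    ([auc_trace()]) in positive and negative episodes, with
#'    time-on-task regressed out.
#'
#' @param trial_logs A list of per-subject trial tibbles, or one tibble
#'   with a `subject` column.
#' @param include_auc Compute the AUC-slope battery? (It replays the
#'   OTG update over every trial, the slowest step.) Default TRUE.
#' @param alpha Nominal two-tailed significance level reported with the
#'   tests.
#' @param otg_cfg An [otg_config()] for the AUC replay.
#' @return An object of class `analysis_report`: tibbles
#'   `choice_contrast`, `mood_logistic`, `rt_model`, `auc_slopes`, plus
#'   `per_subject` intermediates, `n_subjects` and `alpha`.
#' @export
analyze_mood_effects <- function(trial_logs, include_auc = TRUE,
                                 alpha = 0.05, otg_cfg = otg_config()) {
  if (is.data.frame(trial_logs)) {
    stopifnot(!is.null(trial_logs$subject))
    trial_logs <- split(trial_logs, trial_logs$subject)
  }
  logs <- purrr::imap(trial_logs, function(d, s) {
    d$subject <- s
    if (!"session" %in% names(d)) d$session <- 1L
    d
  })

  # (1) choice-rate contrast, pooled and per cost type
  rate_of <- function(d, cond, ct = NULL) {
    keep <- d$condition == cond
    if (!is.null(ct)) keep <- keep & d$cost_type == ct
    if (!any(keep)) return(NA_real_)
    mean(d$choice[keep] == "costly")
  }
  contrast_tbl <- purrr::map_dfr(logs, function(d) {
    row <- tibble::tibble(
      subject = d$subject[1],
      pooled = rate_of(d, "positive") - rate_of(d, "negative")
    )
    for (ct in cost_types()) {
      row[[ct]] <- rate_of(d, "positive", ct) - rate_of(d, "negative", ct)
    }
    row
  })
  choice_contrast <- purrr::map_dfr(
    c("pooled", cost_types()),
    ~ group_ttest(contrast_tbl[[.x]], .x)
  )

  # (2) logistic regression of choice on rated mood
  mood_logistic <- NULL
  per_subject_mood <- NULL
  if (!"mood_z" %in% names(logs[[1]])) {
    warning("no `mood_z` column: skipping the choice ~ mood regression")
  } else {
    per_subject_mood <- purrr::map_dfr(logs, function(d) {
      co <- tryCatch({
        fit <- stats::glm(I(choice == "costly") ~ mood_z, data = d,
                          family = stats::binomial())
        stats::coef(fit)[["mood_z"]]
      }, error = function(e) NA_real_, warning = function(w) {
        fit <- suppressWarnings(
          stats::glm(I(choice == "costly") ~ mood_z, data = d,
                     family = stats::binomial())
        )
        stats::coef(fit)[["mood_z"]]
      })
      tibble::tibble(subject = d$subject[1], beta_mood = co)
    })
    mood_logistic <- group_ttest(per_subject_mood$beta_mood,
                                 "choice ~ mood_z")
  }

  # (3) RT ~ choice * condition on preprocessed residuals
  all_trials <- dplyr::bind_rows(logs)
  rt_pre <- preprocess_rt(all_trials)
  rt_terms <- c("choice", "condition", "interaction")
  per_subject_rt <- purrr::map_dfr(
    split(rt_pre$trials, rt_pre$trials$subject),
    function(d) {
      d <- d[d$condition %in% c("positive", "negative"), ]
      out <- tibble::tibble(subject = d$subject[1],
                            choice = NA_real_, condition = NA_real_,
                            interaction = NA_real_)
      if (nrow(d) < 8 || length(unique(d$choice)) < 2 ||
          length(unique(d$condition)) < 2) {
        return(out)
      }
      d$x_choice <- as.numeric(d$choice == "costly")
      d$x_cond <- as.numeric(d$condition == "positive")
      fit <- stats::lm(rt_resid ~ x_choice * x_cond, data = d)
      co <- stats::coef(fit)
      out$choice <- co[["x_choice"]]
      out$condition <- co[["x_cond"]]
      out$interaction <- co[["x_choice:x_cond"]]
      out
    }
  )
  rt_model <- purrr::map_dfr(rt_terms,
                             ~ group_ttest(per_subject_rt[[.x]], .x))

  # (4) AUC slopes within episodes
  auc_slopes <- NULL
  if (include_auc) {
    per_subject_auc <- purrr::map_dfr(logs, function(d) {
      tr <- auc_trace(d, otg_cfg)
      # time-on-task out first
      tr$auc_detr <- stats::residuals(
        stats::lm(auc_interp ~ index, data = tr)
      )
      ep <- tr[tr$condition %in% c("positive", "negative"), ]
      new_ep <- c(TRUE, diff(ep$index) != 1 |
                    ep$session[-1] != ep$session[-nrow(ep)])
      ep$ep_id <- cumsum(new_ep)
      ep <- dplyr::mutate(dplyr::group_by(ep, .data$ep_id),
                          ep_trial = dplyr::row_number())
      ep <- dplyr::ungroup(ep)
      slope_for <- function(cond) {
        dd <- ep[ep$condition == cond, ]
        if (nrow(dd) < 4) return(NA_real_)
        stats::coef(stats::lm(auc_detr ~ ep_trial, data = dd))[["ep_trial"]]
      }
      tibble::tibble(subject = d$subject[1],
                     positive = slope_for("positive"),
                     negative = slope_for("negative"))
    })
    auc_slopes <- purrr::map_dfr(
      c("positive", "negative"),
      ~ group_ttest(per_subject_auc[[.x]], .x)
    )
  }

  structure(
    list(
      choice_contrast = choice_contrast,
      mood_logistic = mood_logistic,
      rt_model = rt_model,
      auc_slopes = auc_slopes,
      per_subject = list(contrast = contrast_tbl,
                         mood = per_subject_mood,
                         rt = per_subject_rt,
                         auc = if (include_auc) per_subject_auc),
      rt_exclusions = rt_pre$exclusions,
      n_subjects = length(logs),
      alpha = alpha
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$n_subjects,
      "subjects (two-tailed group tests, alpha =", x$alpha, ")\n")
  cat("-- costly-choice contrast (positive - negative):\n")
  print(x$choice_contrast)
  if (!is.null(x$mood_logistic)) {
    cat("-- choice ~ mood logistic coefficient:\n")
    print(x$mood_logistic)
  }
  cat("-- RT ~ choice * condition:\n")
  print(x$rt_model)
  if (!is.null(x$auc_slopes)) {
    cat("-- AUC within-episode slopes:\n")
    print(x$auc_slopes)
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes the group-level tables of an `analysis_report` (and its
#' alpha and subject count) to a JSON file.
#'
#' @param report An `analysis_report`.
#' @param path File path.
#' @return `report`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    n_subjects = report$n_subjects,
    alpha = report$alpha,
    choice_contrast = report$choice_contrast,
    mood_logistic = report$mood_logistic,
    rt_model = report$rt_model,
    auc_slopes = report$auc_slopes
  )
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       digits = NA, auto_unbox = TRUE)
  invisible(report)
}

#' @rdname analyze_mood_effects
#' @param x An `analysis_report`.
#' @param ... Unused.
#' @export
tidy.analysis_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$choice_contrast, analysis = "choice_contrast"),
    if (!is.null(x$mood_logistic)) {
      dplyr::mutate(x$mood_logistic, analysis = "mood_logistic")
    },
    dplyr::mutate(x$rt_model, analysis = "rt_model"),
    if (!is.null(x$auc_slopes)) {
      dplyr::mutate(x$auc_slopes, analysis = "auc_slopes")
    }
  )
}
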