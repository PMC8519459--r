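# End-to-end annotation of one deployment and validation against ground
# truth.

#' Annotate a full deployment
#'
#' Runs the whole pipeline for one individual: clock-drift correction,
#' static/dynamic decomposition with VeDBA and body angles, 1-min epoch
#' statistics, phase segmentation, event detection (breathing within Night
#' bouts, basking/diving within Midday bouts, nest digging anywhere),
#' stratum inference for Night bouts, daily budgets and laying alignment.
#'
#' @param env 1 Hz environmental stream (`time,temp_c,pressure_bar,
#'   light_lux`).
#' @param accel 10 Hz acceleration stream (`time,ax,ay,az`).
#' @param meta deployment metadata (see [read_deployment_meta()]); when
#'   NULL no clock correction is applied.
#' @param ref optional reference temperature series for stratum inference.
#' @param seg_config [segmentation_config()].
#' @param keep_motion return the full 10 Hz motion series (memory-heavy on
#'   long deployments).
#' @return list with `bouts`, `epochs`, `epoch_labels`, `breathing`,
#'   `inhalations`, `basking`, `dives`, `nesting`, `strata`, `budgets`,
#'   and optionally `motion`.
#' @export
annotate_deployment <- function(env, accel, meta = NULL, ref = NULL,
                                seg_config = segmentation_config(),
                                keep_motion = FALSE) {
  origin <- attr(env, "origin")
  if (!is.null(meta)) {
    env$time <- correct_clock_drift(env$time, meta$rtc_anchors)
    accel$time <- correct_clock_drift(accel$time, meta$rtc_anchors)
    attr(env, "origin") <- origin
  }
  motion <- motion_series(accel)
  eps <- epoch_stats(env)
  labels <- classify_epochs(eps, seg_config)
  bouts <- segment_cycles(eps, labels, seg_config)

  inh_all <- list(); bt_all <- list()
  bask_all <- list(); dive_all <- list()
  for (i in seq_len(nrow(bouts))) {
    sel <- env$time >= bouts$t_start[i] & env$time < bouts$t_end[i]
    if (bouts$label[i] == "Night") {
      inh <- detect_inhalations(env$time[sel], env$pressure_bar[sel])
      grp <- group_breathing_bouts(inh)
      if (nrow(grp$bouts)) {
        grp$bouts$cycle <- bouts$cycle[i]
        bt_all[[length(bt_all) + 1L]] <- grp$bouts
        inh_all[[length(inh_all) + 1L]] <- grp$inhalations
      }
    } else if (bouts$label[i] == "Midday") {
      bk <- detect_basking(env$time[sel], env$temp_c[sel])
      if (nrow(bk)) bask_all[[length(bask_all) + 1L]] <- bk
      dv <- detect_dives(env$time[sel], env$temp_c[sel],
                         env$pressure_bar[sel])
      if (nrow(dv)) dive_all[[length(dive_all) + 1L]] <- dv
    }
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  breathing <- bind(bt_all, data.frame(bout = integer(0),
                                       t_start = numeric(0),
                                       t_end = numeric(0),
                                       duration_s = numeric(0),
                                       n_inhalations = integer(0),
                                       cycle = integer(0)))
  inhalations <- bind(inh_all, data.frame(t = numeric(0),
                                          pre_pressure = numeric(0),
                                          min_pressure = numeric(0),
                                          rise_cm = numeric(0),
                                          bout = integer(0)))
  basking <- bind(bask_all, data.frame(t_start = numeric(0),
                                       t_end = numeric(0),
                                       duration_s = numeric(0),
                                       delta_t = numeric(0)))
  dives <- bind(dive_all, data.frame(t_start = numeric(0),
                                     t_end = numeric(0),
                                     trigger = character(0),
                                     delta_t = numeric(0)))
  good <- motion$ok & !motion$edge
  nesting <- detect_nesting(motion$time[good], motion$pitch[good],
                            motion$roll[good], motion$vedba[good])
  if (nrow(nesting) && nrow(bouts)) {
    nesting$phase <- vapply(nesting$t_start, function(t) {
      j <- which(bouts$t_start <= t & bouts$t_end > t)
      if (length(j)) bouts$label[j[1]] else NA_character_
    }, character(1))
  } else if (nrow(nesting)) {
    nesting$phase <- NA_character_
  }
  strata <- if (!is.null(ref)) bout_strata(bouts, env, ref) else NULL
  budgets <- budget_cycles(bouts, list(breathing = breathing,
                                       nesting = nesting,
                                       basking = basking),
                           motion$time, motion$vedba)
  if (nrow(budgets)) {
    budgets <- align_to_laying(budgets, nesting,
                               observed = meta$nesting_observed %||%
                                 numeric(0),
                               origin = origin)
  }
  out <- list(bouts = bouts, epochs = eps, epoch_labels = labels,
              breathing = breathing, inhalations = inhalations,
              basking = basking, dives = dives, nesting = nesting,
              strata = strata, budgets = budgets)
  if (keep_motion) out$motion <- motion
  out
}

#' Score an annotated deployment against the generator's ground truth
#'
#' Epoch-level phase accuracy, breathing-bout and nest-digging confusion
#' counts, basking-time recovery and Night stratum agreement.  Event-level
#' scoring is restricted to the segmented span (first to last detected
#' Night onset): the first and last partial nights of a deployment lie
#' outside any complete night-to-night cycle, so the detector never
#' searches them.
#'
#' @param ann result of [annotate_deployment()].
#' @param truth truth list from [generate_individual()].
#' @return list of metrics.
#' @export
evaluate_against_truth <- function(ann, truth) {
  bouts <- ann$bouts
  eps <- ann$epochs
  span <- if (nrow(bouts)) c(min(bouts$t_start), max(bouts$t_end)) else
    c(Inf, -Inf)
  # epoch phase accuracy over the segmented span
  pred <- phase_at_epochs(eps, bouts)
  mid <- eps$t_start + 30
  tp <- truth$phases
  tru <- rep(NA_character_, length(mid))
  for (i in seq_len(nrow(tp))) {
    inside <- mid >= tp$t_start[i] & mid < tp$t_end[i]
    tru[inside] <- tp$phase[i]
  }
  scored <- !is.na(pred) & !is.na(tru)
  phase_acc <- if (any(scored)) mean(pred[scored] == tru[scored]) * 100 else
    NA_real_
  in_span <- function(df) df[df$t_start >= span[1] & df$t_start < span[2], ,
                             drop = FALSE]
  breathing <- validate_detections(in_span(ann$breathing),
                                   in_span(truth$breathing))
  digs <- in_span(truth$nesting)
  nest <- validate_detections(in_span(ann$nesting), digs)
  long <- digs[digs$t_end - digs$t_start >= 1800, , drop = FALSE]
  long_hit <- vapply(seq_len(nrow(long)), function(i) {
    overlaps_any(long$t_start[i], long$t_end[i],
                 ann$nesting$t_start, ann$nesting$t_end)
  }, logical(1))
  # false digs on dig-free days
  dig_days <- unique(floor(digs$t_start / 86400))
  det_days <- floor(ann$nesting$t_start / 86400)
  fp_digfree <- sum(!(det_days %in% dig_days))
  # basking time within the segmented span
  tb <- truth$intervals[truth$intervals$state == "bask", , drop = FALSE]
  tb <- tb[tb$t0 >= span[1] & tb$t0 < span[2], , drop = FALSE]
  det_bask <- in_span(ann$basking)
  stratum_tab <- if (!is.null(ann$strata) && nrow(ann$strata)) {
    table(ann$strata$stratum[ann$strata$label == "Night"])
  } else NULL
  list(
    phase_accuracy_pct = phase_acc,
    n_epochs_scored = sum(scored),
    breathing = breathing,
    nesting = nest,
    long_digs_total = nrow(long),
    long_digs_detected = sum(long_hit),
    dig_fp_on_digfree_days = fp_digfree,
    bask_time_true_h = sum(tb$t1 - tb$t0) / 3600,
    bask_time_detected_h = if (nrow(det_bask))
      sum(det_bask$duration_s) / 3600 else 0,
    night_strata = stratum_tab
  )
}
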