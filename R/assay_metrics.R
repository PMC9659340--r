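# Closed-form cell-assay computations: doubling time, respirometry state
# extraction with antimycin-background subtraction, flux control ratios,
# ROS-per-respiration normalization, flow-cytometry channel ratios and the
# calcein-cobalt mPTP ratio.

#' Cell-culture doubling time
#'
#' `doubling time (h) = culture time (h) / log2(n_end / n_start)`.
#'
#' @param culture_time_h Culture duration in hours (> 0).
#' @param n_start,n_end Cell counts at start and end; `n_end > n_start`
#'   required (no growth is flagged as an error, never returned as a silent
#'   infinity).
#' @return Doubling time in hours.
#' @examples
#' doubling_time(48, 2e6, 8e6)  # 24
#' @export
doubling_time <- function(culture_time_h, n_start, n_end) {
  if (culture_time_h <= 0) stop("culture_time_h must be > 0", call. = FALSE)
  if (n_start <= 0) stop("n_start must be > 0", call. = FALSE)
  if (n_end <= n_start) {
    stop(sprintf("no growth: n_end (%g) must exceed n_start (%g)", n_end, n_start),
         call. = FALSE)
  }
  culture_time_h / log2(n_end / n_start)
}

# plateau statistic: median of the samples in the terminal `window` seconds of
# the segment [seg_start, seg_end)
plateau_value <- function(trace, seg_start, seg_end, window) {
  sel <- trace$time >= seg_start & trace$time < seg_end
  if (!any(sel)) stop("empty plateau segment", call. = FALSE)
  seg_len <- seg_end - min(trace$time[sel])
  if (window > seg_len) {
    stop(sprintf("plateau window (%g s) exceeds segment length (%g s)", window, seg_len),
         call. = FALSE)
  }
  keep <- sel & trace$time >= seg_end - window
  median(trace$flux[keep])
}

#' Extract respiratory states from an oxygen-flux trace
#'
#' Segments the trace at titration event markers and reports each state as the
#' median flux over the last `plateau_window` seconds before the next event
#' (robust to titration spikes). ETS is the maximum across the stepwise FCCP
#' plateaus. The post-antimycin plateau defines non-mitochondrial background
#' respiration, which is subtracted from every other state.
#'
#' @param trace A `resp_trace` (see [simulate_respirometry_trace()] /
#'   [read_resp_trace()]).
#' @param protocol `"intact"` (Routine, Leak, ETS, background) or
#'   `"permeabilized"` (Routine, L_S, CI, Ox, L_Olg, ETS, CII, background).
#' @param plateau_window Terminal-window width in seconds (default 60).
#' @return A [state_table()] holding raw and background-subtracted fluxes.
#' @export
respirometry_states <- function(trace, protocol = c("intact", "permeabilized"),
                                plateau_window = 60) {
  stopifnot(inherits(trace, "resp_trace"))
  protocol <- match.arg(protocol)
  ev <- trace$events[order(trace$events$time), , drop = FALSE]
  tr <- trace$trace
  end_time <- max(tr$time) + 1e-9

  # segment following the k-th occurrence of an event label
  seg_after <- function(label, k = 1L) {
    hits <- which(ev$label == label)
    if (length(hits) < k) stop(sprintf("missing required event: %s", label), call. = FALSE)
    i <- hits[k]
    nxt <- if (i < nrow(ev)) ev$time[i + 1L] else end_time
    c(ev$time[i], nxt)
  }

  states <- list()
  if (protocol == "intact") {
    need <- c("start", "oligomycin", "FCCP_step", "antimycin")
    for (lbl in need) if (!lbl %in% ev$label) {
      stop(sprintf("missing required event: %s", lbl), call. = FALSE)
    }
    s <- seg_after("start");      states$Routine <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("oligomycin"); states$Leak <- plateau_value(tr, s[1], s[2], plateau_window)
  } else {
    need <- c("start", "PMG", "ADP", "succinate", "oligomycin", "FCCP_step",
              "rotenone", "antimycin")
    for (lbl in need) if (!lbl %in% ev$label) {
      stop(sprintf("missing required event: %s", lbl), call. = FALSE)
    }
    s <- seg_after("start")
    # the digitonin marker may subdivide the Routine segment; end Routine there
    dig <- ev$time[ev$label == "digitonin"]
    if (length(dig) > 0) s[2] <- min(s[2], dig[1])
    states$Routine <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("PMG");        states$L_S <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("ADP");        states$CI <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("succinate");  states$Ox <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("oligomycin"); states$L_Olg <- plateau_value(tr, s[1], s[2], plateau_window)
    s <- seg_after("rotenone");   states$CII <- plateau_value(tr, s[1], s[2], plateau_window)
  }
  n_fccp <- sum(ev$label == "FCCP_step")
  steps <- vapply(seq_len(n_fccp), function(k) {
    s <- seg_after("FCCP_step", k)
    plateau_value(tr, s[1], s[2], plateau_window)
  }, numeric(1))
  states$ETS <- max(steps)
  s <- seg_after("antimycin")
  states$background <- plateau_value(tr, s[1], s[2], plateau_window)

  subtract_background(state_table(unlist(states), protocol = protocol,
                                  plateau_window = plateau_window,
                                  ets_steps = steps))
}

#' Respiratory state table
#'
#' Holds raw per-state fluxes and, after [subtract_background()], the
#' background-subtracted values used for all downstream ratios.
#'
#' @param raw Named numeric vector of raw state fluxes; must include
#'   `background`.
#' @param protocol Protocol label.
#' @param plateau_window Window used for extraction (metadata).
#' @param ets_steps Raw FCCP step plateaus (metadata).
#' @return An object of class `state_table`.
#' @export
state_table <- function(raw, protocol = "intact", plateau_window = NA_real_,
                        ets_steps = numeric(0)) {
  if (!"background" %in% names(raw)) stop("state table needs a background state", call. = FALSE)
  structure(list(raw = raw, subtracted = NULL, protocol = protocol,
                 plateau_window = plateau_window, ets_steps = ets_steps,
                 background_subtracted = FALSE),
            class = "state_table")
}

#' Subtract non-mitochondrial background respiration
#'
#' Subtracts the post-antimycin background flux from every state (the
#' background state itself becomes exactly 0). Refuses to subtract twice.
#'
#' @param states A [state_table()].
#' @return The table with `subtracted` filled in and the flag set.
#' @export
subtract_background <- function(states) {
  stopifnot(inherits(states, "state_table"))
  if (states$background_subtracted) {
    stop("background already subtracted from this state table", call. = FALSE)
  }
  states$subtracted <- states$raw - states$raw[["background"]]
  states$background_subtracted <- TRUE
  states
}

#' @export
print.state_table <- function(x, ...) {
  cat(sprintf("state_table (%s protocol):\n", x$protocol))
  df <- data.frame(raw = x$raw)
  if (x$background_subtracted) df$subtracted <- x$subtracted
  print(df)
  invisible(x)
}

#' ETS-normalized flux control ratios
#'
#' Emits the three candidate respiratory control ratios for intact cells, each
#' normalized to maximal electron-transfer capacity: `Routine/ETS`,
#' `Leak/ETS` and net Routine `(Routine - Leak)/ETS`. All from
#' background-subtracted fluxes.
#'
#' @param states A background-subtracted [state_table()] with `Routine`,
#'   `Leak` and `ETS`.
#' @return Named numeric vector `routine_ets`, `leak_ets`, `net_routine_ets`.
#' @export
control_ratios <- function(states) {
  stopifnot(inherits(states, "state_table"))
  if (!states$background_subtracted) {
    stop("subtract background before forming control ratios", call. = FALSE)
  }
  need <- c("Routine", "Leak", "ETS")
  if (!all(need %in% names(states$subtracted))) {
    stop("control ratios need subtracted Routine, Leak and ETS states", call. = FALSE)
  }
  s <- states$subtracted
  if (s[["ETS"]] == 0) stop("ETS is 0; control ratios undefined", call. = FALSE)
  c(routine_ets = s[["Routine"]] / s[["ETS"]],
    leak_ets = s[["Leak"]] / s[["ETS"]],
    net_routine_ets = (s[["Routine"]] - s[["Leak"]]) / s[["ETS"]])
}

#' ROS production per unit respiration, normalized to control
#'
#' `(ros_flux / o2_flux) / control_value`, with the ROS flux assumed already
#' corrected for the pre-cell background.
#'
#' @param ros_flux Background-corrected ROS (H2O2) flux.
#' @param o2_flux Oxygen flux at the same respiratory state (> 0).
#' @param control_value The control line's `ros_flux / o2_flux` (> 0).
#' @return Normalized ratio (1 when the sample equals the control).
#' @export
ros_per_respiration <- function(ros_flux, o2_flux, control_value) {
  if (o2_flux <= 0) stop("o2_flux must be > 0", call. = FALSE)
  if (control_value <= 0) stop("control_value must be > 0", call. = FALSE)
  (ros_flux / o2_flux) / control_value
}

#' Unstained-corrected flow-cytometry channel ratio
#'
#' Subtracts the unstained-sample autofluorescence from each channel (flooring
#' at 0 with a flag rather than propagating negative intensities) and returns
#' corrected numerator / corrected denominator — e.g. JC-1 PE/FITC as a
#' membrane-potential surrogate, or Fura Red BV650/PerCP for cytosolic
#' calcium.
#'
#' @param stained Named numeric vector of mean fluorescence intensities.
#' @param unstained Named numeric vector of unstained-control intensities for
#'   (at least) the same channels.
#' @param numerator_channel,denominator_channel Channel names.
#' @return Ratio with attribute `floored` naming channels floored at 0.
#' @examples
#' channel_ratio(c(PE = 200, FITC = 100), c(PE = 0, FITC = 0), "PE", "FITC")  # 2
#' @export
channel_ratio <- function(stained, unstained, numerator_channel, denominator_channel) {
  for (ch in c(numerator_channel, denominator_channel)) {
    if (!ch %in% names(stained) || !ch %in% names(unstained)) {
      stop(sprintf("channel '%s' missing from measurement", ch), call. = FALSE)
    }
  }
  if (any(stained < 0) || any(unstained < 0)) {
    stop("fluorescence intensities must be >= 0", call. = FALSE)
  }
  corr <- stained[c(numerator_channel, denominator_channel)] -
    unstained[c(numerator_channel, denominator_channel)]
  floored <- names(corr)[corr < 0]
  corr[corr < 0] <- 0
  if (corr[[denominator_channel]] <= 0) {
    stop(sprintf("corrected denominator channel '%s' is <= 0", denominator_channel),
         call. = FALSE)
  }
  out <- corr[[numerator_channel]] / corr[[denominator_channel]]
  attr(out, "floored") <- floored
  out
}

#' mPTP opening from the calcein-cobalt quench assay
#'
#' `(calcein_ionomycin / calcein_untreated) / control_ratio`: the
#' ionomycin-to-untreated calcein fluorescence ratio of the sample, normalized
#' to the same ratio in control cells. Lower values mean more quench upon the
#' calcium challenge, i.e. more permeability-transition-pore opening.
#'
#' @param calcein_ionomycin Mean calcein fluorescence after ionomycin (> 0).
#' @param calcein_untreated Mean calcein fluorescence untreated (> 0).
#' @param control_ratio Control line's ionomycin/untreated ratio (> 0).
#' @return Normalized mPTP ratio (1 when sample equals control).
#' @export
mptp_ratio <- function(calcein_ionomycin, calcein_untreated, control_ratio) {
  if (calcein_ionomycin <= 0 || calcein_untreated <= 0 || control_ratio <= 0) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  (calcein_ionomycin / calcein_untreated) / control_ratio
}
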