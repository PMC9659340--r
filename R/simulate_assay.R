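# TCSPC photon-decay and oxygen-flux trace generators.

#' Configuration for the synthetic TCSPC decay generator
#'
#' Emulates per-pixel photon-arrival histograms from time-correlated
#' single-photon counting of NADH autofluorescence: a biexponential decay with
#' fixed short (free-NADH) and long (protein-bound NADH) lifetime components,
#' sampled into time channels across one laser pulse period.
#'
#' @param seed Integer seed.
#' @param image_shape `c(rows, cols)`.
#' @param a1_map Per-pixel amplitude fraction of the short-lifetime (free)
#'   component, in `[0, 1]`; a scalar is recycled to the whole image.
#' @param photons_per_pixel Expected total decay photons per pixel (> 0; 0 is
#'   allowed and produces an all-zero, flagged stack).
#' @param background_rate Expected background counts per channel (default 0).
#' @param tau1,tau2 Short and long lifetime components in picoseconds
#'   (defaults 400 and 2500; `tau1 < tau2` required).
#' @param n_channels Number of time channels (default 256).
#' @param period Pulse period in picoseconds (default 12500).
#' @return An object of class `sim_decay_config`.
#' @export
sim_decay_config <- function(seed, image_shape, a1_map, photons_per_pixel,
                             background_rate = 0, tau1 = 400, tau2 = 2500,
                             n_channels = 256L, period = 12500) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L)) {
    stop("image_shape must be c(rows, cols) with positive entries", call. = FALSE)
  }
  if (is.matrix(a1_map)) {
    if (!all(dim(a1_map) == image_shape)) stop("a1_map dimensions must match image_shape", call. = FALSE)
  } else {
    a1_map <- matrix(a1_map, image_shape[1], image_shape[2])
  }
  if (any(a1_map < 0 | a1_map > 1)) stop("a1 must lie in [0, 1] everywhere", call. = FALSE)
  if (photons_per_pixel < 0) stop("photons_per_pixel must be >= 0", call. = FALSE)
  if (background_rate < 0) stop("background_rate must be >= 0", call. = FALSE)
  if (!(tau1 < tau2)) stop("tau1 must be < tau2", call. = FALSE)
  structure(list(seed = as.integer(seed), image_shape = image_shape, a1_map = a1_map,
                 photons_per_pixel = photons_per_pixel, background_rate = background_rate,
                 tau1 = tau1, tau2 = tau2, n_channels = as.integer(n_channels),
                 period = period),
            class = "sim_decay_config")
}

# normalized biexponential shape at times t (ps); a1 weights the tau1 term
biexp_shape <- function(t, a1, tau1, tau2) {
  a1 * exp(-t / tau1) + (1 - a1) * exp(-t / tau2)
}

#' Simulate a photon decay stack
#'
#' Per-pixel channel counts are independent Poisson draws around
#' `A * (a1 * exp(-t/tau1) + (1-a1) * exp(-t/tau2)) + background` evaluated at
#' channel centers, with `A` scaled so the expected decay photons per pixel
#' equal `photons_per_pixel`.
#'
#' @param config A [sim_decay_config()].
#' @return A [decay_stack()]; all-zero stacks (photons and background both 0)
#'   carry attribute `empty = TRUE`.
#' @export
simulate_decay_stack <- function(config) {
  stopifnot(inherits(config, "sim_decay_config"))
  set.seed(config$seed)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  nch <- config$n_channels
  dt <- config$period / nch
  t_mid <- (seq_len(nch) - 0.5) * dt
  counts <- array(0L, dim = c(nr, nc, nch))
  if (config$photons_per_pixel > 0 || config$background_rate > 0) {
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        shape <- biexp_shape(t_mid, config$a1_map[i, j], config$tau1, config$tau2)
        lam <- config$photons_per_pixel * shape / sum(shape) + config$background_rate
        counts[i, j, ] <- rpois(nch, lam)
      }
    }
  }
  out <- decay_stack(counts, period = config$period)
  if (config$photons_per_pixel == 0 && config$background_rate == 0) attr(out, "empty") <- TRUE
  out
}

#' Simulate a high-resolution respirometry trace
#'
#' Produces a piecewise-constant oxygen-flux trace following a titration
#' protocol, with Gaussian noise and optional linear drift, plus the event
#' markers recorded at segment boundaries. Two protocols are supported:
#'
#' * intact cells: `Routine` -> oligomycin (`Leak`) -> stepwise FCCP (`ETS`,
#'   one value per step) -> antimycin (`background`);
#' * permeabilized cells: `Routine` -> digitonin + substrates (`L_S`) -> ADP
#'   (`CI`) -> succinate (`Ox`) -> oligomycin (`L_Olg`) -> stepwise FCCP
#'   (`ETS`) -> rotenone (`CII`) -> antimycin (`background`).
#'
#' @param states Named list of true plateau fluxes (pmol O2 s^-1 per 10^6
#'   cells). For the intact protocol: `Routine`, `Leak`, `ETS` (scalar or
#'   vector of FCCP steps), `background`. For the permeabilized protocol:
#'   `Routine`, `L_S`, `CI`, `Ox`, `L_Olg`, `ETS`, `CII`, `background`.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param drift Linear drift in flux units per second (default 0).
#' @param seed Integer seed.
#' @param segment_duration Seconds per titration plateau (default 180).
#' @param interval Data recording interval in seconds (default 2, the
#'   instrument's setting).
#' @return An object of class `resp_trace`: list with data frames `trace`
#'   (`time`, `flux`) and `events` (`time`, `label`), and the protocol name.
#' @export
simulate_respirometry_trace <- function(states, noise_sd = 0, drift = 0, seed = 1L,
                                        segment_duration = 180, interval = 2) {
  if (length(states) == 0L) stop("state map must not be empty", call. = FALSE)
  if (any(unlist(states) < 0)) stop("state fluxes must be >= 0", call. = FALSE)
  intact_states <- c("Routine", "Leak", "ETS", "background")
  perm_states <- c("Routine", "L_S", "CI", "Ox", "L_Olg", "ETS", "CII", "background")
  protocol <- if (setequal(names(states), perm_states)) "permeabilized"
              else if (setequal(names(states), intact_states)) "intact"
              else stop(sprintf("state names must match the intact (%s) or permeabilized (%s) protocol",
                                paste(intact_states, collapse = ", "),
                                paste(perm_states, collapse = ", ")), call. = FALSE)
  # triggering event for each plateau; Routine begins at `start`
  trigger <- c(Routine = "start", Leak = "oligomycin", L_S = "PMG", CI = "ADP",
               Ox = "succinate", L_Olg = "oligomycin", ETS = "FCCP_step",
               CII = "rotenone", background = "antimycin")
  order_names <- if (protocol == "intact") intact_states else perm_states

  seg_flux <- numeric(0); seg_label <- character(0)
  for (nm in order_names) {
    val <- states[[nm]]
    if (nm == "ETS") {
      seg_flux <- c(seg_flux, val)
      seg_label <- c(seg_label, rep("FCCP_step", length(val)))
    } else {
      if (length(val) != 1L) stop(sprintf("state '%s' must be a scalar flux", nm), call. = FALSE)
      seg_flux <- c(seg_flux, val)
      seg_label <- c(seg_label, trigger[[nm]])
    }
  }

  set.seed(seed)
  n_per <- max(2L, as.integer(round(segment_duration / interval)))
  time <- numeric(0); flux <- numeric(0)
  ev_time <- numeric(0); ev_label <- character(0)
  t0 <- 0
  for (s in seq_along(seg_flux)) {
    tt <- t0 + interval * (seq_len(n_per) - 1L)
    ev_time <- c(ev_time, t0)
    ev_label <- c(ev_label, seg_label[s])
    if (protocol == "permeabilized" && seg_label[s] == "PMG") {
      # permeabilization marker recorded just before substrate addition
      ev_time <- c(ev_time, max(0, t0 - interval))
      ev_label <- c(ev_label, "digitonin")
    }
    flux <- c(flux, seg_flux[s] + rnorm(n_per, 0, noise_sd) + drift * tt)
    time <- c(time, tt)
    t0 <- tt[length(tt)] + interval
  }
  o <- order(ev_time)
  structure(list(trace = data.frame(time = time, flux = flux),
                 events = data.frame(time = ev_time[o], label = ev_label[o],
                                     stringsAsFactors = FALSE),
                 protocol = protocol),
            class = "resp_trace")
}

#' Write / read a respirometry trace as TSV pairs
#'
#' Serializes to a two-column trace TSV (`time`, `flux`) plus an events TSV
#' (`time`, `label`).
#'
#' @param x A `resp_trace`.
#' @param trace_path,events_path File paths.
#' @return For the writer, `trace_path` invisibly; for the reader, a
#'   `resp_trace` (protocol re-inferred from event labels).
#' @export
write_resp_trace <- function(x, trace_path, events_path) {
  stopifnot(inherits(x, "resp_trace"))
  write.table(x$trace, trace_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$events, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(trace_path)
}

#' @rdname write_resp_trace
#' @export
read_resp_trace <- function(trace_path, events_path) {
  tr <- read.delim(trace_path, sep = "\t")
  ev <- read.delim(events_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("time", "flux") %in% names(tr)) || !all(c("time", "label") %in% names(ev))) {
    stop("trace TSV needs columns time,flux; events TSV needs time,label", call. = FALSE)
  }
  if (is.unsorted(tr$time, strictly = TRUE)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  protocol <- if (any(ev$label %in% c("digitonin", "PMG", "ADP", "succinate", "rotenone")))
    "permeabilized" else "intact"
  structure(list(trace = tr, events = ev, protocol = protocol), class = "resp_trace")
}
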