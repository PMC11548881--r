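# BRET arithmetic and simulators. Raw BRET is the acceptor-window
# (520-545 nm) photon count divided by the donor-window (475-495 nm) count;
# net BRET subtracts the raw ratio of donor-only cells. Bystander BRET uses
# an inert compartment marker as acceptor, so the net signal reports
# co-residence of donor and marker on the same membrane.

#' Raw BRET ratio
#'
#' @param acceptor_counts photon counts in the acceptor window (520-545 nm).
#' @param donor_counts photon counts in the donor window (475-495 nm); must
#'   be positive.
#' @return `acceptor_counts / donor_counts` (vectorized). Scale-invariant:
#'   multiplying both windows by the same factor (luciferase expression)
#'   leaves it unchanged.
#' @export
raw_bret <- function(acceptor_counts, donor_counts) {
  if (any(acceptor_counts < 0) || any(donor_counts < 0))
    stop("luminescence counts must be >= 0", call. = FALSE)
  if (any(donor_counts == 0))
    stop("zero donor counts: raw BRET undefined", call. = FALSE)
  acceptor_counts / donor_counts
}

#' Net BRET
#'
#' Raw BRET minus the raw BRET of donor-only cells. Not clipped: small
#' negative values are legitimate readings.
#'
#' @param raw raw BRET of the sample.
#' @param donor_only_raw raw BRET measured from cells expressing only the
#'   donor.
#' @return `raw - donor_only_raw`.
#' @export
net_bret <- function(raw, donor_only_raw) {
  if (any(!is.finite(raw)) || any(!is.finite(donor_only_raw)))
    stop("raw BRET values must be finite", call. = FALSE)
  raw - donor_only_raw
}

#' Kinetic BRET trace
#'
#' @param times timepoints in seconds, strictly increasing.
#' @param donor_counts,acceptor_counts luminescence counts per timepoint.
#' @param injections data.frame with columns `time` and `label`, each
#'   injection time within the trace span.
#' @return An object of class `bret_trace` with a computed `raw` component.
#' @export
bret_trace <- function(times, donor_counts, acceptor_counts,
                       injections = data.frame(time = numeric(0),
                                               label = character(0))) {
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(donor_counts) != length(times) ||
      length(acceptor_counts) != length(times))
    stop("counts must match timepoints", call. = FALSE)
  if (nrow(injections) &&
      (min(injections$time) < min(times) || max(injections$time) > max(times)))
    stop("injection times must lie within the trace span", call. = FALSE)
  structure(list(times = times, donor_counts = donor_counts,
                 acceptor_counts = acceptor_counts,
                 raw = raw_bret(acceptor_counts, donor_counts),
                 injections = injections),
            class = "bret_trace")
}

#' @export
print.bret_trace <- function(x, ...) {
  cat(sprintf("<bret_trace> %d timepoints over %g s, %d injection(s)\n",
              length(x$times), diff(range(x$times)), nrow(x$injections)))
  invisible(x)
}

#' Agonist-induced BRET change
#'
#' Mean raw BRET in a response window minus the mean in a baseline window.
#'
#' @param trace a `bret_trace`.
#' @param baseline_window,response_window `c(start, end)` in seconds;
#'   non-overlapping, both within the trace; the baseline must end before
#'   the first injection (when any).
#' @return Dimensionless BRET change.
#' @export
agonist_delta <- function(trace, baseline_window, response_window) {
  stopifnot(inherits(trace, "bret_trace"))
  span <- range(trace$times)
  wins <- list(baseline = baseline_window, response = response_window)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) != 2 || w[1] >= w[2] || w[1] < span[1] || w[2] > span[2])
      stop("invalid ", nm, " window", call. = FALSE)
  }
  if (baseline_window[2] > response_window[1] &&
      response_window[2] > baseline_window[1])
    stop("baseline and response windows overlap", call. = FALSE)
  if (nrow(trace$injections) && baseline_window[2] > min(trace$injections$time))
    stop("baseline window must precede the first injection", call. = FALSE)
  in_win <- function(w) trace$times >= w[1] & trace$times <= w[2]
  for (nm in names(wins)) if (!any(in_win(wins[[nm]])))
    stop("empty ", nm, " window: no timepoints inside", call. = FALSE)
  mean(trace$raw[in_win(response_window)]) -
    mean(trace$raw[in_win(baseline_window)])
}

#' Simulate a kinetic BRET trace with injections
#'
#' The underlying raw BRET approaches a new steady state exponentially after
#' each injection (piecewise-exponential relaxation); donor and acceptor
#' counts carry multiplicative Gaussian noise.
#'
#' @param baseline raw BRET before the first injection.
#' @param injections list of `list(time=, target=, tau=, label=)`: at `time`
#'   seconds the steady state moves to `target` with time constant `tau`.
#' @param duration,dt trace length and sampling interval, seconds.
#' @param donor_level expected donor-window counts.
#' @param noise_frac multiplicative noise sd on each window.
#' @param seed integer seed.
#' @return A `bret_trace`; the noiseless underlying ratio is attached as
#'   attribute `"truth"`.
#' @export
simulate_kinetic_trace <- function(baseline = 0.10,
                                   injections = list(),
                                   duration = 300, dt = 1,
                                   donor_level = 1e5,
                                   noise_frac = 0.003,
                                   seed = 1L) {
  times <- seq(0, duration, by = dt)
  truth <- rep(baseline, length(times))
  level <- baseline
  if (length(injections)) {
    ord <- order(vapply(injections, `[[`, numeric(1), "time"))
    injections <- injections[ord]
    for (inj in injections) {
      after <- times >= inj$time
      start <- truth[which(after)[1]]
      truth[after] <- inj$target +
        (start - inj$target) * exp(-(times[after] - inj$time) / inj$tau)
      level <- inj$target
    }
  }
  set.seed(as.integer(seed))
  donor <- donor_level * (1 + rnorm(length(times), 0, noise_frac))
  acceptor <- truth * donor_level * (1 + rnorm(length(times), 0, noise_frac))
  inj_df <- if (length(injections))
    data.frame(time = vapply(injections, `[[`, numeric(1), "time"),
               label = vapply(injections, function(i) i$label %||% "",
                              character(1)))
  else data.frame(time = numeric(0), label = character(0))
  tr <- bret_trace(times, donor, acceptor, inj_df)
  attr(tr, "truth") <- truth
  tr
}

# Default bystander colocalization fractions across compartments, expressed
# relative to the PM signal (the panels in the source experiments are
# graphical, so these are simulator choices, not measured values; absolute
# bystander amplitudes are not comparable across compartments).
default_bystander_fractions <- c(PM = 1.00, EE = 0.25, RE = 0.30, LE = 0.20,
                                 ER = 0.03, MT = 0.02)

#' Simulate a bystander BRET panel at the well level
#'
#' Generates donor/acceptor window counts for marker-expressing wells and
#' donor-only wells. The underlying raw BRET of a marker well is
#' `donor_only_raw + amplitude_max * fraction + effect + noise`; donor-only
#' wells sit at `donor_only_raw + noise`. Net BRET is recovered with
#' [panel_net()], reproducing the plate workflow.
#'
#' @param fractions named per-compartment colocalization fractions in
#'   `[0, 1]`.
#' @param amplitude_max net BRET of a fully colocalized marker (free scale).
#' @param effect named per-compartment additive treatment effect on net BRET
#'   (default 0: the null of no agonist-induced change).
#' @param treatment condition label stored with the wells.
#' @param n_replicates wells per compartment.
#' @param donor_level expected donor-window counts per well.
#' @param donor_only_raw raw BRET of donor-only wells (acceptor-window
#'   bleed-through of the donor emission).
#' @param noise_sd additive Gaussian noise sd on the underlying raw ratio.
#' @param seed integer seed; deterministic per seed.
#' @return data.frame of wells: `well_id`, `compartment` (donor-only wells
#'   have `"donor_only"`), `treatment`, `replicate`, `donor_counts`,
#'   `acceptor_counts`.
#' @export
simulate_bystander_panel <- function(fractions = default_bystander_fractions,
                                     amplitude_max = 0.5,
                                     effect = 0,
                                     treatment = "control",
                                     n_replicates = 4L,
                                     donor_level = 2e5,
                                     donor_only_raw = 0.40,
                                     noise_sd = 0.01,
                                     seed = 1L) {
  if (any(fractions < 0 | fractions > 1))
    stop("invalid parameter 'fractions': must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("invalid parameter 'noise_sd': must be >= 0", call. = FALSE)
  eff <- structure(rep(0, length(fractions)), names = names(fractions))
  if (length(effect) == 1 && is.null(names(effect))) eff[] <- effect
  else eff[names(effect)] <- effect
  set.seed(as.integer(seed))
  rows <- list()
  wid <- 0L
  for (comp in names(fractions)) {
    for (r in seq_len(n_replicates)) {
      wid <- wid + 1L
      raw <- donor_only_raw + amplitude_max * fractions[[comp]] +
        eff[[comp]] + rnorm(1, 0, noise_sd)
      donor <- donor_level * exp(rnorm(1, 0, 0.05))
      rows[[wid]] <- data.frame(well_id = sprintf("W%04d", wid),
                                compartment = comp, treatment = treatment,
                                replicate = r, donor_counts = donor,
                                acceptor_counts = raw * donor)
    }
  }
  for (r in seq_len(n_replicates)) {
    wid <- wid + 1L
    raw <- donor_only_raw + rnorm(1, 0, noise_sd)
    donor <- donor_level * exp(rnorm(1, 0, 0.05))
    rows[[wid]] <- data.frame(well_id = sprintf("W%04d", wid),
                              compartment = "donor_only", treatment = treatment,
                              replicate = r, donor_counts = donor,
                              acceptor_counts = raw * donor)
  }
  do.call(rbind, rows)
}

#' Simulate a paired bystander BRET study
#'
#' Emulates the paired experimental design: each independent experiment
#' (biological replicate) contains control wells, one well set per agonist
#' treatment, and donor-only wells, all read on the same plate. Within an
#' experiment every condition shares the same donor-only correction, so the
#' correction noise cancels from paired control/treated contrasts — the
#' reason the downstream analysis uses paired t-tests.
#'
#' @inheritParams simulate_bystander_panel
#' @param treatments agonist condition labels.
#' @param n_experiments number of independent experiments (paired
#'   replicates).
#' @return data.frame of wells with columns `experiment`, `well_id`,
#'   `compartment` (`"donor_only"` for donor-only wells), `treatment`
#'   (`"control"`, an agonist label, or `"donor_only"`), `donor_counts`,
#'   `acceptor_counts`.
#' @export
simulate_bystander_study <- function(fractions = default_bystander_fractions[c("EE", "RE", "LE")],
                                     treatments = c("Iso", "DA", "Ach"),
                                     n_experiments = 4L,
                                     effect = 0,
                                     amplitude_max = 0.5,
                                     donor_level = 2e5,
                                     donor_only_raw = 0.40,
                                     noise_sd = 0.01,
                                     seed = 1L) {
  if (any(fractions < 0 | fractions > 1))
    stop("invalid parameter 'fractions': must lie in [0, 1]", call. = FALSE)
  eff <- structure(rep(0, length(fractions)), names = names(fractions))
  if (length(effect) == 1 && is.null(names(effect))) eff[] <- effect
  else eff[names(effect)] <- effect
  set.seed(as.integer(seed))
  rows <- list(); wid <- 0L
  for (ex in seq_len(n_experiments)) {
    for (cond in c("control", treatments)) {
      for (comp in names(fractions)) {
        wid <- wid + 1L
        raw <- donor_only_raw + amplitude_max * fractions[[comp]] +
          (cond != "control") * eff[[comp]] + rnorm(1, 0, noise_sd)
        donor <- donor_level * exp(rnorm(1, 0, 0.05))
        rows[[wid]] <- data.frame(experiment = ex,
                                  well_id = sprintf("W%04d", wid),
                                  compartment = comp, treatment = cond,
                                  donor_counts = donor,
                                  acceptor_counts = raw * donor)
      }
    }
    for (r in 1:3) {  # donor-only wells of this experiment
      wid <- wid + 1L
      raw <- donor_only_raw + rnorm(1, 0, noise_sd)
      donor <- donor_level * exp(rnorm(1, 0, 0.05))
      rows[[wid]] <- data.frame(experiment = ex,
                                well_id = sprintf("W%04d", wid),
                                compartment = "donor_only",
                                treatment = "donor_only",
                                donor_counts = donor,
                                acceptor_counts = raw * donor)
    }
  }
  do.call(rbind, rows)
}

#' Net BRET for a paired study, corrected per experiment
#'
#' Computes raw BRET per well and subtracts, within each experiment, the
#' mean raw BRET of that experiment's donor-only wells.
#'
#' @param wells data.frame from [simulate_bystander_study()] (or a plate CSV
#'   with the same columns).
#' @param donor_only `compartment` value marking donor-only wells.
#' @return data.frame of marker wells with an added `net_bret` column.
#' @export
study_net <- function(wells, donor_only = "donor_only") {
  raw <- raw_bret(wells$acceptor_counts, wells$donor_counts)
  out <- NULL
  for (ex in unique(wells$experiment)) {
    in_ex <- wells$experiment == ex
    is_do <- in_ex & wells$compartment == donor_only
    if (!any(is_do))
      stop("experiment ", ex, " has no donor-only wells", call. = FALSE)
    keep <- in_ex & !wells$compartment == donor_only
    part <- wells[keep, , drop = FALSE]
    part$net_bret <- net_bret(raw[keep], mean(raw[is_do]))
    out <- rbind(out, part)
  }
  out
}

#' Paired control/treated contrasts from a study table
#'
#' Builds the (treated, control) replicate-vector pairs — one per
#' (compartment, treatment) — expected by [paired_t_fdr()], matching
#' replicates by experiment.
#'
#' @param net data.frame from [study_net()].
#' @param control label of the control condition.
#' @return Named list of pairs.
#' @export
bystander_pairs <- function(net, control = "control") {
  comps <- setdiff(unique(net$compartment), "donor_only")
  trts <- setdiff(unique(net$treatment), c(control, "donor_only"))
  pairs <- list()
  for (tr in trts) {
    for (comp in comps) {
      sel_t <- net$treatment == tr & net$compartment == comp
      sel_c <- net$treatment == control & net$compartment == comp
      pairs[[paste(comp, tr, sep = ":")]] <- list(
        treated = net$net_bret[sel_t][order(net$experiment[sel_t])],
        control = net$net_bret[sel_c][order(net$experiment[sel_c])])
    }
  }
  pairs
}

#' Net BRET per well from a plate table
#'
#' Computes raw BRET per well and subtracts the mean raw BRET of the
#' donor-only wells.
#'
#' @param wells data.frame as produced by [simulate_bystander_panel()] or
#'   read from a plate CSV (`well_id`, `compartment`, `treatment`,
#'   `replicate`, `donor_counts`, `acceptor_counts`).
#' @param donor_only value of `compartment` marking donor-only wells.
#' @return data.frame of marker wells with an added `net_bret` column.
#' @export
panel_net <- function(wells, donor_only = "donor_only") {
  raw <- raw_bret(wells$acceptor_counts, wells$donor_counts)
  is_do <- wells$compartment == donor_only
  if (!any(is_do))
    stop("no donor-only wells found (compartment == '", donor_only, "')",
         call. = FALSE)
  out <- wells[!is_do, , drop = FALSE]
  out$net_bret <- net_bret(raw[!is_do], mean(raw[is_do]))
  out
}
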