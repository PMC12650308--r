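#' Kinetic archetype catalogue
#'
#' Sixteen trajectory archetypes (codes A-P) spanning the kinds of kinetic
#' signatures seen in occlusion/reperfusion microdialysis time courses:
#' declines and spikes during probe implantation, peaks inside or at the
#' boundaries of the surgical and ischemic phases, reperfusion ramps, and
#' whole-run monotone or fluctuating backgrounds. Each archetype carries the
#' annotation (`peak_location`, `trend`) that its zero-noise template is
#' expected to receive from [annotate_clusters()].
#'
#' @return Tibble with columns `code`, `description`, `peak_location`,
#'   `trend`.
#' @examples
#' archetype_specs()
#' @export
archetype_specs <- function() {
  tibble::tribble(
    ~code, ~description,                                            ~peak_location, ~trend,
    "A", "gradual decline across phase I, then stable",             "I",     "decrease",
    "B", "rapid early decline within phase I, then stable",         "I",     "decrease",
    "C", "sharp spike-and-return within phase I",                   "I",     "peak",
    "D", "twin peaks in phases I and II",                           "II",    "biphasic",
    "E", "peak at the II/III boundary",                             "II/III", "peak",
    "F", "wide peak spanning phases II-III, centred in II",         "II",    "peak",
    "G", "wide peak spanning phases II-III, centred in early III",  "IIIA",  "peak",
    "H", "broad peak across the ischemia block",                    "IIIA/IIIB", "peak",
    "I", "peak at the III/IV boundary",                             "III/IV", "peak",
    "J", "peak at the end of phase III with incomplete recovery",   "IIIB",  "peak",
    "K", "broad peak straddling the III/IV boundary",               "III/IV", "peak",
    "L", "rapid rise across phase IV",                              "IV",    "increase",
    "M", "gradual decline across phase IV",                         "IV",    "decrease",
    "N", "continuous fluctuation throughout all phases",            "none",  "fluctuating",
    "O", "gradual decline throughout all phases",                   "all",   "decrease",
    "P", "gradual rise throughout all phases",                      "all",   "increase"
  )
}

#' Zero-noise intensity template for one archetype
#'
#' Templates are positive multiplicative profiles (baseline 1) over the
#' collections of `schedule`, built from piecewise-linear ramps and Gaussian
#' bumps anchored to the phase blocks, so that each template realizes its
#' archetype's qualitative dynamics at any schedule resolution.
#'
#' @param code Single archetype code, one of `LETTERS[1:16]`.
#' @param schedule A [build_schedule()] result.
#' @return Numeric vector, one value per collection, all positive.
#' @examples
#' sched <- build_schedule()
#' plot(archetype_template("E", sched), type = "b")
#' @export
archetype_template <- function(code, schedule = build_schedule()) {
  codes <- archetype_specs()$code
  if (length(code) != 1 || !code %in% codes) {
    abort(sprintf(
      "Unknown archetype code %s; valid codes are %s.",
      deparse(code), paste(codes, collapse = ", ")
    ))
  }
  stopifnot(inherits(schedule, "phase_schedule"))
  t <- schedule$collection_index
  n <- length(t)
  ph <- as.character(schedule$phase)
  rng <- function(p) range(t[ph %in% p])
  first <- function(p) rng(p)[1]
  last <- function(p) rng(p)[2]
  mid <- function(p) mean(rng(p))
  bound <- function(p, q) (last(p) + first(q)) / 2
  bump <- function(center, width) exp(-0.5 * ((t - center) / width)^2)
  ## linear 0 -> 1 ramp across a phase block, 0 before, 1 after
  ramp_up <- function(p) {
    r <- rng(p)
    pmin(1, pmax(0, (t - r[1]) / (r[2] - r[1])))
  }
  u <- t / (n - 1)

  switch(code,
    A = 1 + 0.8 * (1 - pmin(1, pmax(0, (t - first("I")) / (last("I") - first("I"))))),
    B = 1 + 1.2 * exp(-t / 1.2),
    C = 1 + 1.5 * bump(mid("I"), 0.8),
    D = 1 + 1.2 * bump(mid("I"), 1.0) + 1.4 * bump(mid("II"), 1.0),
    E = 1 + 1.6 * bump(bound("II", "IIIA"), 1.2),
    F = 1 + 1.5 * bump(mid("II") + 0.25 * (mid("IIIA") - mid("II")), 2.5),
    G = 1 + 1.5 * bump(mid("IIIA"), 2.5),
    H = 1 + 1.4 * bump(bound("IIIA", "IIIB"), 3.2),
    I = 1 + 1.6 * bump(bound("IIIB", "IV"), 1.2),
    J = 1 + 1.5 * bump(last("IIIB") - 1, 1.3) +
      0.5 * stats::plogis(t - (last("IIIB") - 1)),
    K = 1 + 1.3 * bump(bound("IIIB", "IV"), 3.0),
    L = 1 + 2.0 * ramp_up("IV"),
    M = 1.6 - 0.9 * ramp_up("IV"),
    N = 1 + 0.8 * sin(2 * pi * 3 * u),
    O = 2 - 1.2 * u,
    P = 0.8 + 1.2 * u
  )
}

#' Declarative template fidelity checks
#'
#' Verifies that a trajectory satisfies the qualitative dynamics its
#' archetype declares: peak inside the declared window for peaked shapes,
#' monotonicity over the declared span for trend shapes. Used to validate the
#' zero-noise templates and in annotation round-trip tests.
#'
#' @param traj Numeric trajectory over the schedule's collections.
#' @param code Archetype code.
#' @param schedule A `phase_schedule`.
#' @return `TRUE` or `FALSE`.
#' @export
check_template <- function(traj, code, schedule = build_schedule()) {
  spec <- dplyr::filter(archetype_specs(), .data$code == !!code)
  if (nrow(spec) != 1) abort("Unknown archetype code.")
  ph <- as.character(schedule$phase)
  t <- schedule$collection_index
  loc <- spec$peak_location
  trend <- spec$trend
  in_window <- function(idx, loc) {
    if (loc %in% c("none", "all")) return(TRUE)
    if (grepl("/", loc)) {
      bs <- phase_boundaries(schedule)
      hit <- purrr::keep(bs, ~ .x$token == loc)
      if (length(hit) == 0) return(FALSE)
      idx %in% hit[[1]]$indices
    } else {
      ph[match(idx, t)] == loc
    }
  }
  strictly <- function(x, dir) all(dir * diff(x) > 0)
  switch(trend,
    peak = ,
    biphasic = in_window(t[which.max(traj)], loc),
    increase = if (loc == "all") strictly(traj, 1) else strictly(traj[ph == loc], 1),
    decrease = if (loc == "all") strictly(traj, -1) else strictly(traj[ph == loc], -1),
    fluctuating = diff(range(traj)) == 0 ||
      abs(cor(traj, seq_along(traj), method = "spearman")) < 0.5
  )
}
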