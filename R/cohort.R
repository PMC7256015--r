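# Synthetic longitudinal cohorts: per-animal delivery variability, stable
# gold content over two weeks, simulated elemental-assay (ICP-OES) ground
# truth, and occasional administration failures.

#' Longitudinal study design
#'
#' Describes one arm-structured cohort: injected cell doses per animal,
#' imaging-day windows, and whether an administration-failure animal is
#' included. Defaults reproduce the two study designs: `"monocolor"`
#' (13 animals at 0.5e6 cells, windows day 0-3 / 4-7 / 13-14, one failure)
#' and `"bicolor"` (9 animals at 0.5/0.25/0.125e6 cells, windows day 1-2 /
#' 4-6 / 12-14).
#'
#' @param design `"monocolor"` or `"bicolor"`, or `"custom"` with explicit
#'   `doses`.
#' @param doses Injected cell counts per animal (overrides the design
#'   default).
#' @param windows List of two-element day ranges, ordered.
#' @param n_failures Number of administration-failure animals (delivery
#'   efficiency ~0.115, below the 0.2 failure threshold).
#' @param per_cell_load_pg Gold load per cell, pg.
#' @return Object of class `study_design`.
#' @export
study_design <- function(design = c("monocolor", "bicolor", "custom"),
                         doses = NULL, windows = NULL, n_failures = NULL,
                         per_cell_load_pg = 128) {
  design <- match.arg(design)
  if (is.null(doses)) {
    doses <- switch(design,
      monocolor = rep(0.5e6, 13),
      bicolor   = c(rep(0.5e6, 5), rep(0.25e6, 2), rep(0.125e6, 2)),
      custom    = stop("custom design requires explicit doses"))
  }
  if (length(doses) < 1 || any(doses <= 0)) stop("doses must be positive (n >= 1)")
  if (is.null(windows)) {
    windows <- if (design == "bicolor")
      list(c(1, 2), c(4, 6), c(12, 14)) else list(c(0, 3), c(4, 7), c(13, 14))
  }
  lo <- vapply(windows, min, 0); hi <- vapply(windows, max, 0)
  if (any(diff(lo) <= 0) || any(hi < lo)) stop("timepoint windows must be ordered")
  if (is.null(n_failures)) n_failures <- if (design == "monocolor") 1L else 0L
  structure(list(design = design, doses = doses, windows = windows,
                 n_failures = as.integer(n_failures),
                 per_cell_load_pg = per_cell_load_pg),
            class = "study_design")
}

# deterministic per-animal substream seed below 2^31
.animal_seed <- function(seed, idx) {
  (as.numeric(seed) * 1000003 + idx * 7919) %% 2147483629
}

#' Generate a synthetic cohort
#'
#' Each animal gets a delivery efficiency drawn from a log-normal
#' distribution (median 0.75, sigma_log 0.3, clipped to (0, 1]) --
#' calibrated so a 0.5e6-cell arm averages ~48 ug of delivered gold.
#' Designated failure animals get efficiency 0.115 instead (~7.4 ug at the
#' 0.5e6 dose). True brain gold is `dose x per-cell load x efficiency`,
#' constant across all timepoints (no proliferation, no label elimination);
#' the terminal ICP-OES measurement adds multiplicative noise via
#' [icpoes_measure()]. Each animal uses its own pseudo-random substream
#' derived from `(seed, animal index)`, so records are independent of
#' generation order.
#'
#' @param design A [study_design()].
#' @param seed Integer seed (mandatory).
#' @param icpoes_cv Coefficient of variation of the ICP-OES measurement.
#' @return data.frame of class `animal_cohort`, one row per animal, with
#'   list-columns `days` and `true_gold_per_timepoint_ug`.
#' @export
#' @examples
#' coh <- generate_cohort(study_design("monocolor"), seed = 42)
#' coh$true_gold_ug
generate_cohort <- function(design, seed, icpoes_cv = 0.05) {
  stopifnot(inherits(design, "study_design"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  nA <- length(design$doses)
  ntp <- length(design$windows)
  fail <- seq_len(nA) %in% utils::tail(seq_len(nA), design$n_failures)
  recs <- lapply(seq_len(nA), function(i) {
    set.seed(.animal_seed(seed, i))          # one substream per animal
    if (fail[i]) {
      eff <- 0.115
    } else {
      eff <- min(stats::rlnorm(1, meanlog = log(0.75), sdlog = 0.3), 1)
    }
    days <- vapply(design$windows, function(w) {
      if (w[1] == w[2]) w[1] else sample(seq(w[1], w[2]), 1)
    }, 0)
    true_gold <- design$doses[i] * design$per_cell_load_pg * 1e-6 * eff  # ug
    icp <- icpoes_measure(true_gold, cv = icpoes_cv)
    list(eff = eff, days = days, true_gold = true_gold, icp = icp)
  })
  out <- data.frame(
    id = sprintf("%s-%02d", design$design, seq_len(nA)),
    design = design$design,
    injected_cells = design$doses,
    delivery_efficiency = vapply(recs, `[[`, 0, "eff"),
    failure = fail,
    true_gold_ug = vapply(recs, `[[`, 0, "true_gold"),
    icp_gold_ug = vapply(recs, `[[`, 0, "icp"))
  out$days <- I(lapply(recs, `[[`, "days"))
  out$true_gold_per_timepoint_ug <- I(lapply(recs, function(r) {
    rep(r$true_gold, ntp)                    # longitudinal stability
  }))
  class(out) <- c("animal_cohort", class(out))
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}

#' Simulated ICP-OES gold measurement
#'
#' The elemental assay is abstracted as ground truth plus multiplicative
#' Gaussian noise (default CV 5%, typical instrument precision), truncated
#' at zero.
#'
#' @param true_gold_ug True gold mass, ug (>= 0).
#' @param cv Coefficient of variation (>= 0, default 0.05).
#' @param seed Optional seed for this draw.
#' @return Measured gold mass, ug.
#' @export
#' @examples
#' icpoes_measure(48, cv = 0)  # 48
icpoes_measure <- function(true_gold_ug, cv = 0.05, seed = NULL) {
  if (any(true_gold_ug < 0)) stop("true gold must be >= 0")
  if (cv < 0) stop("cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pmax(true_gold_ug * (1 + cv * stats::rnorm(length(true_gold_ug))), 0)
}

#' Long-format cohort table
#'
#' One row per animal x timepoint, suitable for CSV export.
#'
#' @param cohort An [generate_cohort()] result.
#' @return data.frame with columns id, design, timepoint, day,
#'   injected_cells, delivery_efficiency, failure, true_gold_ug,
#'   icp_gold_ug.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    days <- cohort$days[[i]]
    data.frame(id = cohort$id[i], design = cohort$design[i],
               timepoint = seq_along(days), day = days,
               injected_cells = cohort$injected_cells[i],
               delivery_efficiency = cohort$delivery_efficiency[i],
               failure = cohort$failure[i],
               true_gold_ug = cohort$true_gold_per_timepoint_ug[[i]],
               icp_gold_ug = cohort$icp_gold_ug[i])
  })
  do.call(rbind, rows)
}
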