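#' Trial schedules for the three experimental designs
#'
#' Builds the per-phase stimulus schedule for one participant of a virtual
#' dot-estimation experiment:
#'
#' * `"lab"` — two 16-trial solo phases whose dot counts run over
#'   25, 27, ..., 55 (each magnitude exactly once), flanking a 144-trial
#'   interaction phase (nine repetitions of the same 16-magnitude set).
#' * `"fmri"` — one 24-trial pre-interaction phase, two 48-trial interaction
#'   phases and two 24-trial post-interaction phases; dot counts drawn from
#'   25, 28, ..., 58.
#' * `"online"` — pre (24), interaction (48) and post (24) phases over the
#'   same 25..58 step-3 magnitude set.
#'
#' Presentation order within each phase is a seeded permutation, so the
#' multiset of magnitudes per phase is seed-independent.
#'
#' @param design_name one of `"lab"`, `"fmri"`, `"online"`.
#' @param seed integer seed controlling presentation order.
#' @param balanced for 24/48-trial phases, repeat each magnitude an equal
#'   number of times (default) or sample magnitudes uniformly when `FALSE`.
#' @return object of class `dyad_schedule`: a list with `design_name` and
#'   `phases`, each phase a list with `phase_label`, `trial_count`,
#'   `dot_counts` and `interaction`.
#' @examples
#' sch <- make_schedule("lab", seed = 1)
#' lengths(lapply(sch$phases, `[[`, "dot_counts"))
#' @export
make_schedule <- function(design_name, seed = 1L, balanced = TRUE) {
  if (!design_name %in% c("lab", "fmri", "online")) {
    stop("unknown design_name: '", design_name,
         "' (expected one of 'lab', 'fmri', 'online')")
  }
  with_seed(seed, {
    phases <- switch(design_name,
      lab = {
        mags <- seq(25L, 55L, by = 2L)
        list(
          sched_phase("phase1", sample(mags), FALSE),
          sched_phase("phase2", sample(rep(mags, 9L)), TRUE),
          sched_phase("phase3", sample(mags), FALSE)
        )
      },
      fmri = {
        mags <- seq(25L, 58L, by = 3L)
        list(
          sched_phase("pre", draw_mags(mags, 24L, balanced), FALSE),
          sched_phase("interaction1", draw_mags(mags, 48L, balanced), TRUE),
          sched_phase("post1", draw_mags(mags, 24L, balanced), FALSE),
          sched_phase("interaction2", draw_mags(mags, 48L, balanced), TRUE),
          sched_phase("post2", draw_mags(mags, 24L, balanced), FALSE)
        )
      },
      online = {
        mags <- seq(25L, 58L, by = 3L)
        list(
          sched_phase("pre", draw_mags(mags, 24L, balanced), FALSE),
          sched_phase("interaction", draw_mags(mags, 48L, balanced), TRUE),
          sched_phase("post", draw_mags(mags, 24L, balanced), FALSE)
        )
      }
    )
    structure(list(design_name = design_name, phases = phases),
              class = "dyad_schedule")
  })
}

sched_phase <- function(label, dots, interaction) {
  stopifnot(all(dots > 0), all(dots == as.integer(dots)))
  list(phase_label = label, trial_count = length(dots),
       dot_counts = as.integer(dots), interaction = interaction)
}

draw_mags <- function(mags, n, balanced) {
  if (balanced && n %% length(mags) == 0) {
    sample(rep(mags, n / length(mags)))
  } else {
    sample(mags, n, replace = TRUE)
  }
}

#' @export
print.dyad_schedule <- function(x, ...) {
  cat("<dyad_schedule>", x$design_name, "design\n")
  for (ph in x$phases) {
    cat(sprintf("  %-14s %3d trials%s\n", ph$phase_label, ph$trial_count,
                if (ph$interaction) "  [interaction]" else ""))
  }
  invisible(x)
}

# Find a phase by label.
schedule_phase <- function(schedule, phase_label) {
  for (ph in schedule$phases) if (ph$phase_label == phase_label) return(ph)
  stop("no phase '", phase_label, "' in schedule")
}
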