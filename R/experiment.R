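#' Simulate a complete virtual experiment
#'
#' Drives the per-phase simulators over one of the three designs, carrying
#' each participant's latent weight across phases (so interaction
#' after-effects persist into post phases):
#'
#' * `"lab"`: `n_pairs` real pairs interact freely in the 144-trial Phase 2
#'   while `n_individual` control participants repeat the task alone;
#'   Phases 1 and 3 are solo for everyone.
#' * `"fmri"`: each participant meets a Sherif-type and an Asch-type partner
#'   (both with built-in weight 0.61) in two 48-trial interaction phases,
#'   order counterbalanced across participants.
#' * `"online"`: each participant is randomly assigned to one cell of the
#'   2 x 2 design (partner type x under-/over-estimating bias, built-in
#'   weights 0.61 / 1.21) for a single 48-trial interaction phase.
#'
#' @param design `"lab"`, `"fmri"`, or `"online"`.
#' @param seed integer master seed; every random draw in the experiment
#'   flows from it.
#' @param n_pairs,n_individual lab design sizes.
#' @param n_participants number of participants (fmri/online designs).
#' @param population passed to [sample_participants()].
#' @param balanced passed to [make_schedule()].
#' @param ... further arguments passed to [virtual_participant()] through
#'   [sample_participants()] (noise SDs, reciprocity coefficients).
#' @return data.frame of trial records for all participants. For the lab
#'   design, attribute `"real_pairs"` holds the 2-column matrix of paired
#'   ids.
#' @examples
#' trials <- simulate_experiment("online", seed = 1, n_participants = 4)
#' head(trials)
#' @export
simulate_experiment <- function(design = c("lab", "fmri", "online"),
                                seed = 1L,
                                n_pairs = 21L, n_individual = 21L,
                                n_participants = 28L,
                                population = default_population_params(),
                                balanced = TRUE, ...) {
  design <- match.arg(design)
  with_seed(seed, {
    switch(design,
           lab = sim_lab(n_pairs, n_individual, population, ...),
           fmri = sim_fmri(n_participants, population, balanced, ...),
           online = sim_online(n_participants, population, balanced, ...))
  })
}

sim_lab <- function(n_pairs, n_individual, population, ...) {
  n <- 2L * n_pairs + n_individual
  parts <- sample_participants(n, seed = NULL, params = population, ...)
  recs <- list()
  pair_ids <- matrix("", nrow = n_pairs, ncol = 2)
  for (k in seq_len(n_pairs)) {
    p1 <- parts[[2 * k - 1]]
    p2 <- parts[[2 * k]]
    pair_ids[k, ] <- c(p1$id, p2$id)
    s1 <- make_schedule("lab", seed = sample.int(2^31 - 1, 1))
    s2 <- make_schedule("lab", seed = sample.int(2^31 - 1, 1))
    shared <- make_schedule("lab", seed = sample.int(2^31 - 1, 1))
    r1a <- simulate_solo_phase(p1, schedule_phase(s1, "phase1"),
                               condition = "pair")
    r2a <- simulate_solo_phase(p2, schedule_phase(s2, "phase1"),
                               condition = "pair")
    ri <- simulate_interaction_phase(
      p1, p2, schedule_phase(shared, "phase2"), condition = "pair",
      start_weight = attr(r1a, "final_weight"),
      partner_start_weight = attr(r2a, "final_weight"))
    r1c <- simulate_solo_phase(p1, schedule_phase(s1, "phase3"),
                               condition = "pair",
                               start_weight = attr(ri, "final_weight"))
    r2c <- simulate_solo_phase(p2, schedule_phase(s2, "phase3"),
                               condition = "pair",
                               start_weight = attr(ri, "partner_final_weight"))
    recs <- c(recs, list(r1a, r2a, ri, attr(ri, "partner_records"), r1c, r2c))
  }
  for (k in seq_len(n_individual)) {
    p <- parts[[2 * n_pairs + k]]
    s <- make_schedule("lab", seed = sample.int(2^31 - 1, 1))
    ra <- simulate_solo_phase(p, schedule_phase(s, "phase1"),
                              condition = "individual")
    ph2 <- schedule_phase(s, "phase2")
    ph2$interaction <- FALSE  # control group repeats the task alone
    rb <- simulate_solo_phase(p, ph2, condition = "individual",
                              start_weight = attr(ra, "final_weight"))
    rc <- simulate_solo_phase(p, schedule_phase(s, "phase3"),
                              condition = "individual",
                              start_weight = attr(rb, "final_weight"))
    recs <- c(recs, list(ra, rb, rc))
  }
  out <- do.call(rbind, lapply(recs, strip_attrs))
  attr(out, "real_pairs") <- pair_ids
  out
}

sim_fmri <- function(n_participants, population, balanced, ...) {
  parts <- sample_participants(n_participants, seed = NULL,
                               params = population, ...)
  recs <- list()
  for (k in seq_len(n_participants)) {
    p <- parts[[k]]
    sch <- make_schedule("fmri", seed = sample.int(2^31 - 1, 1),
                         balanced = balanced)
    order_sherif_first <- k %% 2 == 1
    partners <- if (order_sherif_first) c("sherif", "asch")
                else c("asch", "sherif")
    pre <- simulate_solo_phase(p, schedule_phase(sch, "pre"))
    w <- attr(pre, "final_weight")
    recs <- c(recs, list(pre))
    for (j in 1:2) {
      agent <- agent_config(partners[j], initial_weight = 0.61)
      ri <- simulate_interaction_phase(
        p, agent, schedule_phase(sch, paste0("interaction", j)),
        condition = partners[j], start_weight = w)
      rp <- simulate_solo_phase(
        p, schedule_phase(sch, paste0("post", j)),
        condition = paste0("post_", partners[j]),
        start_weight = attr(ri, "final_weight"))
      w <- attr(rp, "final_weight")
      recs <- c(recs, list(ri, rp))
    }
  }
  do.call(rbind, lapply(recs, strip_attrs))
}

sim_online <- function(n_participants, population, balanced, ...) {
  parts <- sample_participants(n_participants, seed = NULL,
                               params = population, ...)
  cells <- expand.grid(type = c("sherif", "asch"),
                       bias = c("under", "over"),
                       stringsAsFactors = FALSE)
  assign <- cells[sample.int(4, n_participants, replace = TRUE), ]
  recs <- list()
  for (k in seq_len(n_participants)) {
    p <- parts[[k]]
    sch <- make_schedule("online", seed = sample.int(2^31 - 1, 1),
                         balanced = balanced)
    type <- assign$type[k]
    bias_w <- if (assign$bias[k] == "under") 0.61 else 1.21
    cond <- paste(type, assign$bias[k], sep = "_")
    agent <- agent_config(type, initial_weight = bias_w)
    pre <- simulate_solo_phase(p, schedule_phase(sch, "pre"),
                               condition = cond)
    ri <- simulate_interaction_phase(p, agent,
                                     schedule_phase(sch, "interaction"),
                                     condition = cond,
                                     start_weight = attr(pre, "final_weight"))
    post <- simulate_solo_phase(p, schedule_phase(sch, "post"),
                                condition = cond,
                                start_weight = attr(ri, "final_weight"))
    recs <- c(recs, list(pre, ri, post))
  }
  do.call(rbind, lapply(recs, strip_attrs))
}

strip_attrs <- function(df) {
  attr(df, "final_weight") <- NULL
  attr(df, "partner_records") <- NULL
  attr(df, "partner_final_weight") <- NULL
  df
}
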