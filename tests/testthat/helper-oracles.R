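# Independent oracles and fixture builders, deliberately written as plain
# loops over the update equations rather than through the package's own
# simulation path.

# Two-pathway delta rule iterated by hand. `cs_list` is a list of character
# vectors (empty = US alone), `us` a 0/1 vector, `flu` a logical vector
# (flupentixol active on that trial).
oracle_two_pathway <- function(stimuli, cs_list, us,
                               flu = rep(FALSE, length(us)),
                               alpha_cr = 0.3, alpha_da = 0.3, lambda = 1) {
  w_cr <- w_da <- stats::setNames(numeric(length(stimuli)), stimuli)
  for (i in seq_along(cs_list)) {
    cs <- cs_list[[i]]
    d <- max(0, lambda * us[i] - sum(w_da[cs]))
    if (length(cs)) {
      w_da[cs] <- w_da[cs] + alpha_da * d
      if (!flu[i]) w_cr[cs] <- w_cr[cs] + alpha_cr * d
    }
  }
  list(w_cr = w_cr, w_da = w_da)
}

# Lone-CS protocol with n paired trials, built through the public constructor.
make_lone_protocol <- function(n, stim = "odor_maple", iti_s = 300) {
  protocol(
    name = sprintf("lone_%d", n), target = stim,
    stimuli = tibble::tibble(
      stimulus = stim,
      modality = ifelse(grepl("^pattern", stim), "visual", "olfactory")),
    phases = tibble::tibble(phase = 1L, label = "training", day = 1L,
                            iti_s = iti_s, flupentixol = FALSE,
                            epinastine = FALSE),
    events = tibble::tibble(phase = 1L, trial = seq_len(n), kind = "paired",
                            cs = stim, us = 1L, time_s = (seq_len(n) - 1) * iti_s)
  )
}

# Hand-built preference records (one row per animal x test).
make_records <- function(animal_id, group, test, sc, scn) {
  tibble::tibble(
    animal_id = animal_id, group = group, test = test,
    seconds_conditioned = as.integer(sc), seconds_control = as.integer(scn),
    test_duration_s = 240,
    retained = (sc + scn) >= 10,
    relative_preference = ifelse(sc + scn > 0, sc / (sc + scn), NA_real_)
  )
}

uniform_salience <- c(olfactory = 1, visual = 1)
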