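#' Circuit state: two modifiable synapse populations per stimulus
#'
#' The circuit carries, for every stimulus, the efficacy of two synapse
#' populations: `w_cs_cr`, the CS->CR synapses that drive the conditioned
#' avoidance response, and `w_cs_da`, the inhibitory CS->DA synapses onto the
#' dopamine neurons that encode how much US the stimulus predicts. Both
#' start at zero (silent or very weak synapses) and are strengthened by
#' CS-US pairing.
#'
#' @param stimuli Data frame with columns `stimulus` and `modality`, or a
#'   character vector of stimulus names (modality then inferred from a
#'   `pattern`/`visual` name prefix, otherwise olfactory).
#' @param w_cs_cr,w_cs_da Optional named numeric vectors of initial weights
#'   (default all zero; must be non-negative).
#' @return An object of class `pe_circuit_state`.
#' @examples
#' circuit_state(c("odor_maple", "pattern_white_center"))
#' @export
circuit_state <- function(stimuli, w_cs_cr = NULL, w_cs_da = NULL) {
  if (is.character(stimuli)) {
    stimuli <- tibble(
      stimulus = stimuli,
      modality = ifelse(grepl("^(pattern|visual)", stimuli), "visual", "olfactory")
    )
  }
  stimuli <- as_tibble(stimuli)
  stopifnot(all(c("stimulus", "modality") %in% names(stimuli)),
            !anyDuplicated(stimuli$stimulus))
  init <- function(w) {
    out <- setNames(rep(0, nrow(stimuli)), stimuli$stimulus)
    if (!is.null(w)) {
      stopifnot(!is.null(names(w)), all(names(w) %in% stimuli$stimulus),
                all(w >= 0))
      out[names(w)] <- w
    }
    out
  }
  structure(
    list(stimuli = stimuli, w_cs_cr = init(w_cs_cr), w_cs_da = init(w_cs_da)),
    class = "pe_circuit_state"
  )
}

#' @export
print.pe_circuit_state <- function(x, ...) {
  cat("<pe_circuit_state>\n")
  print(final_weights(x))
  invisible(x)
}

#' Pharmacology flags for one training phase
#'
#' Drugs are injected 30 min before training and assumed active for the
#' whole phase, cleared by the next day. Flupentixol (a dopamine-receptor
#' antagonist) blocks plasticity at the CS->CR synapses but spares the
#' CS->DA prediction pathway; epinastine (an octopamine-receptor antagonist)
#' has no effect on this aversive circuit.
#'
#' @param flupentixol_active,epinastine_active Logical flags.
#' @return A list of class `pe_pharmacology_state`.
#' @export
pharmacology_state <- function(flupentixol_active = FALSE,
                               epinastine_active = FALSE) {
  stopifnot(is.logical(flupentixol_active), length(flupentixol_active) == 1,
            is.logical(epinastine_active), length(epinastine_active) == 1)
  structure(list(flupentixol_active = flupentixol_active,
                 epinastine_active = epinastine_active),
            class = "pe_pharmacology_state")
}

#' Dopamine-neuron activity: the US prediction error
#'
#' During a trial the dopamine neurons receive excitatory input representing
#' the actual US and inhibitory input from the CS neurons representing the
#' US predicted by the presented stimuli; their activity is therefore the
#' prediction error
#' `delta = lambda_us * us - sum(w_cs_da[cs_set])`,
#' floored at zero when `rectify_error` is set (the default; firing rates
#' cannot go below baseline).
#'
#' @param state A [circuit_state()].
#' @param cs_set Character vector of presented stimuli (possibly empty);
#'   stimuli without a weight entry contribute zero prediction.
#' @param us_magnitude 0 or 1 (presence of the salt-water US).
#' @param params A [learning_params()] object.
#' @return The scalar prediction error `delta`.
#' @examples
#' st <- circuit_state("odor_maple")
#' da_activity(st, "odor_maple", 1, learning_params()) # nothing predicted: 1
#' @export
da_activity <- function(state, cs_set, us_magnitude, params) {
  stopifnot(inherits(state, "pe_circuit_state"),
            is.numeric(us_magnitude), length(us_magnitude) == 1,
            us_magnitude %in% c(0, 1))
  if (any(state$w_cs_da < 0) || any(state$w_cs_cr < 0)) {
    abort("circuit weights must be non-negative")
  }
  known <- intersect(cs_set, names(state$w_cs_da))
  raw <- params$lambda_us * us_magnitude - sum(state$w_cs_da[known])
  if (isTRUE(params$rectify_error)) max(0, raw) else raw
}

#' Apply one trial event to the circuit
#'
#' Both pathways share the same prediction-error signal `delta` (see
#' [da_activity()]) and are updated by a summed-error delta rule: for each
#' presented stimulus `i`,
#' `dw_cs_da[i] = alpha_da * s_i * delta` always, and
#' `dw_cs_cr[i] = alpha_cr * s_i * delta` unless flupentixol is active, in
#' which case the response-pathway update is zero while the prediction
#' pathway still learns — the circuit-level assumption behind auto-blocking.
#' Epinastine leaves both pathways of this aversive circuit untouched.
#' `us_alone` events change nothing (no eligible CS).
#'
#' @param state A [circuit_state()].
#' @param event A list or one-row data frame with elements `kind`
#'   (`paired`, `cs_alone`, `us_alone`), `cs` (character vector of stimuli,
#'   or a single `"a+b"` string), and `us` (0 or 1).
#' @param pharm A [pharmacology_state()].
#' @param params A [learning_params()].
#' @return The updated `pe_circuit_state`, with the trial's `delta` attached
#'   as attribute `"delta"`.
#' @export
apply_trial <- function(state, event, pharm = pharmacology_state(),
                        params = learning_params()) {
  stopifnot(inherits(state, "pe_circuit_state"),
            inherits(pharm, "pe_pharmacology_state"))
  cs_set <- event$cs
  if (is.list(cs_set)) cs_set <- cs_set[[1]]
  if (length(cs_set) == 1 && (grepl("+", cs_set, fixed = TRUE) || !nzchar(cs_set))) {
    cs_set <- split_cs(cs_set)[[1]]
  }
  kind <- event$kind
  us <- as.numeric(event$us)
  if (kind == "cs_alone" && us != 0) abort("cs_alone events must have us = 0")
  if (kind == "paired" && (length(cs_set) == 0 || us != 1)) {
    abort("paired events need a nonempty CS set and us = 1")
  }
  if (!all(cs_set %in% state$stimuli$stimulus)) {
    abort(sprintf("unknown stimulus: %s",
                  paste(setdiff(cs_set, state$stimuli$stimulus), collapse = ", ")))
  }
  delta <- da_activity(state, cs_set, us, params)
  if (length(cs_set)) {
    modality <- state$stimuli$modality[match(cs_set, state$stimuli$stimulus)]
    s_i <- stimulus_salience(params, cs_set, modality)
    state$w_cs_da[cs_set] <- state$w_cs_da[cs_set] + params$alpha_da * s_i * delta
    if (!pharm$flupentixol_active) {
      state$w_cs_cr[cs_set] <- state$w_cs_cr[cs_set] + params$alpha_cr * s_i * delta
    }
  }
  attr(state, "delta") <- delta
  state
}

#' Simulate a full protocol through the circuit
#'
#' Runs every phase of a protocol through [apply_trial()] in order and
#' returns the trajectory: one row per event and stimulus with the synaptic
#' weights after the event and the event's prediction error. The dynamics
#' are deterministic; `seed` is accepted only for interface uniformity with
#' the stochastic stages of the pipeline.
#'
#' @param protocol A `pe_protocol` (see [build_protocol()]).
#' @param params A [learning_params()].
#' @param seed Ignored (deterministic stage).
#' @return A tibble of class `pe_trajectory` with columns `phase`,
#'   `trial_index`, `event_kind`, `stimulus`, `w_cs_cr`, `w_cs_da`, `delta`,
#'   and attributes `final_state` (a `pe_circuit_state`), `target`,
#'   `protocol_name` and `params`.
#' @examples
#' traj <- run_protocol(build_protocol("control_Y_plus"), learning_params())
#' final_weights(traj)
#' @export
run_protocol <- function(protocol, params = learning_params(), seed = NULL) {
  stopifnot(inherits(protocol, "pe_protocol"))
  violations <- validate_protocol(protocol)
  if (length(violations)) {
    abort(paste0("invalid protocol: ", paste(violations, collapse = "; ")))
  }
  state <- circuit_state(protocol$stimuli)
  phases <- protocol$phases[order(protocol$phases$phase), ]
  rows <- vector("list", nrow(protocol$events))
  r <- 0L
  for (i in seq_len(nrow(phases))) {
    ph <- phases[i, ]
    pharm <- pharmacology_state(ph$flupentixol, ph$epinastine)
    ev <- protocol$events[protocol$events$phase == ph$phase, ]
    ev <- ev[order(ev$time_s), ]
    for (j in seq_len(nrow(ev))) {
      state <- apply_trial(state, as.list(ev[j, ]), pharm, params)
      r <- r + 1L
      rows[[r]] <- tibble(
        phase = ph$phase,
        trial_index = ev$trial[j],
        event_kind = ev$kind[j],
        stimulus = names(state$w_cs_cr),
        w_cs_cr = unname(state$w_cs_cr),
        w_cs_da = unname(state$w_cs_da),
        delta = attr(state, "delta")
      )
    }
  }
  traj <- dplyr::bind_rows(rows)
  attr(state, "delta") <- NULL
  structure(traj,
            class = c("pe_trajectory", class(traj)),
            final_state = state,
            target = protocol$target,
            protocol_name = protocol$name,
            params = params)
}

#' Final synaptic weights of a simulation
#'
#' @param x A `pe_trajectory` (from [run_protocol()]) or a
#'   `pe_circuit_state`.
#' @return A tibble with columns `stimulus`, `w_cs_cr`, `w_cs_da`.
#' @export
final_weights <- function(x) {
  if (inherits(x, "pe_trajectory")) x <- attr(x, "final_state")
  stopifnot(inherits(x, "pe_circuit_state"))
  tibble(stimulus = names(x$w_cs_cr),
         w_cs_cr = unname(x$w_cs_cr),
         w_cs_da = unname(x$w_cs_da))
}

#' Closed-form single-CS acquisition curve
#'
#' For a lone CS paired with the US on every trial, the summed-error delta
#' rule has the closed form
#' `w_n = lambda_us * (1 - (1 - alpha_eff)^n)`,
#' with `alpha_eff = alpha * salience`. Used as the analytic oracle for the
#' simulated dynamics.
#'
#' @param n_trials Number of paired trials (>= 0).
#' @param alpha_eff Effective learning rate in (0, 1].
#' @param lambda_us US asymptote (> 0).
#' @return The weight after `n_trials` trials.
#' @examples
#' closed_form_single_cs(2, 0.3, 1) # 0.51
#' @export
closed_form_single_cs <- function(n_trials, alpha_eff, lambda_us = 1) {
  stopifnot(all(n_trials >= 0), all(n_trials == round(n_trials)),
            all(alpha_eff > 0), all(alpha_eff <= 1), all(lambda_us > 0))
  lambda_us * (1 - (1 - alpha_eff)^n_trials)
}

#' Learned / not-learned verdict for a stimulus
#'
#' Maps the continuous response-pathway weight onto the binary outcome the
#' behavioral experiments report: a stimulus counts as learned when its
#' CS->CR weight reaches the threshold (default `0.1 * lambda_us`).
#'
#' @param x A `pe_trajectory` or `pe_circuit_state`.
#' @param stimulus Stimulus name; defaults to the trajectory's target.
#' @param threshold Weight threshold (> 0); defaults to the
#'   `learned_threshold` of the parameters the trajectory was run with.
#' @return `"learned"` or `"not_learned"`.
#' @examples
#' traj <- run_protocol(build_protocol("control_Y_plus"))
#' learned_verdict(traj) # "learned" (w = 0.51)
#' @export
learned_verdict <- function(x, stimulus = NULL, threshold = NULL) {
  if (inherits(x, "pe_trajectory")) {
    stimulus <- stimulus %||% attr(x, "target")
    threshold <- threshold %||% attr(x, "params")$learned_threshold
    x <- attr(x, "final_state")
  }
  stopifnot(inherits(x, "pe_circuit_state"), !is.null(stimulus),
            is.numeric(threshold), threshold > 0)
  if (!stimulus %in% names(x$w_cs_cr)) {
    abort(sprintf("unknown stimulus '%s'", stimulus))
  }
  if (x$w_cs_cr[[stimulus]] >= threshold) "learned" else "not_learned"
}

#' Export a trajectory as CSV
#'
#' Writes the tidy trajectory table (columns `phase`, `trial_index`,
#' `event_kind`, `stimulus`, `w_cs_cr`, `w_cs_da`, `delta`).
#'
#' @param traj A `pe_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pe_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
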