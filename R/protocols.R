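# A US delivered within this window of CS offset counts as paired; the
# unpaired presentations used as controls are separated by 150 s, far outside
# the window.
PAIRING_WINDOW_S <- 5
CS_DURATION_S <- 3

#' Construct a conditioning protocol
#'
#' A protocol is a phased schedule of paired and unpaired CS-US
#' presentations with timing and pharmacology, plus the identity of the
#' target stimulus whose learning is queried in the preference test. Most
#' users will want [build_protocol()], which returns the standard compound /
#' blocking / auto-blocking designs; `protocol()` is the constructor for
#' custom designs and for file round-trips.
#'
#' @param name Protocol name (token).
#' @param target Name of the stimulus whose learning is queried.
#' @param stimuli Data frame with columns `stimulus`, `modality`
#'   (`"olfactory"` or `"visual"`).
#' @param phases Data frame with columns `phase` (1-based index), `label`,
#'   `day`, `iti_s` (seconds between successive presentations),
#'   `flupentixol`, `epinastine` (logical, constant within phase), and
#'   optionally `gap_after_s` (seconds to the next same-day phase).
#' @param events Data frame with columns `phase`, `trial`, `kind`
#'   (`paired`, `cs_alone`, `us_alone`), `cs` (stimulus names joined with
#'   `"+"`, empty for `us_alone`), `us` (0 or 1), `time_s` (from phase
#'   start).
#' @param tests Optional data frame of test placement markers
#'   (columns `test`, `timing`); tests are non-plastic probes and carry no
#'   dynamical effect.
#' @param schema_version Schema version string for file IO.
#'
#' @return An object of class `pe_protocol`.
#' @seealso [build_protocol()], [validate_protocol()], [write_protocol()]
#' @export
protocol <- function(name, target, stimuli, phases, events, tests = NULL,
                     schema_version = "1.0") {
  stopifnot(is.character(name), length(name) == 1,
            is.character(target), length(target) == 1)
  stimuli <- as_tibble(stimuli)
  phases <- as_tibble(phases)
  events <- as_tibble(events)
  if (!"gap_after_s" %in% names(phases)) phases$gap_after_s <- NA_real_
  phases <- tibble(
    phase = as.integer(phases$phase),
    label = as.character(phases$label),
    day = as.integer(phases$day),
    iti_s = as.numeric(phases$iti_s),
    flupentixol = as.logical(phases$flupentixol),
    epinastine = as.logical(phases$epinastine),
    gap_after_s = as.numeric(phases$gap_after_s)
  )
  if (!"cs_duration_s" %in% names(events)) {
    events$cs_duration_s <- ifelse(nzchar(events$cs), CS_DURATION_S, 0)
  }
  events <- tibble(
    phase = as.integer(events$phase),
    trial = as.integer(events$trial),
    kind = as.character(events$kind),
    cs = as.character(events$cs),
    us = as.integer(events$us),
    time_s = as.numeric(events$time_s),
    cs_duration_s = as.numeric(events$cs_duration_s)
  )
  if (is.null(tests)) {
    tests <- tibble(test = c("pre", "post"),
                    timing = c("before training", "20 min after final training phase"))
  } else {
    tests <- tibble(test = as.character(tests$test),
                    timing = as.character(tests$timing))
  }
  structure(
    list(schema_version = schema_version, name = name, target = target,
         stimuli = tibble(stimulus = as.character(stimuli$stimulus),
                          modality = as.character(stimuli$modality)),
         phases = phases, events = events, tests = tests),
    class = "pe_protocol"
  )
}

#' @export
print.pe_protocol <- function(x, ...) {
  cat(sprintf("<pe_protocol> %s  (target: %s)\n", x$name, x$target))
  for (i in seq_len(nrow(x$phases))) {
    ph <- x$phases[i, ]
    ev <- x$events[x$events$phase == ph$phase, ]
    drug <- c(if (ph$flupentixol) "flupentixol", if (ph$epinastine) "epinastine")
    cat(sprintf("  phase %d (%s, day %d): %d events [%s]%s\n",
                ph$phase, ph$label, ph$day, nrow(ev),
                paste(unique(ev$kind), collapse = ", "),
                if (length(drug)) paste0(" + ", paste(drug, collapse = "+")) else ""))
  }
  invisible(x)
}

split_cs <- function(cs) {
  out <- strsplit(cs, "+", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

#' Names of the built-in protocols
#'
#' @return Character vector of names accepted by [build_protocol()].
#' @export
protocol_names <- function() {
  c("compound_olfactory", "compound_visual",
    "blocking_olfactory", "blocking_visual",
    "unpaired_control_olfactory", "unpaired_control_visual",
    "auto_blocking_flupentixol", "auto_blocking_control",
    "epinastine_control", "control_Y_plus")
}

paired_phase <- function(phase, label, day, cs, n, iti_s = 300,
                         flupentixol = FALSE, epinastine = FALSE,
                         gap_after_s = NA_real_) {
  list(
    phase = tibble(phase = phase, label = label, day = day, iti_s = iti_s,
                   flupentixol = flupentixol, epinastine = epinastine,
                   gap_after_s = gap_after_s),
    events = tibble(phase = phase, trial = seq_len(n), kind = "paired",
                    cs = cs, us = 1L, time_s = (seq_len(n) - 1) * iti_s,
                    cs_duration_s = CS_DURATION_S)
  )
}

# Unpaired presentations: CS and US alternate, each presentation iti_s apart,
# so the CS-US separation equals iti_s (150 s = 2.5 min by default).
unpaired_phase <- function(phase, label, day, cs, n, iti_s = 150,
                           flupentixol = FALSE, epinastine = FALSE,
                           gap_after_s = NA_real_) {
  k <- seq_len(n)
  ev <- dplyr::bind_rows(
    tibble(phase = phase, trial = k, kind = "cs_alone", cs = cs, us = 0L,
           time_s = (k - 1) * 2 * iti_s, cs_duration_s = CS_DURATION_S),
    tibble(phase = phase, trial = k, kind = "us_alone", cs = "", us = 1L,
           time_s = (k - 1) * 2 * iti_s + iti_s, cs_duration_s = 0)
  )
  list(
    phase = tibble(phase = phase, label = label, day = day, iti_s = iti_s,
                   flupentixol = flupentixol, epinastine = epinastine,
                   gap_after_s = gap_after_s),
    events = dplyr::arrange(ev, .data$time_s)
  )
}

assemble_protocol <- function(name, target, stimuli, parts) {
  protocol(
    name = name, target = target, stimuli = stimuli,
    phases = dplyr::bind_rows(lapply(parts, `[[`, "phase")),
    events = dplyr::bind_rows(lapply(parts, `[[`, "events"))
  )
}

#' Build a named experimental protocol
#'
#' Returns the standard designs of the cricket compound-conditioning,
#' blocking and auto-blocking experiments with their literal trial counts,
#' inter-trial intervals and pharmacology:
#'
#' * `compound_olfactory`: 2 odor+pattern compound pairings (target odor);
#'   its single-CS control is `control_Y_plus` (2 odor pairings).
#' * `compound_visual`: 8 compound pairings (target pattern).
#' * `blocking_olfactory`: 8 pattern pairings, then (20 min later) 2 compound
#'   pairings; target odor.
#' * `blocking_visual`: 2 odor pairings, then 8 compound pairings; target
#'   pattern.
#' * `unpaired_control_olfactory` / `unpaired_control_visual`: phase 1
#'   replaced by unpaired CS / US presentations (150 s apart).
#' * `auto_blocking_flupentixol`: day 1, 6 odor pairings under flupentixol
#'   (ITI 5 min); day 2, drug-free, 2 odor pairings.
#' * `auto_blocking_control`: day 1, 6 unpaired odor / US presentations under
#'   flupentixol (ITI 2.5 min); day 2, 2 odor pairings.
#' * `epinastine_control`: as `auto_blocking_flupentixol` but with the
#'   octopamine-receptor antagonist epinastine on day 1.
#' * `control_Y_plus`: 2 odor pairings (plain acquisition).
#'
#' @param name One of [protocol_names()].
#' @param conditioned_odor Which odor serves as the conditioned stimulus
#'   (`"maple"`, the default, or `"vanilla"`); the other odor is the test
#'   control.
#' @return A `pe_protocol` object (valid by construction; see
#'   [validate_protocol()]).
#' @examples
#' build_protocol("blocking_olfactory")
#' @export
build_protocol <- function(name, conditioned_odor = c("maple", "vanilla")) {
  conditioned_odor <- match.arg(conditioned_odor)
  if (!name %in% protocol_names()) {
    abort(sprintf("Unknown protocol '%s'. Valid names: %s.",
                  name, paste(protocol_names(), collapse = ", ")))
  }
  odor <- paste0("odor_", conditioned_odor)
  pat <- "pattern_white_center"
  both <- paste(odor, pat, sep = "+")
  stim_both <- tibble(stimulus = c(odor, pat),
                      modality = c("olfactory", "visual"))
  stim_odor <- stim_both[1, ]

  parts <- switch(
    name,
    compound_olfactory = list(
      stimuli = stim_both, target = odor,
      list(paired_phase(1L, "compound_training", 1L, both, 2L))
    ),
    compound_visual = list(
      stimuli = stim_both, target = pat,
      list(paired_phase(1L, "compound_training", 1L, both, 8L))
    ),
    blocking_olfactory = list(
      stimuli = stim_both, target = odor,
      list(paired_phase(1L, "pattern_training", 1L, pat, 8L, gap_after_s = 1200),
           paired_phase(2L, "compound_training", 1L, both, 2L))
    ),
    blocking_visual = list(
      stimuli = stim_both, target = pat,
      list(paired_phase(1L, "odor_training", 1L, odor, 2L, gap_after_s = 1200),
           paired_phase(2L, "compound_training", 1L, both, 8L))
    ),
    unpaired_control_olfactory = list(
      stimuli = stim_both, target = odor,
      list(unpaired_phase(1L, "pattern_unpaired", 1L, pat, 8L, gap_after_s = 1200),
           paired_phase(2L, "compound_training", 1L, both, 2L))
    ),
    unpaired_control_visual = list(
      stimuli = stim_both, target = pat,
      list(unpaired_phase(1L, "odor_unpaired", 1L, odor, 2L, gap_after_s = 1200),
           paired_phase(2L, "compound_training", 1L, both, 8L))
    ),
    auto_blocking_flupentixol = list(
      stimuli = stim_odor, target = odor,
      list(paired_phase(1L, "odor_training_flupentixol", 1L, odor, 6L,
                        flupentixol = TRUE),
           paired_phase(2L, "odor_training", 2L, odor, 2L))
    ),
    auto_blocking_control = list(
      stimuli = stim_odor, target = odor,
      list(unpaired_phase(1L, "odor_unpaired_flupentixol", 1L, odor, 6L,
                          flupentixol = TRUE),
           paired_phase(2L, "odor_training", 2L, odor, 2L))
    ),
    epinastine_control = list(
      stimuli = stim_odor, target = odor,
      list(paired_phase(1L, "odor_training_epinastine", 1L, odor, 6L,
                        epinastine = TRUE),
           paired_phase(2L, "odor_training", 2L, odor, 2L))
    ),
    control_Y_plus = list(
      stimuli = stim_odor, target = odor,
      list(paired_phase(1L, "odor_training", 1L, odor, 2L))
    )
  )
  assemble_protocol(name, parts$target, parts$stimuli, parts[[3]])
}

#' Validate a protocol
#'
#' Checks the structural invariants a protocol must satisfy before it can be
#' simulated: known stimuli, positive inter-trial intervals, phases on
#' non-decreasing days, events ordered in time, event-kind consistency
#' (paired events carry a CS and the US; `cs_alone` events no US; `us_alone`
#' events no CS), and the pairing-window rule (a `cs_alone` and a `us_alone`
#' event closer than 5 s after CS offset should have been encoded as a
#' single paired event).
#'
#' @param p A `pe_protocol` object.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_protocol <- function(p) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(p, "pe_protocol")) return("not a pe_protocol object")
  if (anyDuplicated(p$stimuli$stimulus)) add("stimulus names must be unique")
  if (!all(p$stimuli$modality %in% c("olfactory", "visual"))) {
    add("modality must be 'olfactory' or 'visual'")
  }
  if (!p$target %in% p$stimuli$stimulus) add("target must be a declared stimulus")
  if (any(p$phases$iti_s <= 0)) add("iti_s must be positive")
  if (is.unsorted(p$phases$day)) add("phases must be on non-decreasing days")
  if (!identical(sort(unique(p$events$phase)), sort(p$phases$phase))) {
    add("every phase must have events and every event a declared phase")
  }
  cs_sets <- split_cs(p$events$cs)
  used <- unique(unlist(cs_sets))
  if (!all(used %in% p$stimuli$stimulus)) {
    add(sprintf("unknown stimulus in events: %s",
                paste(setdiff(used, p$stimuli$stimulus), collapse = ", ")))
  }
  if (!p$target %in% used) add("target never presented in any phase")
  for (ph in p$phases$phase) {
    ev <- p$events[p$events$phase == ph, ]
    sets <- split_cs(ev$cs)
    if (is.unsorted(ev$time_s)) add(sprintf("phase %d: events not ordered by time_s", ph))
    bad_kind <- !ev$kind %in% c("paired", "cs_alone", "us_alone")
    if (any(bad_kind)) add(sprintf("phase %d: unknown event kind", ph))
    n_cs <- lengths(sets)
    if (any(ev$kind == "paired" & (n_cs == 0 | ev$us != 1))) {
      add(sprintf("phase %d: paired events need a nonempty CS set and us = 1", ph))
    }
    if (any(ev$kind == "cs_alone" & (n_cs == 0 | ev$us != 0))) {
      add(sprintf("phase %d: cs_alone events need a CS and us = 0", ph))
    }
    if (any(ev$kind == "us_alone" & (n_cs > 0 | ev$us != 1))) {
      add(sprintf("phase %d: us_alone events must have no CS and us = 1", ph))
    }
    cs_off <- ev$time_s[ev$kind == "cs_alone"] + ev$cs_duration_s[ev$kind == "cs_alone"]
    us_t <- ev$time_s[ev$kind == "us_alone"]
    if (length(cs_off) && length(us_t)) {
      gaps <- outer(us_t, cs_off, `-`)
      if (any(gaps >= 0 & gaps <= PAIRING_WINDOW_S)) {
        add(sprintf(
          "phase %d: events within the %d s pairing window must be a paired event",
          ph, PAIRING_WINDOW_S))
      }
    }
  }
  v
}

#' Read and write protocols as YAML or JSON
#'
#' Protocols round-trip losslessly through a versioned document schema
#' (`schema_version` field), so designs can be archived, edited by hand and
#' shared. `read_protocol()` reconstructs the canonical `pe_protocol`
#' object and errors with the offending path on schema violations.
#'
#' @param p A `pe_protocol` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a `pe_protocol`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_protocol(build_protocol("blocking_olfactory"), f)
#' read_protocol(f)
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "pe_protocol"))
  doc <- list(
    schema_version = p$schema_version,
    name = p$name,
    target = p$target,
    stimuli = lapply(seq_len(nrow(p$stimuli)), function(i) as.list(p$stimuli[i, ])),
    phases = lapply(seq_len(nrow(p$phases)), function(i) {
      row <- as.list(p$phases[i, ])
      if (is.na(row$gap_after_s)) row$gap_after_s <- NULL
      row
    }),
    events = lapply(seq_len(nrow(p$events)), function(i) as.list(p$events[i, ])),
    tests = lapply(seq_len(nrow(p$tests)), function(i) as.list(p$tests[i, ]))
  )
  write_doc(doc, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  doc <- read_doc(path)
  for (field in c("name", "target", "stimuli", "phases", "events")) {
    if (is.null(doc[[field]])) {
      abort(sprintf("Protocol document parse error at \"/%s\": field missing.", field))
    }
  }
  rowbind <- function(rows, field) {
    tryCatch(
      dplyr::bind_rows(lapply(rows, function(r) as_tibble(r))),
      error = function(e) abort(sprintf(
        "Protocol document parse error at \"/%s\": %s", field, conditionMessage(e)))
    )
  }
  protocol(
    name = doc$name,
    target = doc$target,
    stimuli = rowbind(doc$stimuli, "stimuli"),
    phases = rowbind(doc$phases, "phases"),
    events = rowbind(doc$events, "events"),
    tests = if (!is.null(doc$tests)) rowbind(doc$tests, "tests"),
    schema_version = doc$schema_version %||% "1.0"
  )
}
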