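#' Theory identifiers
#'
#' The registry of the four accounts of blocking that can be run against a
#' protocol: the two-pathway prediction-error circuit (`pe_circuit`), the
#' single-pathway summed-error Rescorla-Wagner model (`rescorla_wagner`),
#' an attentional model (`attentional`), and a comparator / retrieval model
#' (`comparator`).
#'
#' @return Character vector of theory names.
#' @export
theory_names <- function() {
  c("pe_circuit", "rescorla_wagner", "attentional", "comparator")
}

#' Parameters for the competing learning theories
#'
#' Minimal literature-standard instantiations are used; the discrimination
#' argument depends only on the structural feature all of them share —
#' cue competition between the blocked and blocking stimulus — not on the
#' particular variant.
#'
#' * Rescorla-Wagner: `dV_i = alpha * s_i * (lambda_us * us - sum_j V_j)`,
#'   summed over the presented set, rectified at zero.
#' * Attentional (default `attentional_error = "summed"`): Mackintosh-style
#'   attention bookkeeping on a common-error base,
#'   `dV_i = theta * attention_i * s_i * (lambda_us * us - sum_j V_j)`;
#'   on compound trials the attention of the relatively better predictor
#'   rises by `gamma` and that of worse predictors falls by `gamma`,
#'   clipped to `[alpha_min, 1]`. `attentional_error = "separate"` switches
#'   to the textbook separate-error Mackintosh rule
#'   `dV_i = theta * attention_i * s_i * (lambda_us * us - V_i)`; see the
#'   methods vignette for why the hybrid is the default.
#' * Comparator: acquisition by a separate-error rule; within-compound
#'   associations `W_ij` move toward 1 by `within_rate` on co-presentation;
#'   responding is discounted at retrieval (see [comparator_response()]).
#'
#' Under all three single-pathway theories flupentixol zeroes every
#' associative change (there is no spared prediction trace), while
#' attention bookkeeping continues; epinastine has no effect on aversive
#' learning.
#'
#' @param alpha Associative learning rate in (0, 1].
#' @param lambda_us US asymptote (> 0).
#' @param salience Named saliences as in [learning_params()].
#' @param theta Attentional-rule gain.
#' @param gamma Attention step per compound trial.
#' @param alpha_min Lower clip for attention.
#' @param attention0 Initial attention; defaults to `alpha` so that a lone
#'   CS follows the same delta rule under every theory.
#' @param k Comparator gain in \[0, 1\] (1 = full discounting).
#' @param within_rate Per-trial approach rate of within-compound
#'   associations toward 1.
#' @param rectify_error Floor prediction errors at zero (no extinction is
#'   probed in these designs).
#' @param attentional_error `"summed"` (default) or `"separate"`.
#' @return An object of class `pe_theory_params`.
#' @export
theory_params <- function(alpha = 0.3,
                          lambda_us = 1,
                          salience = c(olfactory = 1, visual = 0.28),
                          theta = 1,
                          gamma = 0.05,
                          alpha_min = 0.05,
                          attention0 = NULL,
                          k = 1,
                          within_rate = 0.5,
                          rectify_error = TRUE,
                          attentional_error = c("summed", "separate")) {
  attentional_error <- match.arg(attentional_error)
  attention0 <- attention0 %||% alpha
  stopifnot(alpha > 0, alpha <= 1, lambda_us > 0,
            is.numeric(salience), !is.null(names(salience)),
            theta > 0, gamma >= 0, alpha_min > 0, alpha_min <= 1,
            attention0 >= alpha_min, attention0 <= 1,
            k >= 0, k <= 1, within_rate >= 0, within_rate <= 1,
            is.logical(rectify_error))
  structure(
    list(alpha = alpha, lambda_us = lambda_us, salience = salience,
         theta = theta, gamma = gamma, alpha_min = alpha_min,
         attention0 = attention0, k = k, within_rate = within_rate,
         rectify_error = rectify_error, attentional_error = attentional_error),
    class = "pe_theory_params"
  )
}

new_theory_state <- function(stimuli, params) {
  s <- stimuli$stimulus
  list(
    V = setNames(rep(0, length(s)), s),
    attention = setNames(rep(params$attention0, length(s)), s),
    W = matrix(0, length(s), length(s), dimnames = list(s, s)),
    salience = setNames(
      stimulus_salience(params, s, stimuli$modality), s)
  )
}

rectify <- function(x, on) if (on) pmax(0, x) else x

# One trial under one of the three single-pathway theories. `cs_set` is a
# character vector (empty for us_alone events).
theory_step <- function(theory, st, cs_set, us, pharm, params) {
  if (!length(cs_set)) return(st)
  lam <- params$lambda_us * us
  if (theory == "attentional" && length(cs_set) >= 2) {
    # relative-predictiveness bookkeeping (pre-trial V); continues under drug
    for (i in cs_set) {
      own <- abs(lam - st$V[[i]])
      others <- abs(lam - sum(st$V[setdiff(cs_set, i)]))
      if (own < others) {
        st$attention[[i]] <- min(1, st$attention[[i]] + params$gamma)
      } else if (own > others) {
        st$attention[[i]] <- max(params$alpha_min, st$attention[[i]] - params$gamma)
      }
    }
  }
  if (pharm$flupentixol_active) return(st)  # all associative change blocked
  s_i <- st$salience[cs_set]
  summed_err <- rectify(lam - sum(st$V[cs_set]), params$rectify_error)
  dV <- switch(
    theory,
    rescorla_wagner = params$alpha * s_i * summed_err,
    attentional = if (params$attentional_error == "summed") {
      params$theta * st$attention[cs_set] * s_i * summed_err
    } else {
      params$theta * st$attention[cs_set] * s_i *
        rectify(lam - st$V[cs_set], params$rectify_error)
    },
    comparator = params$alpha * s_i * rectify(lam - st$V[cs_set], params$rectify_error)
  )
  st$V[cs_set] <- st$V[cs_set] + dV
  if (theory == "comparator" && length(cs_set) >= 2) {
    for (i in cs_set) for (j in setdiff(cs_set, i)) {
      st$W[i, j] <- st$W[i, j] + params$within_rate * (1 - st$W[i, j])
    }
  }
  st
}

#' Run a competing theory over a protocol
#'
#' Iterates a protocol's events through one of the single-pathway theories
#' (`rescorla_wagner`, `attentional`, `comparator`). For the two-pathway
#' circuit use [run_protocol()].
#'
#' @param theory One of `"rescorla_wagner"`, `"attentional"`,
#'   `"comparator"`.
#' @param protocol A `pe_protocol`.
#' @param params A [theory_params()] object.
#' @return An object of class `pe_theory_run`: a list with the theory name,
#'   the final state (`V`, `attention`, `W`), the protocol target, the
#'   target's `response` strength (comparator-discounted where applicable),
#'   and `trajectory`, a tibble of `V` after every event.
#' @examples
#' run_theory("rescorla_wagner", build_protocol("control_Y_plus"))$response
#' @export
run_theory <- function(theory, protocol, params = theory_params()) {
  theory <- match.arg(theory, setdiff(theory_names(), "pe_circuit"))
  stopifnot(inherits(protocol, "pe_protocol"))
  violations <- validate_protocol(protocol)
  if (length(violations)) {
    abort(paste0("invalid protocol: ", paste(violations, collapse = "; ")))
  }
  st <- new_theory_state(protocol$stimuli, params)
  phases <- protocol$phases[order(protocol$phases$phase), ]
  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(phases))) {
    ph <- phases[i, ]
    pharm <- pharmacology_state(ph$flupentixol, ph$epinastine)
    ev <- protocol$events[protocol$events$phase == ph$phase, ]
    ev <- ev[order(ev$time_s), ]
    for (j in seq_len(nrow(ev))) {
      cs_set <- split_cs(ev$cs[j])[[1]]
      st <- theory_step(theory, st, cs_set, ev$us[j], pharm, params)
      idx <- idx + 1L
      rows[[idx]] <- tibble(event_index = idx, phase = ph$phase,
                            stimulus = names(st$V), V = unname(st$V))
    }
  }
  response <- if (theory == "comparator") {
    comparator_response(st$V, st$W, protocol$target, params$k)
  } else {
    unname(st$V[protocol$target])
  }
  structure(
    list(theory = theory, final = st[c("V", "attention", "W")],
         target = protocol$target, response = response,
         trajectory = dplyr::bind_rows(rows), params = params),
    class = "pe_theory_run"
  )
}

#' Comparator (retrieval-theory) response strength
#'
#' Responding to a target is discounted at retrieval by its strongest
#' within-compound associate:
#' `response = max(0, V[target] - k * max_x(W[target, x] * V[x]))`.
#' Blocking thus appears as a performance effect — the target's own
#' association is intact but out-competed at test — which is exactly why
#' the account has no way to produce auto-blocking, where no competitor
#' exists.
#'
#' @param V Named numeric vector of associative strengths.
#' @param W Square within-compound association matrix (rows/cols named like
#'   `V`), or `NULL` for no within-compound partners.
#' @param target Stimulus name.
#' @param k Comparator gain in \[0, 1\].
#' @return Non-negative response strength.
#' @examples
#' comparator_response(c(Y = 0.5), NULL, "Y")                 # 0.5
#' comparator_response(c(Y = 0.5, X = 1),
#'                     matrix(c(0, 1, 1, 0), 2, 2,
#'                            dimnames = list(c("Y", "X"), c("Y", "X"))),
#'                     "Y", k = 1)                            # 0
#' @export
comparator_response <- function(V, W = NULL, target, k = 1) {
  if (!target %in% names(V)) abort(sprintf("unknown target '%s'", target))
  discount <- 0
  if (!is.null(W)) {
    partners <- setdiff(colnames(W), target)
    if (length(partners)) {
      discount <- max(W[target, partners] * V[partners], 0)
    }
  }
  max(0, unname(V[target]) - k * discount)
}

#' Theory x protocol discrimination table
#'
#' Runs every requested theory on every protocol, reads out the target
#' stimulus's response strength (the CS->CR weight for the circuit, `V` for
#' Rescorla-Wagner and the attentional model, the retrieval-discounted
#' response for the comparator), and applies the learned threshold. The
#' auto-blocking rows are the discriminating ones: every account reproduces
#' blocking, but only the two-pathway circuit — whose US-prediction pathway
#' keeps learning under the dopamine antagonist — withholds learning when
#' the same training is repeated drug-free.
#'
#' @param protocols List of `pe_protocol` objects or character names for
#'   [build_protocol()].
#' @param theories Character vector from [theory_names()].
#' @param circuit_params A [learning_params()] for the `pe_circuit` rows.
#' @param params A [theory_params()] for the other theories.
#' @param threshold Learned threshold; defaults to
#'   `circuit_params$learned_threshold`.
#' @return A tibble with columns `theory`, `protocol`, `target`,
#'   `response`, `verdict` (`"learned"` / `"not_learned"`), one row per
#'   theory x protocol pair; row order follows the inputs, but the table
#'   contents are order-invariant.
#' @examples
#' discriminate_theories(
#'   c("control_Y_plus", "auto_blocking_flupentixol"),
#'   circuit_params = learning_params(salience = c(olfactory = 1, visual = 1)),
#'   params = theory_params(salience = c(olfactory = 1, visual = 1)))
#' @export
discriminate_theories <- function(protocols,
                                  theories = theory_names(),
                                  circuit_params = learning_params(),
                                  params = theory_params(),
                                  threshold = NULL) {
  if (length(protocols) == 0 || length(theories) == 0) {
    abort("need at least one protocol and one theory")
  }
  stopifnot(all(theories %in% theory_names()))
  threshold <- threshold %||% circuit_params$learned_threshold
  if (is.character(protocols)) protocols <- lapply(protocols, build_protocol)
  purrr::map_dfr(theories, function(th) {
    purrr::map_dfr(protocols, function(p) {
      response <- if (th == "pe_circuit") {
        traj <- run_protocol(p, circuit_params)
        final_weights(traj)$w_cs_cr[final_weights(traj)$stimulus == p$target]
      } else {
        run_theory(th, p, params)$response
      }
      tibble(theory = th, protocol = p$name, target = p$target,
             response = response,
             verdict = if (response >= threshold) "learned" else "not_learned")
    })
  })
}
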