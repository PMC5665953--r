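#' Learning parameters for the prediction-error circuit
#'
#' Bundles the delta-rule constants shared by the two modifiable synapse
#' populations of the circuit: the US asymptote `lambda_us`, per-pathway
#' learning rates (`alpha_cr` for the response pathway, `alpha_da` for the
#' US-prediction pathway), stimulus saliences, and the error-rectification
#' flag.
#'
#' Saliences are looked up by stimulus name first and then by modality
#' (`olfactory`, `visual`), so `salience = c(olfactory = 1, visual = 0.28)`
#' applies to every odor and every pattern, while
#' `salience = c(odor_maple = 0.9, visual = 0.28)` pins one stimulus. The
#' default visual salience 0.28 solves `(1 - alpha*s_p)^8 = (1 - alpha*s_o)^2`
#' at `alpha = 0.3`, so that 8-trial visual acquisition reaches the same
#' weight as 2-trial olfactory acquisition, matching the different trial
#' numbers the two modalities require behaviorally.
#'
#' @param lambda_us US asymptote (dimensionless, > 0). Magnitude of the fully
#'   surprising salt-water US.
#' @param alpha_cr Learning rate of the CS->CR (response) pathway, in (0, 1].
#' @param alpha_da Learning rate of the CS->DA (US-prediction) pathway, in
#'   (0, 1].
#' @param salience Named numeric vector of stimulus saliences in (0, 1],
#'   keyed by stimulus name or modality. Unlisted stimuli default to 1.
#' @param rectify_error If `TRUE` (default) the prediction-error signal is
#'   floored at zero: dopamine firing rates cannot go below baseline, and the
#'   protocols modeled here never probe extinction.
#' @param learned_threshold Weight above which a stimulus counts as learned
#'   for verdict purposes; defaults to `0.1 * lambda_us`.
#'
#' @return An object of class `pe_learning_params` (a validated list).
#' @seealso [run_protocol()], [learned_verdict()]
#' @examples
#' learning_params()
#' learning_params(salience = c(olfactory = 1, visual = 1))
#' @export
learning_params <- function(lambda_us = 1,
                            alpha_cr = 0.3,
                            alpha_da = 0.3,
                            salience = c(olfactory = 1, visual = 0.28),
                            rectify_error = TRUE,
                            learned_threshold = 0.1 * lambda_us) {
  stopifnot(
    is.numeric(lambda_us), length(lambda_us) == 1, lambda_us > 0,
    is.numeric(alpha_cr), length(alpha_cr) == 1, alpha_cr > 0, alpha_cr <= 1,
    is.numeric(alpha_da), length(alpha_da) == 1, alpha_da > 0, alpha_da <= 1,
    is.numeric(salience), !is.null(names(salience)), all(nzchar(names(salience))),
    all(salience > 0), all(salience <= 1),
    is.logical(rectify_error), length(rectify_error) == 1,
    is.numeric(learned_threshold), length(learned_threshold) == 1,
    learned_threshold > 0
  )
  # no-overshoot guarantee for a lone CS trained from zero
  if (max(alpha_cr, alpha_da) * max(salience) > 1 + 1e-12) {
    abort("alpha * salience must not exceed 1 for any stimulus.")
  }
  structure(
    list(
      lambda_us = lambda_us,
      alpha_cr = alpha_cr,
      alpha_da = alpha_da,
      salience = salience,
      rectify_error = rectify_error,
      learned_threshold = learned_threshold
    ),
    class = "pe_learning_params"
  )
}

#' @export
print.pe_learning_params <- function(x, ...) {
  cat("<pe_learning_params>\n")
  cat(sprintf("  lambda_us: %g   alpha_cr: %g   alpha_da: %g\n",
              x$lambda_us, x$alpha_cr, x$alpha_da))
  cat("  salience:", paste(sprintf("%s=%g", names(x$salience), x$salience),
                           collapse = ", "), "\n")
  cat(sprintf("  rectify_error: %s   learned_threshold: %g\n",
              x$rectify_error, x$learned_threshold))
  invisible(x)
}

#' Look up the salience of a stimulus
#'
#' Stimulus-name entries take precedence over modality entries; stimuli with
#' neither get salience 1.
#'
#' @param params A [learning_params()] object (or any list with a named
#'   `salience` vector).
#' @param stimulus Character vector of stimulus names.
#' @param modality Character vector of modalities, recycled against
#'   `stimulus`.
#' @return Numeric vector of saliences.
#' @keywords internal
stimulus_salience <- function(params, stimulus, modality) {
  s <- params$salience
  out <- rep(1, length(stimulus))
  hit_mod <- modality %in% names(s)
  out[hit_mod] <- s[modality[hit_mod]]
  hit_name <- stimulus %in% names(s)
  out[hit_name] <- s[stimulus[hit_name]]
  unname(out)
}

#' Generative parameters for synthetic preference-test data
#'
#' Defines the study conditions the synthetic two-odor preference test is
#' drawn under: group size, the logit-scale baseline and aversion gain, the
#' per-animal random-intercept SD, and the distribution of total visiting
#' time within the 4-minute test.
#'
#' The generative model for one animal i in one test is
#' `seconds_conditioned ~ Binomial(T_i, plogis(theta0 + u_i - theta1 * w))`
#' with `u_i ~ Normal(0, sigma_u^2)` shared between the pre and post tests,
#' `w` the animal's current CS->CR weight for the conditioned stimulus
#' (zero at the pre test), and `T_i` the total visiting time drawn from
#' `visit_time_model` (independently per test, capped at the 240 s test
#' duration). Records with `T_i < 10` s fail the retention filter.
#'
#' Default `visit_time_model` is lognormal with median 30 s and sdlog 1.1,
#' which yields a below-10-s rejection rate of about 15%, matching the
#' fraction of poorly motivated animals the assay discards. Defaults for
#' `theta1` and `n_per_group` come from an a-priori power analysis: at
#' `theta1 = 0.7` and 40 animals/group the within-group Wald test detects
#' acquisition-scale weights (0.4-0.5) with ~98% power, while weights well
#' below the learned threshold (the residuals left by blocking and
#' auto-blocking) stay near the nominal false-positive rate — mirroring the
#' qualitative resolution of the real assay.
#'
#' @param n_per_group Animals per training group (>= 2).
#' @param theta0 Baseline log-odds of visiting the conditioned source
#'   (0 = no innate bias between maple and vanilla).
#' @param theta1 Aversion gain: drop in log-odds per unit CS->CR weight
#'   (>= 0).
#' @param sigma_u SD of the per-animal random intercept on the logit scale
#'   (>= 0).
#' @param visit_time_model List describing the total-visit-time
#'   distribution. Currently `list(dist = "lognormal", meanlog, sdlog)`.
#' @param test_duration_s Test length in seconds (240 = 4 min).
#' @param retention_min_s Minimum total visiting time to retain a record
#'   (strictly-less rejection; exactly 10 s is retained).
#'
#' @return An object of class `pe_behavior_params`.
#' @seealso [generate_preferences()], [apply_retention_filter()]
#' @examples
#' behavior_params(n_per_group = 20)
#' @export
behavior_params <- function(n_per_group = 40,
                            theta0 = 0,
                            theta1 = 0.7,
                            sigma_u = 0.5,
                            visit_time_model = list(dist = "lognormal",
                                                    meanlog = log(30),
                                                    sdlog = 1.1),
                            test_duration_s = 240,
                            retention_min_s = 10) {
  stopifnot(
    is.numeric(n_per_group), length(n_per_group) == 1, n_per_group >= 2,
    n_per_group == round(n_per_group),
    is.numeric(theta0), length(theta0) == 1,
    is.numeric(theta1), length(theta1) == 1, theta1 >= 0,
    is.numeric(sigma_u), length(sigma_u) == 1, sigma_u >= 0,
    is.list(visit_time_model), !is.null(visit_time_model$dist),
    is.numeric(test_duration_s), test_duration_s > 0,
    is.numeric(retention_min_s), retention_min_s >= 0
  )
  if (!identical(visit_time_model$dist, "lognormal")) {
    abort(sprintf("Unknown visit_time_model dist '%s' (supported: 'lognormal').",
                  visit_time_model$dist))
  }
  if (!is.numeric(visit_time_model$meanlog) || !is.numeric(visit_time_model$sdlog) ||
      visit_time_model$sdlog <= 0) {
    abort("lognormal visit_time_model needs numeric 'meanlog' and positive 'sdlog'.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      theta0 = theta0,
      theta1 = theta1,
      sigma_u = sigma_u,
      visit_time_model = visit_time_model,
      test_duration_s = test_duration_s,
      retention_min_s = retention_min_s
    ),
    class = "pe_behavior_params"
  )
}

#' @export
print.pe_behavior_params <- function(x, ...) {
  cat("<pe_behavior_params>\n")
  cat(sprintf("  n_per_group: %d   theta0: %g   theta1: %g   sigma_u: %g\n",
              x$n_per_group, x$theta0, x$theta1, x$sigma_u))
  cat(sprintf("  visit time: %s(meanlog=%.3f, sdlog=%.2f), capped at %g s; retain >= %g s\n",
              x$visit_time_model$dist, x$visit_time_model$meanlog,
              x$visit_time_model$sdlog, x$test_duration_s, x$retention_min_s))
  invisible(x)
}

#' Read or write a parameter file
#'
#' Round-trips [learning_params()] and [behavior_params()] through a single
#' YAML or JSON document, so a run's conditions can be archived alongside its
#' outputs.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param learning A `pe_learning_params` object.
#' @param behavior A `pe_behavior_params` object.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   `list(learning, behavior)` with both objects reconstructed.
#' @export
write_params <- function(path, learning = learning_params(),
                         behavior = behavior_params()) {
  doc <- list(
    learning = unclass(learning),
    behavior = unclass(behavior)
  )
  doc$learning$salience <- as.list(learning$salience)
  write_doc(doc, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- read_doc(path)
  lp <- doc$learning
  lp$salience <- unlist(lp$salience)
  list(
    learning = do.call(learning_params, lp),
    behavior = do.call(behavior_params, doc$behavior)
  )
}

# shared YAML/JSON document IO ------------------------------------------------

write_doc <- function(doc, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    abort(sprintf("Unsupported parameter file extension '.%s' (use yaml or json).", ext))
  }
  invisible(path)
}

read_doc <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    abort(sprintf("Unsupported parameter file extension '.%s' (use yaml or json).", ext))
  }
}
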