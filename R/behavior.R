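# Run code under a temporary RNG state so generation is reproducible from an
# explicit seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Probability of visiting the conditioned odor source
#'
#' The generative inverse of the binomial logit analysis model: each second
#' of visiting is a Bernoulli choice of the conditioned source with
#' probability `plogis(theta0 + u_i - theta1 * w)`, where `u_i` is the
#' animal's random intercept and `w` the CS->CR weight of the conditioned
#' stimulus. Conditioning (`w > 0`, `theta1 > 0`) pushes the probability
#' below the animal's baseline — learned avoidance.
#'
#' @param w_cs_cr CS->CR weight of the conditioned stimulus (0 before
#'   training).
#' @param u_i Per-animal random intercept (log-odds).
#' @param params A [behavior_params()] object.
#' @return Probability in (0, 1); vectorized over the inputs.
#' @examples
#' preference_probability(0, 0, behavior_params())            # 0.5
#' preference_probability(0.51, 0, behavior_params(theta1 = 2)) # ~0.265
#' @export
preference_probability <- function(w_cs_cr, u_i, params = behavior_params()) {
  plogis(params$theta0 + u_i - params$theta1 * w_cs_cr)
}

#' Generate synthetic preference-test records
#'
#' Emulates the cricket two-odor preference test in a pre/post x group
#' design. Per animal: a random intercept `u_i ~ Normal(0, sigma_u^2)`
#' shared between its pre and post tests; per test: a total visiting time
#' `T` drawn from the visit-time model (rounded to whole seconds, capped at
#' the 240 s test duration) and `seconds_conditioned ~ Binomial(T, p)` with
#' `p` from [preference_probability()] — the pre test uses weight 0, the
#' post test the group's trained CS->CR weight. Records with `T` below 10 s
#' carry `retained = FALSE` (the poorly-motivated-animal filter).
#'
#' @param group_weights Data frame with columns `group` and `w_cs_cr`
#'   (post-training response-pathway weight of the conditioned stimulus in
#'   that group), e.g. assembled from [final_weights()] of per-group
#'   simulations.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A tibble with one row per animal x test: `animal_id`, `group`,
#'   `test` (`"pre"`/`"post"`), `seconds_conditioned`, `seconds_control`,
#'   `test_duration_s`, `retained`, `relative_preference`.
#' @examples
#' gw <- tibble::tibble(group = c("control", "blocking"),
#'                      w_cs_cr = c(0.51, 0.024))
#' generate_preferences(gw, behavior_params(n_per_group = 5), seed = 1)
#' @export
generate_preferences <- function(group_weights, params = behavior_params(),
                                 seed) {
  stopifnot(is.data.frame(group_weights),
            all(c("group", "w_cs_cr") %in% names(group_weights)),
            !anyDuplicated(group_weights$group),
            all(group_weights$w_cs_cr >= 0),
            is.numeric(seed), length(seed) == 1)
  vm <- params$visit_time_model
  n <- params$n_per_group
  with_local_seed(seed, {
    recs <- purrr::map_dfr(seq_len(nrow(group_weights)), function(g) {
      grp <- group_weights$group[g]
      w_post <- group_weights$w_cs_cr[g]
      u <- rnorm(n, 0, params$sigma_u)
      purrr::map_dfr(c(pre = 0, post = w_post), function(w) {
        total <- pmin(round(rlnorm(n, vm$meanlog, vm$sdlog)),
                      params$test_duration_s)
        p <- preference_probability(w, u, params)
        sc <- rbinom(n, total, p)
        tibble(
          animal_id = sprintf("%s_%03d", grp, seq_len(n)),
          group = grp,
          seconds_conditioned = as.integer(sc),
          seconds_control = as.integer(total - sc),
          test_duration_s = params$test_duration_s
        )
      }, .id = "test")
    })
    total <- recs$seconds_conditioned + recs$seconds_control
    recs$retained <- total >= params$retention_min_s
    recs$relative_preference <- ifelse(total > 0,
                                       recs$seconds_conditioned / total, NA_real_)
    dplyr::select(recs, "animal_id", "group", "test", dplyr::everything())
  })
}

#' Retention filter for preference-test records
#'
#' Animals whose total visiting time is below 10 s are considered
#' unmotivated and their record is rejected; exactly 10 s is retained (the
#' rule is strictly-less-than). `apply_retention_filter()` returns the
#' retained records with the per-test rejection counts attached as the
#' `"rejections"` attribute; [retention_counts()] returns the counts alone.
#'
#' @param records A tibble as from [generate_preferences()].
#' @param min_total_s Retention threshold in seconds (default 10).
#' @return The retained records (tibble); attribute `"rejections"` holds the
#'   per-test counts.
#' @examples
#' gw <- tibble::tibble(group = "g", w_cs_cr = 0)
#' recs <- generate_preferences(gw, behavior_params(n_per_group = 20), seed = 2)
#' nrow(apply_retention_filter(recs))
#' retention_counts(recs)
#' @export
apply_retention_filter <- function(records, min_total_s = 10) {
  if (nrow(records) == 0) {
    out <- records
    attr(out, "rejections") <- tibble(test = character(), n_records = integer(),
                                      n_rejected = integer(),
                                      rejection_rate = numeric())
    return(out)
  }
  total <- records$seconds_conditioned + records$seconds_control
  keep <- total >= min_total_s
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- retention_counts(records, min_total_s)
  out
}

#' @rdname apply_retention_filter
#' @export
retention_counts <- function(records, min_total_s = 10) {
  if (nrow(records) == 0) {
    return(tibble(test = character(), n_records = integer(),
                  n_rejected = integer(), rejection_rate = numeric()))
  }
  records |>
    dplyr::mutate(total = .data$seconds_conditioned + .data$seconds_control) |>
    dplyr::group_by(test = .data$test) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_rejected = sum(.data$total < min_total_s),
      rejection_rate = .data$n_rejected / .data$n_records,
      .groups = "drop"
    )
}

#' Write preference-test records as CSV
#'
#' @param records Records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read preference-test records from CSV
#'
#' @param path CSV path with the columns written by [write_records()].
#' @return A records tibble.
#' @export
read_records <- function(path) {
  recs <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("animal_id", "group", "test", "seconds_conditioned", "seconds_control")
  missing <- setdiff(needed, names(recs))
  if (length(missing)) {
    abort(sprintf("records file missing columns: %s", paste(missing, collapse = ", ")))
  }
  recs
}
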