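#' Analyze one behavioral experiment
#'
#' The full analysis stage for a pre/post x group preference experiment:
#' retention filtering, the interaction GLMM (or a test-only model for
#' single-group experiments), Wald tests for the terms the experiments
#' report (`test`, `test x training`), per-group decline tests (a
#' `test_only` fit within each group, as used for the single-group
#' epinastine experiment), and box-plot-ready cell quantiles of the
#' relative preference.
#'
#' @param records Preference-test records (pre-filter; the retention rule
#'   is applied here).
#' @param ref_group Reference training group (see [build_design()]).
#' @param quadrature_nodes Passed to [fit_preference_glmm()].
#' @return An object of class `pe_analysis`: list with `fit` (`pe_glmm`),
#'   `wald` (term table), `group_declines` (per-group test-term estimate,
#'   z, p and `significant_decline` = negative estimate with p < 0.05),
#'   `cells` (median and quartiles of relative preference per group x
#'   test), `retention` (per-test rejection counts) and `coding`.
#' @examples
#' gw <- tibble::tibble(group = c("control", "blocking"),
#'                      w_cs_cr = c(0.51, 0.024))
#' recs <- generate_preferences(gw, behavior_params(n_per_group = 15,
#'                                                  theta1 = 2), seed = 4)
#' analyze_experiment(recs)
#' @export
analyze_experiment <- function(records, ref_group = NULL,
                               quadrature_nodes = 9) {
  retention <- retention_counts(records)
  retained <- apply_retention_filter(records)
  if (nrow(retained) == 0) abort("no records remain after the retention filter")
  groups <- sort(unique(retained$group))
  design <- if (length(groups) >= 2) "test_by_training" else "test_only"
  fit <- fit_preference_glmm(retained, design = design, ref_group = ref_group,
                             quadrature_nodes = quadrature_nodes,
                             filter_retained = FALSE)
  wald <- wald_tests(fit)

  group_declines <- purrr::map_dfr(groups, function(g) {
    sub <- retained[retained$group == g, , drop = FALSE]
    gfit <- fit_preference_glmm(sub, design = "test_only",
                                quadrature_nodes = quadrature_nodes,
                                filter_retained = FALSE)
    if (!gfit$converged) {
      return(tibble(group = g, estimate = NA_real_, statistic = NA_real_,
                    p.value = NA_real_, significant_decline = NA))
    }
    w <- wald_tests(gfit)
    row <- w[w$term == "testpost", ]
    tibble(group = g, estimate = row$estimate, statistic = row$statistic,
           p.value = row$p.value,
           significant_decline = row$p.value < 0.05 & row$estimate < 0)
  })

  cells <- retained |>
    dplyr::group_by(group = .data$group, test = .data$test) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$relative_preference),
      q25 = quantile(.data$relative_preference, 0.25, names = FALSE),
      q75 = quantile(.data$relative_preference, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, factor(.data$test, levels = c("pre", "post")))

  structure(
    list(fit = fit, wald = wald, group_declines = group_declines,
         cells = cells, retention = retention, coding = fit$coding),
    class = "pe_analysis"
  )
}

#' @export
print.pe_analysis <- function(x, ...) {
  cat("<pe_analysis>\n")
  cat(sprintf("  %s\n", x$coding))
  cat("  Wald tests:\n")
  print(as.data.frame(x$wald), digits = 4)
  cat("  per-group post-vs-pre decline:\n")
  print(as.data.frame(x$group_declines), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pe_analysis <- function(x, ...) x$wald

#' @exportS3Method generics::glance
glance.pe_analysis <- function(x, ...) glance(x$fit)
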