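#' One-at-a-time cost slices around the true parameters
#'
#' For each parameter, evaluates the cost along a grid of fractional
#' perturbations of its true value with all other parameters held at
#' truth (a profile-likelihood-style slice without nuisance-parameter
#' re-optimisation). Slices are the basis of the problem-specific success
#' thresholds and make weakly identified parameters visible as flat
#' curves.
#'
#' @param problem A benchmark problem.
#' @param grid Fractional perturbations (default -5% to +5% in 1% steps).
#' @param reoptimise If `TRUE`, re-optimise the remaining parameters at
#'   each grid point with a short bounded trust-region run (a full profile
#'   likelihood; much slower).
#' @return A tibble with columns `parameter`, `delta`, `cost`; simulation
#'   failures at a grid point are recorded as `NA`, not errors.
#' @export
cost_slices <- function(problem, grid = seq(-0.05, 0.05, by = 0.01),
                        reoptimise = FALSE) {
  np <- n_parameters(problem)
  out <- tidyr::expand_grid(parameter = seq_len(np), delta = grid)
  out$cost <- purrr::pmap_dbl(out, function(parameter, delta) {
    p <- problem$p_star
    p[parameter] <- p[parameter] * (1 + delta)
    cst <- tryCatch(problem_cost(problem, p), error = function(e) NA_real_)
    if (!reoptimise || delta == 0) return(cst)
    tracker <- new_tracker(termination_spec(cost_threshold = 1e-300,
                                            max_evaluations = 200),
                           keep_records = FALSE)
    mp <- modified_problem(problem, modification(parameter_bounds = TRUE),
                           tracker)
    fixed <- parameter
    # profile out the other parameters with the perturbed one pinned
    pen_cost <- function(x_free) {
      x <- p
      x[-fixed] <- x_free
      mp$cost(x)
    }
    free0 <- p[-fixed]
    res <- tryCatch(
      stats::optim(free0, pen_cost, method = "Nelder-Mead",
                   control = list(maxit = 200)),
      chanbench_terminate = function(c) NULL,
      error = function(e) NULL)
    if (is.null(res)) min(cst, tracker$best_cost) else min(cst, res$value)
  })
  if (any(is.finite(out$cost[out$delta == 0]))) {
    class(out) <- c("cost_slices", class(out))
  }
  out
}

#' Success threshold from cost slices
#'
#' The threshold is the minimum, over the parameters not excluded as
#' unidentifiable (or strongly noise-biased), of the slice cost at the
#' outermost perturbations. A run beating this threshold has located the
#' cost basin more tightly than a 5% error in the most sensitive
#' parameter.
#'
#' @param slices A [cost_slices()] tibble.
#' @param exclude Integer parameter indices to ignore.
#' @return Scalar threshold.
#' @export
cost_threshold <- function(slices, exclude = integer()) {
  keep <- !(slices$parameter %in% exclude)
  if (!any(keep)) stop("all parameters excluded", call. = FALSE)
  edges <- slices[keep & abs(slices$delta) ==
                    max(abs(slices$delta[keep])), ]
  min(edges$cost, na.rm = TRUE)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cost_slices <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Fractional perturbation of the true value",
                  y = "Cost")
}
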