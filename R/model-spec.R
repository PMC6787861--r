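#' Specify an LFMC mixed-effects model
#'
#' A model specification combines (i) a mean function -- the four-parameter
#' declining logistic, a straight line in time, or a constant; (ii) a
#' fixed-effects map saying which mean parameters vary with leaf type
#' (reference level GW plus 0/1 dummy offsets for GE, SM, SS) and which are
#' common to all types; (iii) an optional set of mean parameters carrying
#' plot-level random effects (independent, mean-zero normal); (iv) an
#' optional set of parameters carrying fixed plot-offset dummies (used by the
#' fixed-effects alternative models); (v) the residual variance model
#' (homoscedastic or per-leaf-type varIdent); and (vi) an optional ARMA
#' serial-correlation structure along within-plot series.
#'
#' @param mean Mean function: `"logistic"` (parameters A, w, m, s),
#'   `"linear"` (intercept `a`, slope `b` in day) or `"constant"` (`c`).
#' @param fixed Named character vector/list mapping mean parameters to
#'   `"leaf_type"` or `"common"`.  Defaults: all `"leaf_type"` for logistic
#'   and linear means, `"common"` for the constant mean.
#' @param random Character vector of mean parameters with plot-level random
#'   effects (e.g. `"A"`); may be empty.
#' @param plot_fixed Character vector of mean parameters receiving fixed
#'   plot-offset dummies (plots beyond the first); may be empty.
#' @param variance `"constant"` for a single residual SD or `"varident"` for
#'   one SD per leaf type (reference GW, ratios `delta` for the others).
#' @param correlation `NULL` for independent residuals, or a list/vector
#'   `c(p = , q = )` giving the ARMA order (orders up to (1,1)).
#' @return An object of class `lfmc_model`.
#' @examples
#' lfmc_model()                      # the full (global) model
#' lfmc_final_model()                # the parsimonious drying model
#' @export
lfmc_model <- function(mean = c("logistic", "linear", "constant"),
                       fixed = NULL,
                       random = character(),
                       plot_fixed = character(),
                       variance = c("varident", "constant"),
                       correlation = NULL) {
  mean <- match.arg(mean)
  variance <- match.arg(variance)
  pars <- mean_parameters(mean)
  if (is.null(fixed)) {
    fixed <- setNames(rep(if (mean == "constant") "common" else "leaf_type",
                          length(pars)), pars)
  }
  fixed <- unlist(fixed)
  if (!all(names(fixed) %in% pars) || !all(pars %in% names(fixed))) {
    abort(paste0("`fixed` must map exactly the parameters: ",
                 paste(pars, collapse = ", ")),
          class = "fuelmoist_invalid_spec")
  }
  fixed <- fixed[pars]
  if (!all(fixed %in% c("common", "leaf_type"))) {
    abort("`fixed` entries must be \"common\" or \"leaf_type\".",
          class = "fuelmoist_invalid_spec")
  }
  random <- as.character(random)
  plot_fixed <- as.character(plot_fixed)
  if (!all(random %in% pars) || !all(plot_fixed %in% pars)) {
    abort("`random` and `plot_fixed` must name mean parameters.",
          class = "fuelmoist_invalid_spec")
  }
  if (length(intersect(random, plot_fixed))) {
    abort("A parameter cannot have both random and fixed plot effects.",
          class = "fuelmoist_invalid_spec")
  }
  if (!is.null(correlation)) {
    if (inherits(correlation, "corr_arma")) {
      correlation <- list(p = correlation$p, q = correlation$q)
    } else {
      correlation <- as.list(correlation)
      if (!all(c("p", "q") %in% names(correlation))) {
        abort("`correlation` must supply ARMA orders p and q.",
              class = "fuelmoist_invalid_spec")
      }
    }
    p <- as.integer(correlation$p)
    q <- as.integer(correlation$q)
    if (p < 0 || q < 0 || p > 1 || q > 1) {
      abort("Only ARMA orders up to (1,1) are supported.",
            class = "fuelmoist_unsupported_order")
    }
    if (p == 0 && q == 0) correlation <- NULL else correlation <- list(p = p, q = q)
  }
  structure(list(mean = mean, fixed = fixed, random = random,
                 plot_fixed = plot_fixed, variance = variance,
                 correlation = correlation),
            class = "lfmc_model")
}

mean_parameters <- function(mean) {
  switch(mean,
         logistic = c("A", "w", "m", "s"),
         linear   = c("a", "b"),
         constant = "c")
}

# mean parameters entering the conditional mean linearly (given the others):
# the marginal likelihood over random effects on these is an exact Gaussian
# integral
linear_parameters <- function(mean) {
  switch(mean,
         logistic = c("A", "w"),
         linear   = c("a", "b"),
         constant = "c")
}

#' The parsimonious final drying model
#'
#' Logistic mean with leaf-type effects on the asymptotes `A` and `w` only,
#' a common inflection time `m` and steepness `s`, a plot-level random effect
#' on `A`, per-leaf-type residual SDs (varIdent) and independent residuals.
#' This structure has 15 parameters: 10 fixed-effect coefficients, one
#' random-effect SD, three variance ratios and the residual SD.
#'
#' @return An `lfmc_model` specification.
#' @export
lfmc_final_model <- function() {
  lfmc_model(mean = "logistic",
             fixed = c(A = "leaf_type", w = "leaf_type",
                       m = "common", s = "common"),
             random = "A",
             variance = "varident",
             correlation = NULL)
}

#' Count estimated parameters of a model specification
#'
#' Fixed-effect coefficients, plot-level random-effect SDs, varIdent ratios,
#' ARMA coefficients and the residual SD, for a dataset with `n_leaf_types`
#' observed leaf types and `n_plots` plots.
#'
#' @param spec An [lfmc_model()] specification.
#' @param n_leaf_types Number of leaf-type levels present (default 4).
#' @param n_plots Number of plots present (default 6); only used when the
#'   spec has fixed plot offsets.
#' @return Integer parameter count.
#' @examples
#' count_parameters(lfmc_final_model())  # 15
#' @export
count_parameters <- function(spec, n_leaf_types = 4L, n_plots = 6L) {
  stopifnot(inherits(spec, "lfmc_model"))
  n_fixed <- sum(ifelse(spec$fixed == "leaf_type", n_leaf_types, 1L)) +
    length(spec$plot_fixed) * (n_plots - 1L)
  n_var <- if (spec$variance == "varident") n_leaf_types - 1L else 0L
  n_cor <- if (is.null(spec$correlation)) 0L else
    spec$correlation$p + spec$correlation$q
  as.integer(n_fixed + length(spec$random) + n_var + n_cor + 1L)
}

#' @export
print.lfmc_model <- function(x, ...) {
  cat("LFMC model specification\n")
  cat("  mean:       ", x$mean, "\n")
  cat("  fixed:      ",
      paste(names(x$fixed), x$fixed, sep = " ~ ", collapse = ", "), "\n")
  cat("  random:     ",
      if (length(x$random)) paste(x$random, collapse = ", ") else "none", "\n")
  if (length(x$plot_fixed)) {
    cat("  plot fixed: ", paste(x$plot_fixed, collapse = ", "), "\n")
  }
  cat("  variance:   ", x$variance, "\n")
  cat("  correlation:",
      if (is.null(x$correlation)) "independent" else
        sprintf("ARMA(%d,%d)", x$correlation$p, x$correlation$q), "\n")
  invisible(x)
}
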