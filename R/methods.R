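# Standard methods for fitted famlmm objects.

#' @method print famlmm
#' @export
print.famlmm <- function(x, ...) {
  cat("Family-based Bayesian linear mixed model (variational Bayes)\n")
  cat(sprintf("  n = %d; fixed-effect variants: %d; regions: %d; familial surrogates: %s\n",
              x$n, x$state$p, length(x$state$regions),
              if (is.null(x$state$gf)) "none" else "kinship + shared environment"))
  cat(sprintf("  %s after %d sweeps; ELBO = %.4f\n",
              x$convergence$stop_reason, x$convergence$sweeps,
              x$convergence$elbo))
  if (length(x$state$regions)) {
    phi <- vapply(x$state$regions, `[[`, 0, "phi")
    cat("  region inclusion:",
        paste(sprintf("%s=%.2f", names(phi), phi), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarise a famlmm fit
#'
#' Reports variational posterior summaries: expected variance components and
#' their share of the total, region inclusion probabilities, and the number
#' of isolated variants with posterior inclusion above 0.5.
#'
#' @param object a [famlmm()] fit.
#' @param ... unused.
#' @return A list of class `summary.famlmm` with elements `varcomp` (data
#'   frame: component, expected variance, fraction of total), `regions`,
#'   `n_selected` and `convergence`.
#' @method summary famlmm
#' @export
summary.famlmm <- function(object, ...) {
  st <- object$state
  e_var <- function(x) {
    if (is.null(x)) return(NULL)
    if (x$fixed) x$value else if (x$a > 1) x$b / (x$a - 1) else x$b / x$a
  }
  # region variances are model-averaged over inclusion: E[r_m] E[sigma_m^2]
  comp <- c(
    lapply(st$regions, function(r) r$phi * e_var(r)),
    list(gf = e_var(st$gf), ef = e_var(st$ef), residual = e_var(st$eps)))
  comp <- comp[!vapply(comp, is.null, TRUE)]
  vc <- data.frame(component = names(comp),
                   variance = unlist(comp), row.names = NULL)
  vc$fraction <- vc$variance / sum(vc$variance)
  regions <- if (length(st$regions)) {
    data.frame(region = names(st$regions),
               phi = vapply(st$regions, `[[`, 0, "phi"),
               k = vapply(st$regions, `[[`, 0L, "k"), row.names = NULL)
  } else NULL
  structure(list(varcomp = vc, regions = regions,
                 n_selected = if (st$p) sum(st$psi > 0.5) else 0L,
                 p = st$p,
                 convergence = object$convergence), class = "summary.famlmm")
}

#' @method print summary.famlmm
#' @export
print.summary.famlmm <- function(x, ...) {
  cat("Variance components (posterior expectations):\n")
  print(x$varcomp, digits = 4)
  if (!is.null(x$regions)) {
    cat("\nRegion inclusion probabilities:\n")
    print(x$regions, digits = 3)
  }
  if (x$p)
    cat(sprintf("\nIsolated variants with posterior inclusion > 0.5: %d of %d\n",
                x$n_selected, x$p))
  cat(sprintf("\nConvergence: %s after %d sweeps (ELBO %.4f)\n",
              x$convergence$stop_reason, x$convergence$sweeps,
              x$convergence$elbo))
  invisible(x)
}

#' Posterior-mean fixed effects
#'
#' Returns the model-averaged effect of each isolated variant,
#' \eqn{E_q[\gamma_j \beta_j] = \psi_j M_{\beta j}}.  The per-variant
#' inclusion probabilities are attached as `attr(, "inclusion")`.
#'
#' @param object a [famlmm()] fit.
#' @param ... unused.
#' @export
coef.famlmm <- function(object, ...) {
  st <- object$state
  if (st$p == 0) return(setNames(numeric(0), character(0)))
  out <- setNames(st$psi * st$Mb, object$x_names)
  attr(out, "inclusion") <- setNames(st$psi, object$x_names)
  out
}

#' @export
fitted.famlmm <- function(object, ...) {
  setNames(object$y_mean + rowSums(object$fitted_components),
           object$sample_ids)
}

#' @export
residuals.famlmm <- function(object, ...) {
  object$y - fitted(object)
}

#' Plot a famlmm fit
#'
#' `type = "elbo"` draws the ELBO trace over coordinate-ascent sweeps (it is
#' non-decreasing by construction); `type = "fitted"` plots fitted against
#' observed training outcomes.
#'
#' @param x a [famlmm()] fit.
#' @param type `"elbo"` or `"fitted"`.
#' @param ... passed to [plot()].
#' @export
plot.famlmm <- function(x, type = c("elbo", "fitted"), ...) {
  type <- match.arg(type)
  if (type == "elbo") {
    plot(seq_along(x$elbo) - 1, x$elbo, type = "l",
         xlab = "sweep", ylab = "ELBO", ...)
  } else {
    plot(fitted(x), x$y, xlab = "fitted", ylab = "observed", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Simulate outcomes from a fitted model
#'
#' Draws phenotypes from the plug-in posterior predictive on the training
#' samples: posterior-mean fitted values plus Gaussian noise at the expected
#' residual variance.
#'
#' @param object a [famlmm()] fit.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, one row per training sample.
#' @export
simulate.famlmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  s2 <- summary(object)$varcomp
  sd_eps <- sqrt(s2$variance[s2$component == "residual"])
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, sd_eps)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$sample_ids
  out
}
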