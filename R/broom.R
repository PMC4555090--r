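# broom-style tidiers for the package's result objects.

#' @method tidy antisense_calls
#' @export
tidy.antisense_calls <- function(x, ...) {
  out <- x
  attr(out, "report") <- NULL
  class(out) <- class(tibble::tibble())
  tibble::as_tibble(out)
}

#' Summarise a set of antisense calls in one row
#'
#' @param x An `antisense_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_expressed`, `n_called`,
#'   `prop_called` (of expressed genes), `artifact_p`, `alpha`, `adjusted`.
#' @method glance antisense_calls
#' @export
glance.antisense_calls <- function(x, ...) {
  expressed <- sum(x$total > 0)
  tibble::tibble(
    n_genes = nrow(x),
    n_expressed = expressed,
    n_called = sum(x$antisense_called),
    prop_called = if (expressed > 0) sum(x$antisense_called) / expressed
                  else NA_real_,
    artifact_p = attr(x, "artifact_p"),
    alpha = attr(x, "alpha"),
    adjusted = attr(x, "adjusted")
  )
}

#' @method tidy cog_enrichment
#' @export
tidy.cog_enrichment <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  tibble::as_tibble(out)
}

#' @method glance cog_enrichment
#' @export
glance.cog_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_genomes = dplyr::n_distinct(x$species_id),
    n_significant_binomial = sum(x$significant_binomial),
    n_significant_fisher = sum(x$significant_fisher),
    q_threshold = attr(x, "q_threshold")
  )
}

#' @method tidy profile_correlation
#' @export
tidy.profile_correlation <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p, n = x$n,
                 method = "pearson")
}

#' @method glance profile_correlation
#' @export
glance.profile_correlation <- function(x, ...) tidy(x)

#' @method tidy expression_dominance
#' @export
tidy.expression_dominance <- function(x, ...) {
  tibble::tibble(estimate = x$rho, p.value = x$p, n = x$n,
                 method = "spearman")
}

#' @method glance expression_dominance
#' @export
glance.expression_dominance <- function(x, ...) tidy(x)

#' @export
print.profile_correlation <- function(x, ...) {
  cat(sprintf("Antisense profile correlation: Pearson r = %.3f (p = %.3g, n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' @export
print.expression_dominance <- function(x, ...) {
  cat(sprintf("log(FPKM) vs |d|: Spearman rho = %.3f (p = %.3g, n = %d genes)\n",
              x$rho, x$p, x$n))
  invisible(x)
}

#' @export
print.artifact_model <- function(x, ...) {
  cat(sprintf("Artifact rate model: p = %.4g (%s)\n", x$p, x$source))
  invisible(x)
}
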