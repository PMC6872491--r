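## Mutational-signature refitting: non-negative least squares of 96-context
## SNV counts onto a fixed signature matrix, with the reporting filter on
## relative contribution and absolute fitted load.

#' Tabulate 96-context counts from a somatic variant table
#'
#' @param variants somatic variant data frame with a `context` column.
#' @return named integer vector of length 96 (canonical context order).
#' @export
context_counts <- function(variants) {
  lev <- context96_levels()
  ctx <- variants$context[variants$type == "SNV" & !is.na(variants$context)]
  tab <- table(factor(ctx, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Refit mutational signature contributions
#'
#' Non-negative least-squares fit of observed 96-context counts as a
#' mixture of fixed signature profiles. The residual is the sum of absolute
#' differences between observed and fitted counts across the 96 contexts.
#' The reported set excludes signatures contributing less than
#' `min_fraction` of the total fitted load or with absolute fitted load
#' below `min_load` (strict `<` on both).
#'
#' @param counts numeric vector of 96 context counts (non-negative).
#' @param signature_matrix 96 x K column-normalised signature matrix.
#' @param min_fraction relative-contribution reporting filter.
#' @param min_load absolute fitted-load reporting filter (variants).
#' @return object of class `signature_fit`: `contributions` (all K),
#'   `reported` (named vector after filtering), `residual`, `fitted`.
#' @export
fit_signatures <- function(counts, signature_matrix, min_fraction = 0.05,
                           min_load = 300) {
  stopifnot(length(counts) == nrow(signature_matrix))
  if (any(counts < 0)) stop("negative context counts")
  nn <- pracma::lsqnonneg(signature_matrix, as.numeric(counts))
  # snap away solver noise so that exact-cone inputs recover exact loads
  x <- stats::setNames(round(nn$x, 6), colnames(signature_matrix))
  fitted <- as.numeric(signature_matrix %*% x)
  residual <- sum(abs(counts - fitted))
  total <- sum(x)
  keep <- if (total > 0) !(x / total < min_fraction | x < min_load)
          else rep(FALSE, length(x))
  structure(list(contributions = x, reported = x[keep],
                 residual = residual, fitted = fitted,
                 observed = as.numeric(counts),
                 min_fraction = min_fraction, min_load = min_load),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("signature_fit: %d signatures reported of %d, residual %.2f\n",
              length(x$reported), length(x$contributions), x$residual))
  if (length(x$reported)) {
    pct <- 100 * x$reported / sum(x$contributions)
    cat(paste(sprintf("  %s: %.0f variants (%.1f%%)", names(x$reported),
                      x$reported, pct), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$contributions

#' @export
fitted.signature_fit <- function(object, ...) object$fitted

#' @export
residuals.signature_fit <- function(object, ...) {
  object$observed - object$fitted
}

#' Barplot of fitted signature contributions
#' @param x a `signature_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.signature_fit <- function(x, ...) {
  nz <- x$contributions[x$contributions > 0]
  graphics::barplot(nz, las = 2, ylab = "fitted variants",
                    col = ifelse(names(nz) %in% names(x$reported),
                                 "firebrick", "grey70"), ...)
  invisible(x)
}
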