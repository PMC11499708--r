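# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Draw one multivariate-normal vector with mean mu and covariance
# diag(s) %*% R %*% diag(s), via the Cholesky factor of R.
mvn_draw <- function(mu, s, chol_R) {
  mu + s * drop(crossprod(chol_R, stats::rnorm(length(mu))))
}

# Symmetrise + eigenvalue check; ridge-regularise a correlation matrix that is
# numerically indefinite. Returns the (possibly regularised) matrix.
ensure_pd <- function(R, ridge = 1e-6, label = "LD matrix") {
  R <- (R + t(R)) / 2
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop(label, " is not positive semi-definite (min eigenvalue ",
                       format(ev), ")", call. = FALSE)
  if (ev < 1e-10) {
    message(label, " ridge-regularised (", format(ridge), " added to diagonal)")
    R <- R + diag(ridge, nrow(R))
  }
  R
}

# exchangeable correlation block
block_cor <- function(m, rho) {
  R <- matrix(rho, m, m)
  diag(R) <- 1
  R
}

# standard error back-derived from a 95% CI printed on the OR scale
or_ci_to_beta <- function(or, ci_low, ci_high) {
  list(beta = log(or), se = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975)))
}

is_palindromic <- function(ea, oa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[ea]) == oa
}

complement_allele <- function(a) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
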