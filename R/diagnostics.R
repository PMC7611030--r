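#' MCMC convergence diagnostics: split R-hat and bulk ESS
#'
#' Computes the split-chain potential scale reduction factor (each chain is
#' halved, so within-chain drift also inflates R-hat) and an effective
#' sample size from combined-chain autocorrelations with Geyer's initial
#' monotone truncation. These are the numerical counterparts of a visual
#' trace-plot check; draws can be exported for plotting with
#' [export_draws()].
#'
#' @param chains A list (length >= 2) of matrices, one per chain, with
#'   identical column names (parameters) and >= 100 rows (draws) each.
#' @return A data frame with columns `parameter`, `rhat`, `ess` and `flag`
#'   (`""`, `"zero_variance"` for degenerate constant chains where R-hat is
#'   undefined, or `"not_converged"` when R-hat > 1.05).
#' @export
convergence_diagnostics <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains to assess convergence")
  if (any(vapply(chains, nrow, 1L) < 100L))
    stop("need at least 100 draws per chain")
  params <- colnames(chains[[1]])
  if (is.null(params)) params <- paste0("par", seq_len(ncol(chains[[1]])))
  out <- lapply(seq_along(params), function(j) {
    draws <- vapply(chains, function(m) m[, j], numeric(nrow(chains[[1]])))
    d <- .split_diag(draws)
    data.frame(parameter = params[j], rhat = d$rhat, ess = d$ess,
               flag = if (is.na(d$rhat)) "zero_variance"
                      else if (d$rhat > 1.05) "not_converged" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# draws: n x m matrix (iterations x chains) for one parameter
.split_diag <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(split); n2 <- nrow(split)
  mu <- colMeans(split)
  s2 <- apply(split, 2, stats::var)
  W <- mean(s2)
  B <- n2 * stats::var(mu)
  if (!is.finite(W) || W <= 0) return(list(rhat = NA_real_, ess = NA_real_))
  varplus <- (n2 - 1) / n2 * W + B / n2
  rhat <- sqrt(varplus / W)

  # combined autocorrelation (Stan-style), Geyer initial monotone sequence
  lag_max <- min(n2 - 2L, 1000L)
  acov <- vapply(seq_len(m), function(i) {
    a <- stats::acf(split[, i], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n2 - 1) / n2
  }, numeric(lag_max + 1L))
  rho <- 1 - (W - rowMeans(acov)) / varplus
  rho[1] <- 1
  # sum consecutive pairs while positive and non-increasing
  tau <- 1
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2L
  }
  ess <- min(m * n2 / tau, m * n2)
  list(rhat = rhat, ess = ess)
}
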