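#' GEE Poisson regression with exchangeable working correlation
#'
#' Population-averaged Poisson regression (log link) estimated by
#' generalized estimating equations for repeated measures within persons.
#' Supported working correlation structures: `exchangeable` (any two
#' observations of the same cluster share correlation rho),
#' `independence`, and `unstructured` (a free correlation per pair of
#' within-cluster time points, which requires `time`).
#'
#' Moment estimators follow Liang & Zeger: the scale (dispersion) phi is
#' the Pearson residual sum of squares over `N - p`, and rho is the
#' average cross-product of Pearson residuals over
#' `(total pairs) - p`, both divided by phi.  Standard errors are robust
#' (sandwich) by default.  With independence working correlation and one
#' observation per cluster the estimates coincide with an ordinary
#' Poisson GLM.
#'
#' @param formula Model formula, e.g. `ecs ~ severity + year + sex`.
#' @param data A data frame.
#' @param id Cluster identifier: a column name (string or bare name).
#' @param corstr Working correlation structure.
#' @param time Column giving the within-cluster time index (required for
#'   `unstructured`; observations of a cluster must have distinct times).
#' @param maxit,tol Iteration control for Fisher scoring.
#' @return An object of class `aud_gee` with coefficients, robust and
#'   model-based covariance, working correlation `rho` (for
#'   `unstructured`: the average off-diagonal, with the full matrix in
#'   `rho_matrix`), scale `phi`, and fit metadata.  Methods: `tidy()`,
#'   `glance()`, `print()`, `autoplot()`.
#' @export
gee_poisson <- function(formula, data, id,
                        corstr = c("exchangeable", "independence",
                                   "unstructured"),
                        time = NULL, maxit = 100, tol = 1e-10) {
  corstr <- match.arg(corstr)
  id_q <- rlang::enquo(id)
  id_vec <- rlang::eval_tidy(id_q, data)
  if (is.null(id_vec)) abort("gee_poisson(): `id` not found in `data`")
  time_q <- rlang::enquo(time)
  time_vec <- rlang::eval_tidy(time_q, data)
  if (corstr == "unstructured" && is.null(time_vec)) {
    abort("gee_poisson(): `time` is required for corstr = 'unstructured'")
  }

  mf <- model.frame(formula, data, na.action = stats::na.omit)
  if (!is.null(attr(mf, "na.action"))) {
    drop_idx <- as.integer(attr(mf, "na.action"))
    id_vec <- id_vec[-drop_idx]
    if (!is.null(time_vec)) time_vec <- time_vec[-drop_idx]
  }
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (any(y < 0)) abort("gee_poisson(): negative response")

  ord <- order(id_vec, if (is.null(time_vec)) seq_along(id_vec) else time_vec)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; id_vec <- id_vec[ord]
  time_vec <- time_vec[ord]
  cl <- match(id_vec, unique(id_vec))
  n_obs <- length(y)
  p <- ncol(X)
  ni <- tabulate(cl)
  n_cl <- length(ni)
  n_pairs <- sum(ni * (ni - 1) / 2)

  if (n_pairs == 0 && corstr != "independence") {
    warn("all clusters have a single observation; working correlation reduces to independence")
  }

  if (corstr == "unstructured") {
    tindex <- match(time_vec, sort(unique(time_vec)))
    n_time <- max(tindex)
    if (anyDuplicated(cbind(cl, tindex))) {
      abort("gee_poisson(): duplicated time points within a cluster")
    }
  }

  beta <- glm.fit(X, y, family = poisson())$coefficients
  rho <- 0; phi <- 1; R_un <- NULL
  converged <- FALSE

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    r <- (y - mu) / sqrt(mu)
    phi <- sum(r^2) / (n_obs - p)

    if (corstr %in% c("exchangeable", "independence")) {
      if (corstr == "exchangeable" && n_pairs > p) {
        s1 <- rowsum(r, cl); s2 <- rowsum(r^2, cl)
        rho <- sum((s1^2 - s2) / 2) / (phi * (n_pairs - p))
        rho <- min(max(rho, -1 / (max(ni) - 1 + 1e-12) + 1e-6), 0.999)
      } else {
        rho <- 0
      }
      upd <- gee_update_exch(X, y, mu, cl, ni, rho, phi)
    } else {
      R_un <- unstructured_corr(r, cl, tindex, n_time, phi, p)
      upd <- gee_update_unstr(X, y, mu, cl, tindex, R_un, phi)
    }

    delta <- solve(upd$B, upd$score)
    beta <- beta + delta
    if (max(abs(delta) / pmax(abs(beta), 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "gee_poisson() did not converge in %d iterations (last max step %.3g); consider rescaling covariates",
      maxit, max(abs(delta))))
  }

  # final quantities at the solution
  eta <- drop(X %*% beta); mu <- exp(eta)
  r <- (y - mu) / sqrt(mu)
  phi <- sum(r^2) / (n_obs - p)
  if (corstr == "exchangeable" && n_pairs > p) {
    s1 <- rowsum(r, cl); s2 <- rowsum(r^2, cl)
    rho <- sum((s1^2 - s2) / 2) / (phi * (n_pairs - p))
    rho <- min(max(rho, -1 / (max(ni) - 1 + 1e-12) + 1e-6), 0.999)
  }
  if (corstr == "unstructured") {
    R_un <- unstructured_corr(r, cl, tindex, n_time, phi, p)
  }
  upd <- if (corstr == "unstructured") {
    gee_update_unstr(X, y, mu, cl, tindex, R_un, phi, meat = TRUE)
  } else {
    gee_update_exch(X, y, mu, cl, ni, rho, phi, meat = TRUE)
  }
  bread <- solve(upd$B)
  vcov_robust <- bread %*% upd$M %*% bread
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  vcov_naive <- bread
  dimnames(vcov_naive) <- dimnames(vcov_robust)

  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    vcov = vcov_robust,
    vcov_naive = vcov_naive,
    rho = if (corstr == "unstructured") {
      mean(R_un[upper.tri(R_un)], na.rm = TRUE)
    } else rho,
    rho_matrix = R_un,
    phi = phi,
    corstr = corstr,
    n_obs = n_obs,
    n_clusters = n_cl,
    max_cluster_size = max(ni),
    iterations = iter,
    converged = converged,
    formula = formula,
    fitted = mu,
    y = y
  ), class = "aud_gee")
}

# Exchangeable / independence scoring step using closed-form cluster
# inverses, fully vectorised via grouped sums:
#   V_i^{-1} = (1/phi) A^{-1/2} [ I/(1-rho) - c_i J ] A^{-1/2},
#   c_i = rho / ((1-rho) (1 + (n_i - 1) rho)).
gee_update_exch <- function(X, y, mu, cl, ni, rho, phi, meat = FALSE) {
  w <- sqrt(mu)
  W <- X * w                       # rows: sqrt(mu_j) x_j
  e <- (y - mu) / w                # Pearson residuals
  ci <- rho / ((1 - rho) * (1 + (ni - 1) * rho))
  S <- rowsum(W, cl)               # cluster sums of sqrt(mu) x
  se <- drop(rowsum(e, cl))        # cluster sums of residuals
  B <- (crossprod(W) / (1 - rho) - crossprod(S, S * ci)) / phi
  G <- (rowsum(W * e, cl) / (1 - rho) - S * (ci * se)) / phi  # cluster scores
  score <- colSums(G)
  out <- list(B = B, score = score)
  if (meat) out$M <- crossprod(G)
  out
}

# moment estimator of the unstructured working correlation (times x times)
unstructured_corr <- function(r, cl, tindex, n_time, phi, p) {
  M <- matrix(0, n_time, n_time)
  Nm <- matrix(0, n_time, n_time)
  sp <- split(seq_along(r), cl)
  for (idx in sp) {
    t_i <- tindex[idx]; r_i <- r[idx]
    M[t_i, t_i] <- M[t_i, t_i] + outer(r_i, r_i)
    Nm[t_i, t_i] <- Nm[t_i, t_i] + 1
  }
  R <- M / (pmax(Nm - p, 1) * phi)
  diag(R) <- 1
  R[Nm == 0] <- 0
  diag(R) <- 1
  R
}

gee_update_unstr <- function(X, y, mu, cl, tindex, R, phi, meat = FALSE) {
  p <- ncol(X)
  B <- matrix(0, p, p)
  score <- numeric(p)
  M <- matrix(0, p, p)
  sp <- split(seq_along(y), cl)
  for (idx in sp) {
    w <- sqrt(mu[idx])
    D <- X[idx, , drop = FALSE] * w
    e <- (y[idx] - mu[idx]) / w
    Ri <- R[tindex[idx], tindex[idx], drop = FALSE]
    Vinv <- solve(Ri) / phi
    DtV <- crossprod(D, Vinv)
    B <- B + DtV %*% D
    g <- drop(DtV %*% e)
    score <- score + g
    if (meat) M <- M + tcrossprod(g)
  }
  out <- list(B = B, score = score)
  if (meat) out$M <- M
  out
}

#' @export
print.aud_gee <- function(x, ...) {
  cat(sprintf("GEE Poisson regression (%s working correlation)\n", x$corstr))
  cat(sprintf("  %d observations in %d clusters (max size %d)\n",
              x$n_obs, x$n_clusters, x$max_cluster_size))
  cat(sprintf("  scale phi = %.3f, working correlation rho = %.3f\n",
              x$phi, x$rho))
  cat("\nExponentiated coefficients (robust 95% CI):\n")
  print(as.data.frame(tidy(x)), digits = 3)
  invisible(x)
}

#' @rdname gee_poisson
#' @param x,object An `aud_gee` fit.
#' @param exponentiate Report rate ratios (`exp(coef)`) instead of raw
#'   coefficients.
#' @param conf.level Confidence level for robust Wald intervals.
#' @param ... Unused.
#' @method tidy aud_gee
#' @export
tidy.aud_gee <- function(x, exponentiate = TRUE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  pv <- 2 * pnorm(-abs(est / se))
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  tibble(term = names(x$coefficients), estimate = unname(est),
         std.error = unname(se), conf.low = unname(lo),
         conf.high = unname(hi), p.value = unname(pv))
}

#' @rdname gee_poisson
#' @method glance aud_gee
#' @export
glance.aud_gee <- function(x, ...) {
  tibble(rho = x$rho, phi = x$phi, n_obs = x$n_obs,
         n_clusters = x$n_clusters, iterations = x$iterations,
         converged = x$converged, corstr = x$corstr)
}

#' @rdname gee_poisson
#' @method autoplot aud_gee
#' @export
autoplot.aud_gee <- function(object, ...) {
  td <- filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Rate ratio (robust 95% CI)", y = NULL,
                  title = "GEE Poisson rate ratios") +
    ggplot2::theme_minimal()
}
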