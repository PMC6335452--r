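# Minimal generalized estimating equations for clustered binary outcomes
# (logit link, binomial variance), with independence and exchangeable
# working correlations, robust (sandwich) covariance and Pan's QIC. Written
# here because no GEE solver ships with the supported dependency set; the
# independence case is validated against stats::glm and cluster-robust
# covariances in the test suite.

#' Fit a repeated-measures logistic regression by GEE
#'
#' Liang-Zeger estimating equations for a binary outcome with logit link:
#' iteratively reweighted updates of the coefficients under the chosen
#' working correlation, moment estimation of the exchangeable correlation
#' from Pearson residuals, and a robust sandwich covariance estimate.
#'
#' @param formula Model formula with a 0/1 (or logical) response.
#' @param data Data.frame holding the variables.
#' @param id Cluster identifier: a vector, or the name of a column of
#'   `data`.
#' @param corstr `"independence"` or `"exchangeable"` working correlation.
#' @param maxit,tol Iteration controls.
#' @return A list of class `gee_fit`: `coefficients`, `vcov` (robust),
#'   `naive_vcov`, `alpha`, `phi`, `qic`, `corstr`, `n_clusters`, `terms`,
#'   `assign`, `fitted`.
#' @export
gee_logit <- function(formula, data, id,
                      corstr = c("independence", "exchangeable"),
                      maxit = 100, tol = 1e-8) {
  corstr <- match.arg(corstr)
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop_config("gee_logit: response must be binary")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- as.character(id)
  if (length(id) != length(y)) stop_config("gee_logit: id length mismatch")
  clusters <- split(seq_along(y), id)
  if (length(clusters) < 2) stop_config("gee_logit: need at least 2 clusters")
  p <- ncol(X); N <- length(y)

  beta <- stats::glm.fit(X, y, family = stats::binomial())$coefficients
  alpha <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    e <- (y - mu) / sqrt(w)
    phi <- sum(e^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (idx in clusters) {
        ni <- length(idx)
        if (ni < 2) next
        s <- sum(e[idx])
        num <- num + (s^2 - sum(e[idx]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- num / ((den - p) * phi)
      alpha <- max(min(alpha, 0.95), -0.95)
    }
    B <- matrix(0, p, p); U <- numeric(p)
    for (idx in clusters) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      wi <- w[idx]
      ri <- y[idx] - mu[idx]
      Di <- Xi * wi                      # dmu/dbeta = A_i X_i
      if (corstr == "independence" || ni == 1) {
        VinvD <- Di / wi                 # V_i^{-1} D_i with V_i = A_i
        U <- U + drop(crossprod(VinvD, ri))
        B <- B + crossprod(VinvD, Di)
      } else {
        Ahalf <- sqrt(wi)
        # R^{-1} for exchangeable has the closed form
        # I/(1-a) - a/((1-a)(1+(n-1)a)) J
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        Z <- Di / Ahalf                  # A^{-1/2} D_i
        RinvZ <- c1 * Z - c2 * matrix(colSums(Z), ni, p, byrow = TRUE)
        VinvD <- RinvZ / Ahalf
        U <- U + drop(crossprod(VinvD, ri))
        B <- B + crossprod(VinvD, Di)
      }
    }
    delta <- solve(B, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  B <- matrix(0, p, p); M <- matrix(0, p, p); OmegaI <- matrix(0, p, p)
  for (idx in clusters) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    wi <- w[idx]
    ri <- y[idx] - mu[idx]
    Di <- Xi * wi
    OmegaI <- OmegaI + crossprod(Xi * sqrt(wi))
    if (corstr == "independence" || ni == 1) {
      VinvD <- Di / wi
    } else {
      Ahalf <- sqrt(wi)
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Z <- Di / Ahalf
      RinvZ <- c1 * Z - c2 * matrix(colSums(Z), ni, p, byrow = TRUE)
      VinvD <- RinvZ / Ahalf
    }
    B <- B + crossprod(VinvD, Di)
    u_i <- drop(crossprod(VinvD, ri))
    M <- M + tcrossprod(u_i)
  }
  Binv <- solve(B)
  vcov_rob <- Binv %*% M %*% Binv
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ql <- sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  qic <- -2 * ql + 2 * sum(diag(OmegaI %*% vcov_rob))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = vcov_rob, naive_vcov = Binv,
                 alpha = if (corstr == "exchangeable") alpha else 0,
                 phi = sum(((y - mu) / sqrt(w))^2) / (N - p),
                 qic = qic, quasi_lik = ql, corstr = corstr,
                 n_clusters = length(clusters), n_obs = N,
                 terms = attr(mf, "terms"), assign = attr(X, "assign"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 fitted = mu, converged = it < maxit),
            class = "gee_fit")
}

#' Wald chi-square tests for every term of a GEE fit
#'
#' Joint robust Wald test that all coefficients belonging to a model term
#' are zero; for a categorical predictor with L levels this is the
#' (L-1)-df test reported alongside repeated-measures logistic regressions.
#'
#' @param fit A `gee_fit`.
#' @return Data.frame with columns `term`, `chisq`, `df`, `p`.
#' @export
gee_wald <- function(fit) {
  labels <- attr(fit$terms, "term.labels")
  out <- lapply(seq_along(labels), function(j) {
    idx <- which(fit$assign == j)
    b <- fit$coefficients[idx]
    W <- drop(t(b) %*% solve(fit$vcov[idx, idx, drop = FALSE]) %*% b)
    data.frame(term = labels[j], chisq = W, df = length(idx),
               p = stats::pchisq(W, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predicted probabilities (with delta-method standard errors) for new data
#'
#' @param object A `gee_fit`.
#' @param newdata Data.frame of predictor values.
#' @param ... Unused.
#' @return `newdata` with `prob` and `se` columns appended.
#' @export
predict.gee_fit <- function(object, newdata, ...) {
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                           xlev = object$xlevels)
  eta <- drop(X %*% object$coefficients)
  p <- stats::plogis(eta)
  se_eta <- sqrt(rowSums((X %*% object$vcov) * X))
  newdata$prob <- p
  newdata$se <- p * (1 - p) * se_eta
  newdata
}
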