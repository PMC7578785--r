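#' Fit the logistic choice model for a mixed-gambles participant
#'
#' Models the probability of accepting a 50/50 gamble as
#' \deqn{p_{accept} = logit^{-1}(\beta_{gains} \cdot gain + \beta_{losses} \cdot loss + intercept)}
#' where `gain` and `loss` are the (non-negative) magnitudes offered on each
#' trial; a loss-averse participant has a negative `beta_losses` roughly twice
#' `beta_gains` in magnitude. Trial-wise subjective value is the linear
#' predictor without the intercept, and inverse decision entropy is the
#' negative binary Shannon entropy of the fitted acceptance probability.
#'
#' Fitting is maximum likelihood by iteratively reweighted least squares with
#' an always-on ridge penalty (`penalty`, default `1e-6`) so that separable
#' data never produces infinite coefficients. If separation is detected (any
#' coefficient exceeding `coef_limit` in magnitude at convergence, or fitted
#' probabilities saturating at the observed responses), the fit is redone with
#' the heavier `separation_penalty` and flagged `separable`.
#'
#' @param formula model formula; default `accept ~ gain + loss`.
#' @param data data frame containing the response and gamble magnitudes.
#'   Rows with a missing response are dropped.
#' @param penalty ridge penalty applied to all coefficients (default `1e-6`).
#' @param separation_penalty penalty used when separation is detected.
#' @param coef_limit coefficient magnitude that triggers the separation
#'   escalation.
#' @param max_iter,tol IRLS iteration controls.
#' @return an object of class `"choice_model"` with components
#'   `coefficients`, `vcov`, `fitted`, `converged`, `separable`,
#'   `loss_aversion` (ratio `-beta_losses / beta_gains`), `logLik`, `n`.
#' @seealso [trial_values()], [subjective_value()], [accept_prob()]
#' @export
#' @examples
#' g <- expand.grid(gain = seq(5, 40, 5), loss = seq(5, 40, 5))
#' p <- plogis(0.1 * g$gain - 0.2 * g$loss)
#' set.seed(1)
#' g$accept <- rbinom(nrow(g), 1, p)
#' fit <- choice_model(accept ~ gain + loss, g)
#' coef(fit)
choice_model <- function(formula = accept ~ gain + loss, data,
                         penalty = 1e-6, separation_penalty = 1e-2,
                         coef_limit = 10, max_iter = 200, tol = 1e-10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  keep <- !is.na(y)
  if (!any(keep)) stop("all responses are missing; cannot fit choice model")
  y <- as.numeric(y[keep])
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)")
  X <- stats::model.matrix(formula, mf)[keep, , drop = FALSE]
  if (sum(keep) < 2)
    stop("need at least 2 non-missing trials to fit the choice model")

  fit <- irls_ridge(X, y, penalty, max_iter, tol)
  separable <- detect_separation(fit, X, y, coef_limit)
  if (separable) {
    fit <- irls_ridge(X, y, separation_penalty, max_iter, tol)
    fit$penalty <- separation_penalty
  }

  beta <- fit$coefficients
  out <- list(
    coefficients = beta,
    vcov = fit$vcov,
    fitted = as.vector(stats::plogis(X %*% beta)),
    y = y, X = X,
    formula = formula,
    converged = fit$converged,
    separable = separable,
    penalty = fit$penalty,
    logLik = fit$logLik,
    n = length(y),
    n_dropped = sum(!keep)
  )
  out$loss_aversion <- loss_aversion_ratio(out)
  class(out) <- "choice_model"
  out
}

# penalised IRLS for logistic regression; ridge keeps the normal equations
# invertible under separation
irls_ridge <- function(X, y, lambda, max_iter, tol) {
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    A <- crossprod(X, w * X) + diag(lambda, p)
    beta_new <- solve(A, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  beta <- as.vector(beta)
  names(beta) <- colnames(X)
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  A <- crossprod(X, w * X) + diag(lambda, ncol(X))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coefficients = beta, vcov = solve(A), converged = converged,
       logLik = ll, penalty = lambda)
}

# separation heuristics: runaway coefficients, or fitted probabilities
# saturated at the observed labels (monotone likelihood), or a one-sided
# response vector
detect_separation <- function(fit, X, y, coef_limit) {
  if (length(unique(y)) == 1) return(TRUE)
  if (any(abs(fit$coefficients) > coef_limit)) return(TRUE)
  mu <- stats::plogis(as.vector(X %*% fit$coefficients))
  all(abs(y - mu) < 1e-4)
}

loss_aversion_ratio <- function(fit) {
  b <- stats::coef(fit)
  bg <- b[["gain"]]; bl <- b[["loss"]]
  if (is.null(bg) || bg == 0) return(NA_real_)
  -bl / bg
}

#' @export
coef.choice_model <- function(object, ...) object$coefficients

#' @export
vcov.choice_model <- function(object, ...) object$vcov

#' @export
logLik.choice_model <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.choice_model <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Logistic choice model (mixed gambles)\n")
  cat("  n =", x$n, "trials")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " missing responses dropped)", sep = "")
  cat("\nCoefficients:\n")
  print.default(format(x$coefficients, digits = digits), print.gap = 2, quote = FALSE)
  if (!is.na(x$loss_aversion))
    cat("Loss aversion (-beta_losses/beta_gains):",
        format(x$loss_aversion, digits = digits), "\n")
  if (x$separable)
    cat("Note: separation detected; ridge-stabilised fit (penalty ",
        format(x$penalty), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.choice_model <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  zval <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  structure(list(coefficients = tab, loss_aversion = object$loss_aversion,
                 converged = object$converged, separable = object$separable,
                 n = object$n, logLik = object$logLik),
            class = "summary.choice_model")
}

#' @export
print.summary.choice_model <- function(x, ...) {
  cat("Logistic choice model: accept ~ gain + loss (n =", x$n, ")\n\n")
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  cat("\nLog-likelihood:", format(x$logLik), "\n")
  if (!is.na(x$loss_aversion))
    cat("Loss aversion:", format(x$loss_aversion, digits = 4), "\n")
  if (x$separable) cat("Separable data: penalised fit.\n")
  invisible(x)
}

#' @export
residuals.choice_model <- function(object,
                                   type = c("deviance", "pearson", "response"),
                                   ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(pmax(mu, 1e-300)) +
                 (1 - y) * log(pmax(1 - mu, 1e-300)))))
}

#' Trial-wise model quantities from a fitted choice model
#'
#' @param object a [choice_model()] fit (or a coefficient vector with
#'   elements `gain`, `loss` and `(Intercept)`).
#' @param newdata data frame with `gain` and `loss` columns; defaults to the
#'   fitting data.
#' @param type one of `"sv"` (subjective value, linear predictor without the
#'   intercept), `"response"` (acceptance probability), `"ide"`,
#'   `"p_correct"`, or `"values"` (a data frame with all of them plus
#'   `p_reject` and `de`).
#' @return numeric vector, or a data frame for `type = "values"`.
#' @export
predict.choice_model <- function(object, newdata = NULL,
                                 type = c("values", "sv", "response",
                                          "ide", "p_correct"), ...) {
  type <- match.arg(type)
  b <- object$coefficients
  if (any(!is.finite(b))) stop("non-finite coefficients; cannot predict")
  if (is.null(newdata)) {
    X <- object$X
  } else {
    X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                             newdata)
  }
  icol <- match("(Intercept)", colnames(X))
  sv <- as.vector(X[, -icol, drop = FALSE] %*% b[colnames(X)[-icol]])
  if (type == "sv") return(sv)
  p <- stats::plogis(sv + b[["(Intercept)"]])
  if (type == "response") return(p)
  de <- decision_entropy(p)
  if (type == "ide") return(-de)
  if (type == "p_correct") return(prob_correct(p))
  data.frame(sv = sv, p_accept = p, p_reject = 1 - p,
             de = de, ide = -de, p_correct = prob_correct(p))
}

#' @rdname predict.choice_model
#' @param ... passed on.
#' @export
trial_values <- function(object, newdata = NULL, ...) {
  stats::predict(object, newdata = newdata, type = "values", ...)
}

#' Subjective value of a gamble
#'
#' `sv = beta_gains * gain + beta_losses * loss` — the fitted linear
#' predictor without the intercept. Gains and losses enter as non-negative
#' magnitudes; the sign of the loss term is carried by `beta_losses`.
#'
#' @param fit a [choice_model()] fit, or a numeric vector
#'   `c(beta_gains, beta_losses)`.
#' @param gain,loss non-negative gamble magnitudes (currency units).
#' @return numeric vector of subjective values (logit units).
#' @export
#' @examples
#' subjective_value(c(0.5, -1), gain = 20, loss = 10)  # exactly 0
subjective_value <- function(fit, gain, loss) {
  if (any(!is.finite(gain)) || any(!is.finite(loss)) ||
      any(gain < 0) || any(loss < 0))
    stop("'gain' and 'loss' must be finite non-negative magnitudes")
  b <- choice_betas(fit)
  if (any(!is.finite(b))) stop("non-finite coefficients")
  b[1] * gain + b[2] * loss
}

#' Acceptance probability from subjective value
#'
#' Inverse-logit of `sv + intercept`; strictly increasing in `sv`.
#'
#' @param fit a [choice_model()] fit or a single numeric intercept.
#' @param sv subjective value(s) (logit units).
#' @return acceptance probabilities.
#' @export
accept_prob <- function(fit, sv) {
  intercept <- if (inherits(fit, "choice_model"))
    fit$coefficients[["(Intercept)"]] else as.numeric(fit)
  if (!is.finite(intercept) || any(!is.finite(sv)))
    stop("'sv' and intercept must be finite")
  stats::plogis(sv + intercept)
}

choice_betas <- function(fit) {
  if (inherits(fit, "choice_model")) {
    b <- fit$coefficients
    c(b[["gain"]], b[["loss"]])
  } else {
    as.numeric(fit[1:2])
  }
}

#' Simulate choices from a choice model
#'
#' Draws Bernoulli accept/reject choices at the model's acceptance
#' probabilities and assigns 4-level responses: the sampled side is labelled
#' "strongly" when the subjective probability of being correct reaches the
#' confidence threshold `theta`, "weakly" otherwise.
#'
#' @param object a [choice_model()] fit (possibly constructed from true
#'   coefficients via [true_choice_model()]).
#' @param nsim number of replicate simulations (columns).
#' @param seed optional integer seed.
#' @param newdata gambles to simulate on (default: fitting data).
#' @param theta confidence threshold on `p_correct` for a "strong" response
#'   (default 0.75).
#' @param ... unused.
#' @return for `nsim = 1`, a data frame with `accept` and `response4`;
#'   otherwise a list of such data frames.
#' @export
simulate.choice_model <- function(object, nsim = 1, seed = NULL,
                                  newdata = NULL, theta = 0.75, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::predict(object, newdata = newdata, type = "response")
  pc <- prob_correct(p)
  one <- function() {
    accept <- stats::rbinom(length(p), 1, p)
    strong <- pc >= theta
    response4 <- ifelse(accept == 1,
                        ifelse(strong, "strongly_accept", "weakly_accept"),
                        ifelse(strong, "strongly_reject", "weakly_reject"))
    data.frame(accept = accept,
               response4 = factor(response4, levels = response_levels()))
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Construct a choice model object from known coefficients
#'
#' Used by the synthetic-data generator: wraps true generating coefficients
#' in a `choice_model` object so that `predict()` and `simulate()` apply.
#'
#' @param beta_gains,beta_losses,intercept model coefficients (logit units
#'   per currency unit; intercept in logit units).
#' @return a `choice_model` object with `converged = TRUE`.
#' @export
true_choice_model <- function(beta_gains, beta_losses, intercept = 0) {
  stopifnot(is.finite(beta_gains), is.finite(beta_losses), is.finite(intercept))
  b <- c("(Intercept)" = intercept, gain = beta_gains, loss = beta_losses)
  out <- list(coefficients = b, vcov = NULL, fitted = NULL, y = NULL,
              X = NULL, formula = accept ~ gain + loss,
              converged = TRUE, separable = FALSE, penalty = 0,
              logLik = NA_real_, n = 0L, n_dropped = 0L)
  out$loss_aversion <- -beta_losses / beta_gains
  class(out) <- "choice_model"
  out
}

#' @export
plot.choice_model <- function(x, sv_range = NULL, ...) {
  if (is.null(sv_range)) {
    sv <- if (!is.null(x$X)) stats::predict(x, type = "sv") else c(-5, 5)
    sv_range <- range(sv)
  }
  s <- seq(sv_range[1], sv_range[2], length.out = 200)
  p <- accept_prob(x, s)
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(s, p, type = "l", xlab = "subjective value",
                 ylab = "p(accept)", main = "Choice curve", ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::plot(s, inverse_decision_entropy(p), type = "l",
                 xlab = "subjective value", ylab = "iDE (bits)",
                 main = "Inverse decision entropy", ...)
  invisible(x)
}

response_levels <- function() {
  c("strongly_reject", "weakly_reject", "weakly_accept", "strongly_accept")
}
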