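# GBLUP: y = X b + u + e with u ~ N(0, G sigma_u^2), e ~ N(0, I sigma_e^2),
# phenotypes observed on the training individuals only. Variance components
# are estimated by average-information REML. The training block of G is
# eigendecomposed once (G = U D U'); in the rotated basis V = sigma_u^2 D +
# sigma_e^2 I is diagonal, so every REML iteration costs O(n) after the
# decomposition. Breeding values of all individuals covered by G (including
# unphenotyped validation animals) are obtained from the BLUP identity
# u_hat = sigma_u^2 G[., train] V^{-1} (y - X b_hat).

# Core REML quantities at th = (sigma_u2, sigma_e2), in the rotated basis.
.reml_quantities <- function(th, yt, Xt, d, n, p) {
  v <- th[1L] * d + th[2L]
  vi_y <- yt / v
  Xv <- Xt / v
  XtVX <- crossprod(Xt, Xv)
  beta <- solve(XtVX, crossprod(Xt, vi_y))
  r <- yt - drop(Xt %*% beta)
  Py <- r / v
  m2ll <- sum(log(v)) + as.numeric(determinant(XtVX)$modulus) +
    sum(r * Py) + (n - p) * log(2 * pi)
  Pz <- function(z) {
    zv <- z / v
    zv - drop(Xv %*% solve(XtVX, crossprod(Xt, zv)))
  }
  trPA <- function(a) {
    B <- crossprod(Xt, Xt * (a / v^2))
    sum(a / v) - sum(diag(solve(XtVX, B)))
  }
  quad_u <- sum(d * Py^2)
  quad_e <- sum(Py^2)
  score <- -0.5 * c(trPA(d) - quad_u, trPA(rep(1, n)) - quad_e)
  zu <- d * Py
  AI <- 0.5 * matrix(c(sum(zu * Pz(zu)), sum(zu * Pz(Py)),
                       sum(zu * Pz(Py)), sum(Py * Pz(Py))), 2L, 2L)
  list(m2ll = m2ll, beta = drop(beta), Py = Py, score = score, AI = AI,
       quad = c(quad_u, quad_e))
}

.as_kinship <- function(K) {
  if (inherits(K, "grm")) K <- K$values
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("'K' must be a square relationship matrix or a 'grm' object",
         call. = FALSE)
  if (is.null(rownames(K))) {
    rn <- sprintf("ind%04d", seq_len(nrow(K)))
    dimnames(K) <- list(rn, rn)
  }
  K
}

#' Fit a GBLUP model by AI-REML
#'
#' Estimates the genetic and residual variance of the single-random-effect
#' animal model `y = X b + u + e`, `u ~ N(0, G sigma_u^2)`, by restricted
#' maximum likelihood with average-information updates (an EM-flavoured step
#' is substituted whenever the AI proposal leaves the parameter space), and
#' predicts genomic breeding values for every individual covered by the
#' relationship matrix, including unphenotyped ones.
#'
#' Before inversion the relationship matrix is stabilized as
#' `G* = (1 - blend) G + blend I`; weighted or reduced-panel matrices can be
#' singular, and the default 1% identity blend keeps the mixed model well
#' posed without materially changing the fit.
#'
#' @param y Named numeric vector of training phenotypes.
#' @param K Relationship matrix (a [build_grm()] result or a symmetric matrix
#'   with id dimnames) covering at least the training individuals; any
#'   additional ids receive predicted breeding values.
#' @param ids Training ids (default `names(y)`).
#' @param X Fixed-effect design matrix for the training individuals (default:
#'   intercept only). Must have full column rank.
#' @param blend Identity weight for stabilizing `K` (default 0.01).
#' @param init Optional starting values `c(sigma_u2, sigma_e2)`; default
#'   splits `var(y)` equally.
#' @param tol Convergence tolerance on the relative change of both variance
#'   components (default 1e-8); the score norm must also fall below 1e-6
#'   (components held at the lower variance floor are exempt).
#' @param max_iter Maximum REML iterations (default 50). Non-convergence is
#'   flagged, not an error.
#' @return An object of class `"gblup"` with components `sigma_u2`,
#'   `sigma_e2`, `h2`, `minus2logL`, `n_iter`, `converged`, `b` (fixed
#'   effects), `u` (named breeding values for every id in `K`), `fitted`,
#'   `train_ids`, `trace` (per-iteration parameter values) and the matched
#'   call. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `logLik`, `simulate`, `plot`.
#' @examples
#' set.seed(42)
#' n <- 120
#' ids <- sprintf("a%03d", 1:n)
#' K <- diag(n); dimnames(K) <- list(ids, ids)
#' u <- rnorm(n, 0, sqrt(0.3))
#' y <- stats::setNames(2 + u + rnorm(n, 0, sqrt(0.7)), ids)
#' fit <- gblup(y, K, blend = 0)
#' fit
#' @export
gblup <- function(y, K, ids = names(y), X = NULL, blend = 0.01, init = NULL,
                  tol = 1e-8, max_iter = 50L) {
  K <- .as_kinship(K)
  all_ids <- rownames(K)
  if (is.null(ids)) {
    if (length(y) != nrow(K))
      stop("'y' has no names and does not match the relationship matrix",
           call. = FALSE)
    ids <- all_ids
  }
  if (!all(ids %in% all_ids))
    stop("some training ids are absent from the relationship matrix",
         call. = FALSE)
  if (anyNA(y)) stop("training phenotypes contain missing values", call. = FALSE)
  n <- length(y)
  if (n != length(ids)) stop("'y' and 'ids' lengths differ", call. = FALSE)
  if (blend < 0 || blend >= 1) stop("'blend' must lie in [0, 1)", call. = FALSE)

  Kb <- if (blend > 0) (1 - blend) * K + blend * diag(nrow(K)) else K
  dimnames(Kb) <- dimnames(K)
  Ktt <- Kb[ids, ids]
  eg <- eigen(Ktt, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.matrix(X) || nrow(X) != n)
    stop("'X' must be a matrix with one row per training individual",
         call. = FALSE)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("'X' is rank deficient", call. = FALSE)

  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vy <- stats::var(y)
  if (vy <= 0) stop("training phenotypes have zero variance", call. = FALSE)
  floor_v <- 1e-8 * vy
  upper_v <- 10 * vy
  th <- if (is.null(init)) c(vy / 2, vy / 2) else as.numeric(init)
  if (length(th) != 2L || any(th <= 0))
    stop("'init' must be two positive variances", call. = FALSE)

  trace <- matrix(NA_real_, max_iter + 1L, 4L,
                  dimnames = list(NULL, c("sigma_u2", "sigma_e2",
                                          "minus2logL", "step")))
  converged <- FALSE
  q <- .reml_quantities(th, yt, Xt, d, n, p)
  trace[1L, ] <- c(th, q$m2ll, NA)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step_type <- "AI"
    delta <- tryCatch(solve(q$AI, q$score), error = function(e) NULL)
    prop <- if (is.null(delta)) NULL else th + delta
    if (is.null(prop) || any(!is.finite(prop)) || any(prop < floor_v) ||
        any(prop > upper_v)) {
      # EM-flavoured fallback: th_i + th_i^2 (y'P A_i P y - tr(P A_i)) / n
      step_type <- "EM"
      prop <- th + 2 * th^2 * q$score / n
      prop <- pmin(pmax(prop, floor_v), upper_v)
    }
    rel_change <- abs(prop - th) / pmax(th, floor_v)
    th <- prop
    q <- .reml_quantities(th, yt, Xt, d, n, p)
    trace[iter + 1L, ] <- c(th, q$m2ll, if (step_type == "AI") 1 else 2)
    # KKT: a component pinned at the floor with an inward-pointing gradient
    # is at its boundary optimum; its score does not block convergence.
    eff_score <- q$score
    at_floor <- th <= floor_v * (1 + 1e-12)
    eff_score[at_floor & eff_score < 0] <- 0
    if (max(rel_change) < tol && sqrt(sum(eff_score^2)) < 1e-6) {
      converged <- TRUE
      break
    }
  }

  Py_orig <- drop(U %*% q$Py)
  u_all <- drop(th[1L] * (Kb[, ids, drop = FALSE] %*% Py_orig))
  names(u_all) <- all_ids
  b <- q$beta
  names(b) <- colnames(X)
  fitted_train <- drop(X %*% b) + u_all[ids]
  names(fitted_train) <- ids

  structure(list(
    sigma_u2 = th[1L], sigma_e2 = th[2L], h2 = th[1L] / sum(th),
    minus2logL = q$m2ll, n_iter = iter, converged = converged,
    b = b, u = u_all, fitted = fitted_train, y = stats::setNames(y, ids),
    train_ids = ids, blend = blend, trace = trace[seq_len(iter + 1L), ,
                                                  drop = FALSE],
    eigen = list(U = U, d = d), X = X, n = n, call = match.call()
  ), class = "gblup")
}

#' Restricted-likelihood deviance of a GBLUP model at fixed variances
#'
#' Evaluates -2 times the restricted log-likelihood of the animal model at
#' the supplied variance components, with the constant convention
#' `log|V| + log|X' V^-1 X| + y' P y + (n - p) log(2 pi)`. Useful for
#' profiling the likelihood or comparing fits at common values.
#'
#' @inheritParams gblup
#' @param sigma_u2,sigma_e2 Variance components at which to evaluate.
#' @return The deviance (scalar).
#' @export
gblup_deviance <- function(y, K, sigma_u2, sigma_e2, ids = names(y),
                           X = NULL, blend = 0.01) {
  K <- .as_kinship(K)
  if (is.null(ids)) ids <- rownames(K)
  n <- length(y)
  Kb <- if (blend > 0) (1 - blend) * K + blend * diag(nrow(K)) else K
  dimnames(Kb) <- dimnames(K)
  eg <- eigen(Kb[ids, ids], symmetric = TRUE)
  if (is.null(X)) X <- matrix(1, n, 1L)
  q <- .reml_quantities(c(sigma_u2, sigma_e2), drop(crossprod(eg$vectors, y)),
                        crossprod(eg$vectors, X), pmax(eg$values, 0), n,
                        ncol(X))
  q$m2ll
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit (AI-REML)\n")
  cat(sprintf("  n train = %d, n predicted = %d\n", x$n, length(x$u)))
  cat(sprintf("  sigma_u2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$h2))
  cat(sprintf("  -2logL = %.3f after %d iterations (%s)\n", x$minus2logL,
              x$n_iter, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  structure(list(fit = object), class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  fixed effects: %s\n",
              paste(sprintf("%s = %.4f", names(f$b), f$b), collapse = ", ")))
  cat(sprintf("  blend = %.2f; variance floor at 1e-8 * var(y)\n", f$blend))
  cat("  iteration trace (last rows):\n")
  print(utils::tail(round(f$trace, 6), 3L))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$b

#' Predicted genomic breeding values
#'
#' @param object A [gblup()] fit.
#' @param ids Ids to return (default: every individual covered by the
#'   relationship matrix, phenotyped or not).
#' @param ... Unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$u)
  if (!all(ids %in% names(object$u)))
    stop("some requested ids were not covered by the relationship matrix",
         call. = FALSE)
  object$u[ids]
}

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$y - object$fitted

#' @export
logLik.gblup <- function(object, ...) {
  structure(-0.5 * object$minus2logL, df = 2L + length(object$b),
            nobs = object$n, class = "logLik")
}

#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  U <- object$eigen$U
  d <- object$eigen$d
  n <- object$n
  xb <- drop(object$X %*% object$b)
  out <- replicate(nsim, {
    u <- drop(U %*% (sqrt(object$sigma_u2 * d) * stats::rnorm(n)))
    xb + u + stats::rnorm(n, 0, sqrt(object$sigma_e2))
  })
  out <- as.data.frame(out, row.names = object$train_ids)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "phenotype",
                 ylab = "fitted (Xb + GEBV)",
                 main = "GBLUP training fit", pch = 20,
                 col = "#00000080", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Accuracy and bias of genomic predictions
#'
#' Accuracy is the Pearson correlation between true and predicted breeding
#' values in the validation set; bias is summarized by the ordinary
#' least-squares regression of the predicted on the true values (slope 1 and
#' intercept 0 indicate unbiased dispersion).
#'
#' @param tbv Named vector of true breeding values.
#' @param gebv Named vector of predicted breeding values.
#' @param ids Validation ids (default: intersection of the names).
#' @return List of class `"gs_accuracy"`: `accuracy`, `intercept`, `slope`,
#'   `n`.
#' @export
evaluate_accuracy <- function(tbv, gebv, ids = NULL) {
  if (is.null(ids)) ids <- intersect(names(tbv), names(gebv))
  if (length(ids) < 3L)
    stop("need at least 3 validation individuals", call. = FALSE)
  t <- as.numeric(tbv[ids])
  g <- as.numeric(gebv[ids])
  if (stats::var(t) == 0 || stats::var(g) == 0)
    stop("zero-variance breeding values: accuracy undefined", call. = FALSE)
  slope <- stats::cov(t, g) / stats::var(t)
  structure(list(accuracy = stats::cor(t, g),
                 intercept = mean(g) - slope * mean(t),
                 slope = slope, n = length(ids)),
            class = "gs_accuracy")
}

#' @export
print.gs_accuracy <- function(x, ...) {
  cat(sprintf("Validation accuracy %.3f (n = %d); GEBV-on-TBV slope %.3f, intercept %.3f\n",
              x$accuracy, x$n, x$slope, x$intercept))
  invisible(x)
}
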