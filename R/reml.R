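# Average-information REML for linear mixed ("animal") models with any mix
# of GRM-structured and group-structured random effects. This is the engine
# behind the chromosome partition, regional heritability scan and the
# mixed-model SNP refits.

#' Fit a variance-component animal model by AI-REML
#'
#' Fits \deqn{y = X\beta + \sum_k Z_k u_k + e,\qquad
#'   u_k \sim N(0, \sigma^2_k K_k),\ e \sim N(0, \sigma^2_e I)}
#' where each random term k is either GRM-structured (\eqn{K_k} a genomic
#' relatedness matrix over individuals) or an identity over the levels of a
#' grouping factor (e.g. birth year, year of measurement, or a permanent
#' environment term on individual for repeated measures).
#'
#' The REML maximum is found by average-information updates with step
#' halving and EM fallback when an AI step proposes out-of-bounds moves;
#' components are constrained non-negative (boundary at 0 allowed).
#' Convergence requires a relative log-likelihood change below
#' \code{tol_logl} and a score norm below \code{tol_grad}. On
#' non-convergence the fit is restarted once from perturbed values and, if
#' still unconverged, returned with \code{converged = FALSE}.
#'
#' @param fixed two-sided formula for the response and fixed effects,
#'   evaluated in \code{data}; factors (e.g. sex, age class) enter as
#'   multilevel factors, aliased columns are dropped.
#' @param data data.frame with one row per observation (repeated measures
#'   per individual allowed).
#' @param id name of the column in \code{data} holding individual ids.
#' @param grms named list of \code{\link{new_grm}} objects, one GRM-structured
#'   random term each; every observation's id must appear in each GRM.
#' @param groups character vector of column names fitted as
#'   identity-on-group random terms.
#' @param permanent_env if TRUE, adds an identity-on-individual random term
#'   capturing repeatable non-genetic variation across repeated measures.
#' @param start optional named numeric vector of starting variance components
#'   (terms plus "residual"); default splits var(y) equally.
#' @param max_iter maximum REML iterations (default 200).
#' @param tol_logl relative log-likelihood convergence tolerance (1e-8).
#' @param tol_grad score-norm convergence tolerance (1e-4).
#' @param check_psd validate that each GRM structure has no substantial
#'   negative spectrum before fitting (skippable for GRMs built by the
#'   package's own scan machinery).
#' @param verbose print per-iteration log-likelihoods.
#' @return An object of class \code{greml} with components \code{vc}
#'   (data.frame of estimates, SEs and boundary flags), \code{beta} and
#'   \code{beta_se} (fixed effects), \code{logLik}, \code{converged},
#'   \code{niter}, the AI matrix and its inverse, and the pieces needed for
#'   BLUPs and conditional residuals.
#' @seealso \code{\link{lrt_varcomp}}, \code{\link{variance_ratios}},
#'   \code{\link{grammar_residuals}}
#' @examples
#' set.seed(1)
#' d <- data.frame(id = as.character(1:40),
#'                 grp = rep(letters[1:8], each = 5))
#' d$y <- rnorm(8)[as.integer(factor(d$grp))] + rnorm(40)
#' fit <- greml(y ~ 1, d, id = "id", groups = "grp")
#' summary(fit)
#' @export
greml <- function(fixed, data, id, grms = list(), groups = character(0),
                  permanent_env = FALSE, start = NULL, max_iter = 200L,
                  tol_logl = 1e-8, tol_grad = 1e-4, check_psd = TRUE,
                  verbose = FALSE) {
  cl <- match.call()
  mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  n <- length(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  # drop aliased columns
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[-seq_len(qx$rank)]
    message("dropping ", length(drop), " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  ids <- as.character(data[[id]])
  if (length(ids) != n) stop("id column length mismatch")

  # build n x n covariance structures V_k for each random term
  Vk <- list()
  term_kind <- character(0)
  if (length(grms) > 0 && is.null(names(grms)))
    names(grms) <- paste0("grm", seq_along(grms))
  for (nm in names(grms)) {
    g <- grms[[nm]]
    stopifnot(inherits(g, "grm"))
    pos <- match(ids, g$ids)
    if (anyNA(pos))
      stop("ids missing from GRM '", nm, "': ",
           paste(utils::head(unique(ids[is.na(pos)]), 5), collapse = ", "))
    # marker-estimated GRMs are routinely indefinite by a whisker (the
    # GCTA-form diagonal is not the off-diagonal Gram diagonal, and
    # few-SNP region GRMs more so); only a negative spectrum comparable in
    # magnitude to the positive one indicates a truly invalid structure
    if (check_psd) {
      ev <- eigen(g$mat, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -0.05 * max(ev))
        stop("covariance structure for term '", nm,
             "' is not positive semi-definite (min eigenvalue ",
             signif(min(ev), 3), ")")
    }
    Vk[[nm]] <- g$mat[pos, pos, drop = FALSE]
    term_kind[nm] <- "grm"
  }
  for (nm in groups) {
    f <- factor(data[[nm]])
    Z <- stats::model.matrix(~ f - 1)
    Vk[[nm]] <- tcrossprod(Z)
    term_kind[nm] <- "group"
  }
  if (permanent_env) {
    f <- factor(ids)
    Z <- stats::model.matrix(~ f - 1)
    Vk[["permanent_env"]] <- tcrossprod(Z)
    term_kind["permanent_env"] <- "group"
  }
  K <- length(Vk)
  comp_names <- c(names(Vk), "residual")

  vy <- stats::var(y)
  if (is.null(start)) {
    s2 <- rep(vy / (K + 1), K + 1)
  } else {
    s2 <- start[comp_names]
    if (anyNA(s2)) stop("start must name every component incl. 'residual'")
  }
  names(s2) <- comp_names
  floor_v <- 1e-8 * vy

  run <- reml_iterate(y, X, Vk, s2, floor_v, max_iter, tol_logl, tol_grad,
                      verbose)
  if (!run$converged) {
    # one restart from perturbed starting values
    s2b <- pmax(s2 * stats::runif(K + 1, 0.3, 3), floor_v)
    run2 <- reml_iterate(y, X, Vk, s2b, floor_v, max_iter, tol_logl,
                         tol_grad, verbose)
    if (run2$converged || run2$logLik > run$logLik) run <- run2
  }

  s2 <- run$s2
  boundary <- s2 <= floor_v * 1.01
  se <- rep(NA_real_, K + 1)
  ai_inv <- NULL
  free <- !boundary
  if (any(free) && !is.null(run$ai)) {
    aif <- run$ai[free, free, drop = FALSE]
    ai_inv_f <- tryCatch(solve(aif), error = function(e) NULL)
    if (!is.null(ai_inv_f)) {
      se[free] <- sqrt(pmax(diag(ai_inv_f), 0))
      ai_inv <- matrix(0, K + 1, K + 1,
                       dimnames = list(comp_names, comp_names))
      ai_inv[free, free] <- ai_inv_f
    }
  }
  vc <- data.frame(term = comp_names, estimate = unname(s2),
                   se = se, boundary = unname(boundary),
                   stringsAsFactors = FALSE)

  beta <- drop(run$beta)
  names(beta) <- colnames(X)
  beta_se <- sqrt(diag(run$beta_cov))
  names(beta_se) <- colnames(X)

  structure(list(call = cl, y = y, X = X, ids = ids, vc = vc,
                 sigma2 = s2, beta = beta, beta_se = beta_se,
                 beta_cov = run$beta_cov, logLik = run$logLik,
                 converged = run$converged, niter = run$niter,
                 ai = run$ai, ai_inv = ai_inv, Py = run$Py,
                 Vk = Vk, term_kind = term_kind, n = n),
            class = "greml")
}

# Single AI-REML run from given starting values.
reml_iterate <- function(y, X, Vk, s2, floor_v, max_iter, tol_logl,
                         tol_grad, verbose) {
  n <- length(y)
  K <- length(Vk)
  nc <- K + 1L
  eval_at <- function(s2) {
    V <- diag(s2[nc], n)
    for (k in seq_len(K)) V <- V + s2[k] * Vk[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVX <- crossprod(X, Vinv %*% X)
    chx <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtVXinv <- chol2inv(chx)
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% XtVXinv %*% t(VinvX)
    Py <- drop(P %*% y)
    logdetV <- 2 * sum(log(diag(ch)))
    logdetX <- 2 * sum(log(diag(chx)))
    logL <- -0.5 * (logdetV + logdetX + sum(y * Py))
    list(P = P, Py = Py, logL = logL, Vinv = Vinv, XtVXinv = XtVXinv)
  }
  st <- eval_at(s2)
  # an indefinite few-SNP GRM can defeat an equal-split start: shift the
  # starting mass toward the residual until V factorises
  tries <- 0
  vy_tot <- sum(s2)
  while (is.null(st) && tries < 6) {
    s2[seq_len(K)] <- s2[seq_len(K)] / 4
    s2[nc] <- vy_tot - sum(s2[seq_len(K)])
    st <- eval_at(s2)
    tries <- tries + 1
  }
  if (is.null(st)) stop("initial variance matrix not positive definite")
  logL <- st$logL
  converged <- FALSE
  it <- 0L
  score <- rep(NA_real_, nc)
  AI <- NULL
  while (it < max_iter) {
    it <- it + 1L
    # working vectors W_k = V_k %*% Py (residual: Py itself)
    W <- matrix(0, n, nc)
    for (k in seq_len(K)) W[, k] <- Vk[[k]] %*% st$Py
    W[, nc] <- st$Py
    PW <- st$P %*% W
    # score: -0.5 * (tr(P V_k) - Py' V_k Py)
    trPV <- numeric(nc)
    for (k in seq_len(K)) trPV[k] <- sum(st$P * Vk[[k]])
    trPV[nc] <- sum(diag(st$P))
    quad <- colSums(W * st$Py)
    score <- -0.5 * (trPV - quad)
    AI <- 0.5 * crossprod(W, PW)
    # At a zero boundary with inward-pointing (negative) score, the
    # component stays pinned; its score is not part of the gradient norm.
    pinned <- s2 <= floor_v * 1.01 & score < 0
    gnorm <- sqrt(sum(score[!pinned]^2))
    if (verbose)
      message(sprintf("iter %d logL %.6f |score| %.3g", it, logL, gnorm))

    # propose AI step on free components
    free <- !pinned
    delta <- rep(0, nc)
    ok <- FALSE
    if (any(free)) {
      aif <- AI[free, free, drop = FALSE]
      sol <- tryCatch(solve(aif, score[free]), error = function(e) NULL)
      if (!is.null(sol)) {
        delta[free] <- sol
        ok <- TRUE
      }
    }
    if (!ok) {
      # EM fallback step
      delta <- (s2^2 / n) * (quad - trPV)
    }
    step <- 1
    new_st <- NULL
    s2_new <- s2
    for (h in 1:12) {
      s2_try <- pmax(s2 + step * delta, floor_v)
      cand <- eval_at(s2_try)
      if (!is.null(cand) && cand$logL >= logL - 1e-10) {
        new_st <- cand
        s2_new <- s2_try
        break
      }
      step <- step / 2
    }
    if (is.null(new_st)) {
      # EM fallback if even halved AI steps fail
      s2_try <- pmax(s2 + (s2^2 / n) * (quad - trPV), floor_v)
      cand <- eval_at(s2_try)
      if (is.null(cand)) break
      new_st <- cand
      s2_new <- s2_try
    }
    dl <- new_st$logL - logL
    s2 <- s2_new
    st <- new_st
    prev <- logL
    logL <- st$logL
    if (abs(dl) < tol_logl * (abs(prev) + 1) && gnorm < tol_grad) {
      converged <- TRUE
      break
    }
  }
  # GLS fixed effects at the final variance estimates
  VinvX <- st$Vinv %*% X
  beta_cov <- st$XtVXinv
  beta <- beta_cov %*% crossprod(VinvX, y)
  list(s2 = s2, logLik = logL, converged = converged, niter = it,
       ai = AI, Py = st$Py, beta = beta, beta_cov = beta_cov)
}

#' @export
print.greml <- function(x, ...) {
  cat("AI-REML fit:", x$n, "observations,",
      length(unique(x$ids)), "individuals\n")
  cat("logLik:", format(x$logLik, digits = 8),
      if (x$converged) "(converged," else "(NOT converged,",
      x$niter, "iterations)\n")
  print(x$vc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  vr <- variance_ratios(object)
  structure(list(fit = object, ratios = vr), class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, ...) {
  print(x$fit)
  cat("\nVariance ratios (component / total phenotypic variance):\n")
  print(x$ratios, row.names = FALSE, digits = 4)
  cat("\nFixed effects:\n")
  fe <- data.frame(estimate = x$fit$beta, se = x$fit$beta_se)
  print(fe, digits = 4)
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$beta

#' @export
logLik.greml <- function(object, ...) {
  structure(object$logLik, df = nrow(object$vc) + length(object$beta),
            class = "logLik")
}

#' @export
vcov.greml <- function(object, ...) object$beta_cov

#' Conditional residuals and GRAMMAR residuals
#'
#' \code{type = "conditional"} returns per-observation residuals
#' \eqn{y - X\hat\beta - \sum_k Z_k \hat u_k}, i.e. the phenotype minus fixed
#' effects and the BLUPs of every random term (equal to
#' \eqn{\hat\sigma^2_e P y}).
#'
#' @param object a \code{greml} fit.
#' @param type "conditional" (default) or "marginal" (\eqn{y - X\hat\beta}).
#' @param ... unused.
#' @return Numeric vector of residuals, one per observation.
#' @export
residuals.greml <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "marginal")
    return(drop(object$y - object$X %*% object$beta))
  drop(object$sigma2[["residual"]] * object$Py)
}

#' @export
fitted.greml <- function(object, ...) {
  object$y - residuals.greml(object, "conditional")
}

#' BLUPs of a random term
#'
#' @param fit a \code{greml} fit.
#' @param term name of the random term.
#' @return Per-observation random-effect predictions
#'   \eqn{Z_k \hat u_k = \hat\sigma^2_k V_k P y}.
#' @export
greml_blup <- function(fit, term) {
  stopifnot(inherits(fit, "greml"))
  if (!term %in% names(fit$Vk)) stop("unknown random term: ", term)
  drop(fit$sigma2[[term]] * (fit$Vk[[term]] %*% fit$Py))
}

#' Likelihood-ratio test between nested REML fits
#'
#' LRT = 2 (logL_full - logL_reduced), floored at 0; P from the upper tail
#' of chi-square with 1 df, as is standard when testing one variance
#' component (a boundary-mixture reference 0.5*chisq(0) + 0.5*chisq(1) is
#' available via \code{mixture = TRUE}; the plain chi-square(1) default is
#' conservative).
#'
#' @param full,reduced \code{greml} fits; \code{reduced} must omit exactly
#'   one random term of \code{full} (same fixed effects and data).
#' @param mixture use the boundary mixture reference instead of chi-square(1).
#' @return list with \code{lrt}, \code{p}, \code{df}.
#' @export
lrt_varcomp <- function(full, reduced, mixture = FALSE) {
  stopifnot(inherits(full, "greml"), inherits(reduced, "greml"))
  tf <- full$vc$term
  tr <- reduced$vc$term
  if (!(all(tr %in% tf) && length(setdiff(tf, tr)) == 1L))
    stop("models are not nested with one fewer variance component")
  if (full$n != reduced$n)
    stop("fits use different numbers of observations")
  lrt <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (mixture) {
    if (lrt == 0) 1 else 0.5 * stats::pchisq(lrt, 1, lower.tail = FALSE)
  } else {
    stats::pchisq(lrt, 1, lower.tail = FALSE)
  }
  list(lrt = lrt, p = p, df = 1L)
}

#' @export
anova.greml <- function(object, object2, ...) {
  # order by logLik dimension: the model with more terms is "full"
  if (nrow(object$vc) >= nrow(object2$vc)) {
    full <- object; red <- object2
  } else {
    full <- object2; red <- object
  }
  r <- lrt_varcomp(full, red)
  out <- data.frame(terms = c(nrow(red$vc), nrow(full$vc)),
                    logLik = c(red$logLik, full$logLik),
                    LRT = c(NA, r$lrt), p = c(NA, r$p))
  rownames(out) <- c("reduced", "full")
  structure(out, heading = "REML likelihood ratio test (chi-square, 1 df)",
            class = c("anova", "data.frame"))
}

#' Variance ratios (heritabilities) with delta-method standard errors
#'
#' Ratio of each component to the total phenotypic variance (sum of all
#' components including the residual). SEs use the first-order delta method
#' with the AI-matrix covariance of the estimates; they are NA for boundary
#' components.
#'
#' @param fit a converged \code{greml} fit.
#' @param terms components to report (default: all non-residual terms).
#' @return data.frame with term, ratio, se.
#' @export
variance_ratios <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "greml"))
  s2 <- fit$sigma2
  tot <- sum(s2)
  if (tot <= 0) stop("zero total variance")
  if (is.null(terms)) terms <- setdiff(names(s2), "residual")
  if (!all(terms %in% names(s2))) stop("unknown term(s)")
  nc <- length(s2)
  se <- rep(NA_real_, length(terms))
  if (!is.null(fit$ai_inv)) {
    for (i in seq_along(terms)) {
      k <- match(terms[i], names(s2))
      if (fit$vc$boundary[k]) next
      g <- rep(-s2[[k]] / tot^2, nc)
      g[k] <- (tot - s2[[k]]) / tot^2
      se[i] <- sqrt(max(0, drop(t(g) %*% fit$ai_inv %*% g)))
    }
  }
  data.frame(term = terms,
             ratio = unname(s2[terms] / tot),
             se = se, stringsAsFactors = FALSE)
}
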