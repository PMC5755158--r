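#' Restricted maximum likelihood for linear covariance structures
#'
#' Fits V(theta) = sum_k theta_k B_k by average-information REML with
#' guarded steps: the AI update is tried first (with step halving) and a
#' multiplicative EM-type update on the variance parameters serves as
#' fallback when the AI proposal leaves the parameter space or decreases
#' the restricted likelihood. This linear parameterization covers both the
#' univariate animal model (B = Z A Z', Z Z', I) and bivariate models
#' (per-structure 2x2 covariance blocks), so one engine backs all the
#' variance-component models in the package.
#'
#' @param y numeric response vector (complete cases).
#' @param X fixed-effects design matrix (full rank).
#' @param Blist list of n x n symmetric matrices (base `matrix` or
#'   `Matrix`), one per parameter; the residual structure must be included.
#' @param var_par logical per parameter: TRUE for variances (floored),
#'   FALSE for covariances (unbounded).
#' @param init optional starting values.
#' @param floor_frac variance floor as a fraction of var(y).
#' @param tol convergence tolerance on relative parameter change and
#'   log-likelihood change.
#' @param max_iter iteration cap.
#' @param verbose print iteration trace.
#' @return list with `theta` (estimates), `se`, `logLik`, `converged`,
#'   `iterations`, `AI`, `beta`, `beta_se`, `beta_names`, `floor`.
#' @export
reml_fit <- function(y, X, Blist, var_par, init = NULL,
                     floor_frac = 1e-8, tol = 1e-8, max_iter = 200,
                     verbose = FALSE) {
  n <- length(y)
  K <- length(Blist)
  stopifnot(length(var_par) == K, nrow(X) == n)
  Blist <- lapply(Blist, function(B) {
    B <- methods::as(methods::as(B, "CsparseMatrix"), "generalMatrix")
    Matrix::forceSymmetric(B)
  })
  vy <- stats::var(y)
  floor_v <- floor_frac * vy
  theta <- if (is.null(init)) {
    ifelse(var_par, vy / sum(var_par), 0)
  } else {
    stopifnot(length(init) == K)
    init
  }
  theta[var_par] <- pmax(theta[var_par], floor_v)

  # likelihood-only evaluation: Cholesky + triangular solves, no inverse
  eval_point <- function(th) {
    V <- Reduce(`+`, Map(function(t, B) t * B, th, Blist))
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(V), LDL = FALSE,
                                    perm = TRUE),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ch)) return(NULL)
    W <- as.matrix(Matrix::solve(ch, X))          # V^{-1} X
    XtViX <- crossprod(X, W)
    cx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    XtViX_inv <- chol2inv(cx)
    Viy <- as.numeric(Matrix::solve(ch, y))
    beta <- XtViX_inv %*% crossprod(X, Viy)
    Py <- as.numeric(Viy - W %*% (XtViX_inv %*% crossprod(X, Viy)))
    ldV <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                              sqrt = TRUE)$modulus)
    ldX <- 2 * sum(log(diag(cx)))
    ll <- -0.5 * (ldV + ldX + sum(y * Py) +
                    (n - ncol(X)) * log(2 * pi))
    list(ch = ch, W = W, XtViX_inv = XtViX_inv, Py = Py,
         beta = as.numeric(beta), logLik = ll)
  }

  ep <- eval_point(theta)
  if (is.null(ep)) stop("starting values give a non-positive-definite V")
  converged <- FALSE
  iter <- 0
  AI <- NULL
  score <- NULL
  repeat {
    iter <- iter + 1
    # first derivatives and AI matrix at the current (accepted) point;
    # the sparse inverse is computed once per iteration, only here
    Vi <- Matrix::solve(ep$ch, Matrix::Diagonal(n))
    U <- matrix(0, n, K)          # columns B_k P y
    trPB <- numeric(K)
    for (k in seq_len(K)) {
      U[, k] <- as.numeric(Blist[[k]] %*% ep$Py)
      tr_ViB <- sum(Vi * Blist[[k]])
      WB <- crossprod(ep$W, as.matrix(Blist[[k]] %*% ep$W))
      trPB[k] <- tr_ViB - sum(ep$XtViX_inv * WB)
    }
    yPBPy <- as.numeric(crossprod(U, ep$Py))
    score <- -0.5 * (trPB - yPBPy)
    ViU <- as.matrix(Matrix::solve(ep$ch, U))
    PU <- ViU - ep$W %*% (ep$XtViX_inv %*% crossprod(X, ViU))
    AI <- 0.5 * crossprod(U, PU)
    AI <- (AI + t(AI)) / 2

    # active set: variance parameters pinned at the floor with a negative
    # gradient stay there; solving the reduced AI system for the rest
    # avoids the boundary dimension contaminating (and damping) the step
    free <- !(var_par & theta <= floor_v * (1 + 1e-6) & score < 0)
    delta <- rep(0, K)
    if (any(free)) {
      d_free <- tryCatch(solve(AI[free, free, drop = FALSE] +
                                 diag(1e-12, sum(free)), score[free]),
                         error = function(e) NULL)
      if (is.null(d_free)) delta <- NULL else delta[free] <- d_free
    }
    accepted <- FALSE
    new_theta <- theta
    new_ep <- ep
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:12) {
        cand <- theta + step * delta
        cand[var_par] <- pmax(cand[var_par], floor_v)
        epc <- eval_point(cand)
        if (!is.null(epc) && epc$logLik >= ep$logLik - 1e-6) {
          new_theta <- cand; new_ep <- epc; accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # EM-type fallback: multiplicative update on variance parameters
      cand <- theta
      ratio <- yPBPy / pmax(trPB, 1e-300)
      ratio[!is.finite(ratio) | ratio <= 0] <- 1
      cand[var_par] <- pmax(theta[var_par] * ratio[var_par], floor_v)
      epc <- eval_point(cand)
      if (!is.null(epc)) {
        new_theta <- cand; new_ep <- epc; accepted <- TRUE
      }
    }
    if (verbose)
      message(sprintf("iter %d logLik %.6f theta %s", iter, new_ep$logLik,
                      paste(signif(new_theta, 4), collapse = " ")))
    rel_change <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-10))
    ll_change <- abs(new_ep$logLik - ep$logLik)
    theta <- new_theta
    ep <- new_ep
    if (accepted && rel_change < tol && ll_change < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  se <- rep(NA_real_, K)
  cov_theta <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(cov_theta)) {
    dg <- diag(cov_theta)
    se[dg > 0] <- sqrt(dg[dg > 0])
  }
  names(theta) <- names(se) <- names(Blist)
  list(theta = theta, se = se, logLik = ep$logLik, converged = converged,
       iterations = iter, AI = AI, cov_theta = cov_theta,
       beta = ep$beta, beta_se = sqrt(diag(ep$XtViX_inv)),
       beta_names = colnames(X), floor = floor_v, n = n)
}

# full-rank fixed-effect design; aliased columns dropped with a note
.design_matrix <- function(fixed, data) {
  X <- stats::model.matrix(stats::reformulate(if (length(fixed)) fixed else "1"),
                           data)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    message("dropping aliased fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  X
}

.indicator <- function(f) {
  f <- factor(f)
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

#' Univariate animal-model REML
#'
#' Estimates variance components for one trait under an individual animal
#' model: fixed effects (default sex + birth site), a pedigree-structured
#' additive animal effect (covariance A sigma2_a), optional
#' identity-covariance litter and pen effects, and a residual. The additive
#' covariance among recorded animals uses the corresponding submatrix of A,
#' which is equivalent to carrying unrecorded ancestors explicitly.
#'
#' @param trait name of the response column in `data`.
#' @param data data.frame with the response and design columns (`animal`,
#'   and the factors named in `fixed`/`random`).
#' @param A numerator relationship matrix covering all animals with
#'   records (required when "animal" is in `random`).
#' @param fixed character vector of fixed-effect column names.
#' @param random subset of c("animal", "litter", "pen"); a residual is
#'   always added.
#' @param ... passed to [reml_fit()].
#' @return a [reml_fit()] result with component names
#'   (e.g. "animal", "litter", "residual") and the model description.
#' @export
reml_univariate <- function(trait, data, A = NULL, fixed = c("sex", "bs"),
                            random = c("animal", "litter"), ...) {
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  y <- data[[trait]]
  for (f in fixed) {
    if (length(unique(data[[f]])) < 2)
      stop("fixed factor '", f, "' has fewer than 2 levels")
  }
  X <- .design_matrix(fixed, data)
  Blist <- list()
  for (term in random) {
    if (term == "animal") {
      if (is.null(A)) stop("the animal effect requires a relationship matrix A")
      ids <- as.character(data$animal)
      miss <- setdiff(unique(ids), rownames(A))
      if (length(miss)) stop("animals missing from A: ",
                             paste(utils::head(miss, 5), collapse = ", "))
      Z <- .indicator(factor(ids, levels = unique(ids)))
      K <- .sparsify(A[unique(ids), unique(ids)])
      B <- Z %*% K %*% Matrix::t(Z)
      Blist$animal <- Matrix::drop0(B, tol = 1e-14)
    } else {
      Z <- .indicator(data[[term]])
      Blist[[term]] <- Matrix::tcrossprod(Z)
    }
  }
  Blist$residual <- Matrix::Diagonal(length(y))
  fit <- reml_fit(y, X, Blist, var_par = rep(TRUE, length(Blist)), ...)
  fit$trait <- trait
  fit$random <- names(Blist)
  fit
}

#' Bivariate animal-model REML
#'
#' Joint REML for two traits with a 2x2 covariance matrix per random
#' structure (animal with covariance A, optional litter/pen with identity
#' covariance, residual matched on animal). Records missing one trait are
#' retained. If an estimated 2x2 block leaves the PSD cone it is bent to
#' the nearest PSD matrix and flagged.
#'
#' @param traits character vector of two response column names.
#' @param data data.frame with responses and design columns.
#' @param A numerator relationship matrix.
#' @param fixed fixed-effect column names (applied to both traits, crossed
#'   with a trait indicator).
#' @param random subset of c("animal", "litter", "pen").
#' @param init optional starting values (one per parameter, structure order
#'   v1/c/v2); e.g. warm starts from univariate fits.
#' @param ... passed to [reml_fit()].
#' @return [reml_fit()] result plus `components`: per-structure 2x2
#'   matrices, and `bent` flags.
#' @export
reml_bivariate <- function(traits, data, A = NULL, fixed = c("sex", "bs"),
                           random = c("animal", "litter"), init = NULL, ...) {
  stopifnot(length(traits) == 2)
  keep1 <- !is.na(data[[traits[1]]])
  keep2 <- !is.na(data[[traits[2]]])
  d1 <- data[keep1, , drop = FALSE]
  d2 <- data[keep2, , drop = FALSE]
  n1 <- nrow(d1); n2 <- nrow(d2); n <- n1 + n2
  y <- c(d1[[traits[1]]], d2[[traits[2]]])
  stacked <- rbind(d1, d2)
  stacked$trait_ <- factor(rep(traits, c(n1, n2)), levels = traits)
  X <- .design_matrix(c("trait_", paste0("trait_:", fixed)), stacked)

  pad <- function(B, where) {
    # place B into the stacked (n1+n2) system via triplets (fast)
    T_ <- methods::as(methods::as(methods::as(B, "CsparseMatrix"),
                                  "generalMatrix"), "TsparseMatrix")
    i <- T_@i + 1L; j <- T_@j + 1L; x <- T_@x
    if (where == "22") {
      i <- i + n1; j <- j + n1
    } else if (where == "12") {
      i_new <- c(i, j + n1)
      j_new <- c(j + n1, i)
      i <- i_new; j <- j_new
      x <- c(x, x)
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  }
  struct_B <- function(g1, g2, K = NULL) {
    levs <- unique(c(as.character(g1), as.character(g2)))
    Z1 <- .indicator(factor(g1, levels = levs))
    Z2 <- .indicator(factor(g2, levels = levs))
    KM <- if (is.null(K)) Matrix::Diagonal(length(levs)) else
      .sparsify(K[levs, levs])
    list(v1 = pad(Matrix::drop0(Z1 %*% KM %*% Matrix::t(Z1), 1e-14), "11"),
         c12 = pad(Matrix::drop0(Z1 %*% KM %*% Matrix::t(Z2), 1e-14), "12"),
         v2 = pad(Matrix::drop0(Z2 %*% KM %*% Matrix::t(Z2), 1e-14), "22"))
  }

  Blist <- list()
  var_par <- logical(0)
  add_struct <- function(name, parts) {
    Blist[[paste0(name, ".v1")]] <<- parts$v1
    Blist[[paste0(name, ".c")]] <<- parts$c12
    Blist[[paste0(name, ".v2")]] <<- parts$v2
    var_par <<- c(var_par, TRUE, FALSE, TRUE)
  }
  for (term in random) {
    if (term == "animal") {
      if (is.null(A)) stop("the animal effect requires a relationship matrix A")
      add_struct("animal", struct_B(d1$animal, d2$animal, K = A))
    } else {
      add_struct(term, struct_B(d1[[term]], d2[[term]]))
    }
  }
  add_struct("residual", struct_B(d1$animal, d2$animal))

  if (is.null(init)) {
    init <- numeric(length(Blist))
    names(init) <- names(Blist)
    nstruct <- length(Blist) / 3
    init[grepl("\\.v1$", names(init))] <- stats::var(d1[[traits[1]]]) / nstruct
    init[grepl("\\.v2$", names(init))] <- stats::var(d2[[traits[2]]]) / nstruct
  } else {
    stopifnot(length(init) == length(Blist))
  }

  fit <- reml_fit(y, X, Blist, var_par = var_par, init = init, ...)
  structs <- sub("\\.(v1|c|v2)$", "", names(fit$theta))
  comp <- list()
  bent <- logical(0)
  for (s in unique(structs)) {
    v1 <- fit$theta[paste0(s, ".v1")]
    cc <- fit$theta[paste0(s, ".c")]
    v2 <- fit$theta[paste0(s, ".v2")]
    b <- FALSE
    if (cc^2 > v1 * v2) {
      cc <- sign(cc) * 0.99 * sqrt(v1 * v2)
      b <- TRUE
    }
    comp[[s]] <- matrix(c(v1, cc, cc, v2), 2, 2,
                        dimnames = list(traits, traits))
    bent[s] <- b
  }
  fit$traits <- traits
  fit$components <- comp
  fit$bent <- bent
  fit
}
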